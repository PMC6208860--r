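test_that("model log ratios subtract matched controls on the shared universe", {
  v_model <- rand_mat(30, 4)
  v_ctrl <- v_model
  colnames(v_ctrl) <- paste0("c", 1:4)
  mds <- make_ds(v_model, group = rep("case", 4))
  cds <- make_ds(v_ctrl, group = rep("control", 4))
  prof <- suppressWarnings(model_log_ratios(mds, cds, min_universe = 10))
  expect_true(all(prof$ratios == 0))
  # one gene shifted +1 gives ratio exactly 1
  v2 <- v_model; v2["G005", ] <- v_model["G005", ] + 1
  prof2 <- suppressWarnings(
    model_log_ratios(make_ds(v2, group = rep("case", 4)), cds,
                     min_universe = 10))
  expect_equal(unname(prof2$ratios["G005"]), 1)
  # orthology applied: rodent symbols come out as human symbols
  om <- orthology_map(paste0("r_", rownames(v_model)), rownames(v_model))
  v3 <- v_model
  rownames(v3) <- paste0("r_", rownames(v_model))
  cv3 <- v_ctrl; rownames(cv3) <- rownames(v3)
  prof3 <- suppressWarnings(
    model_log_ratios(make_ds(v3, group = rep("case", 4)),
                     make_ds(cv3, group = rep("control", 4)),
                     orthology = om, min_universe = 10))
  expect_true(all(names(prof3$ratios) %in% rownames(v_model)))
  foreign <- rand_mat(3, 2, seed = 9)
  rownames(foreign) <- c("X1", "X2", "X3")
  expect_error(model_log_ratios(mds, make_ds(foreign)), "universe")
})

test_that("expression scoring hits the proportion bounds and classifies", {
  genes <- sprintf("g%03d", 1:200)
  r <- setNames(seq(-1, 1, length.out = 200), genes)
  sig <- gene_signature(genes[191:200], genes[1:10])  # extremes
  prof <- log_ratio_profile(r, model = "toy")
  sc <- score_expression(prof, sig, B = 200, seed = 1)
  expect_equal(sc$p_up, 0)
  expect_equal(sc$p_down, 0)
  expect_equal(sc$class, "strong")
  # all-equal ratios: every null mean equals the observed means
  flat <- log_ratio_profile(setNames(rep(0.3, 200), genes), model = "flat")
  sc_flat <- score_expression(flat, sig, B = 200, seed = 2)
  expect_equal(sc_flat$p_up, 1)
  expect_equal(sc_flat$p_down, 1)
  expect_equal(sc_flat$class, "none")
  # unmeasured direction flagged
  sig_miss <- gene_signature(c("zzz1", "zzz2"), genes[1:10])
  suppressMessages(
    expect_warning(sc_m <- score_expression(prof, sig_miss, B = 200, seed = 3),
                   "unmeasured"))
  expect_true(is.na(sc_m$class))
})

test_that("classification thresholds are exact on hand-built p-values", {
  expect_equal(classify_model(0.01, 0.01), "strong")
  expect_equal(classify_model(0.01, 0.011), "weak")
  expect_equal(classify_model(0.05, 0.05), "weak")
  expect_equal(classify_model(0.05, 0.051), "none")
  expect_equal(classify_model(0.2, 0.001), "none")
  expect_true(is.na(classify_model(NA, 0.01)))
})

test_that("concordant synthetic models classify strong; anticorrelated never do", {
  sim <- gen_human_datasets(n_datasets = 2, n_genes = 1000, n_case = 4,
                            n_control = 4, seed = 2)
  truth <- sim$truth
  om <- gen_orthology(truth)
  sig <- gene_signature(truth$up, truth$down)
  for (i in 1:5) {
    pos <- suppressMessages(map_profile_orthologs(
      gen_animal_model(truth, rho = 1, seed = i), om))
    expect_equal(score_expression(pos, sig, B = 500, seed = i)$class,
                 "strong")
    neg <- suppressMessages(map_profile_orthologs(
      gen_animal_model(truth, rho = -1, seed = i), om))
    expect_equal(score_expression(neg, sig, B = 500, seed = i)$class,
                 "none")
  }
  # rho = 1, sigma_m = 0 reproduces the planted effects exactly
  exact <- gen_animal_model(truth, rho = 1, sigma_m = 0, seed = 1)
  mapped <- suppressMessages(map_profile_orthologs(exact, om))
  expect_equal(unname(mapped$ratios[truth$up]),
               rep(truth$delta, length(truth$up)))
})

test_that("pathway scoring mirrors expression scoring on activities", {
  acts <- setNames(c(rep(2, 5), rep(-2, 5), rnorm(30, 0, 0.1)),
                   sprintf("PW%03d", 1:40))
  sc <- score_pathways(acts, names(acts)[1:5], names(acts)[6:10],
                       B = 200, seed = 1, model = "m1")
  expect_equal(sc$class, "strong")
  zero <- setNames(rep(0, 40), names(acts))
  sc0 <- score_pathways(zero, names(acts)[1:5], names(acts)[6:10],
                        B = 200, seed = 2)
  expect_equal(sc0$p_up, 1)
  expect_equal(sc0$class, "none")
  expect_error(score_pathways(acts[1:3], names(acts)[1], names(acts)[2],
                              B = 200), "fewer than")
})

test_that("DEG selection applies the inclusive 2-fold boundary", {
  r <- c(a = log2(2.5), b = 1, c = log2(1.9), d = -1.2, e = 0)
  degs <- select_degs(log_ratio_profile(r, model = "x"), mode = "fold",
                      threshold = 2)
  expect_setequal(degs$up, c("a", "b"))   # 2.5-fold and exactly 2-fold in
  expect_setequal(degs$down, "d")
  expect_false("c" %in% degs$up)          # 1.9-fold out
  # SAM mode delegates to the two-class machinery
  set.seed(31)
  v <- rand_mat(60, 8)
  v[1:5, 1:4] <- v[1:5, 1:4] + 4
  ds <- make_ds(v, group = rep(c("case", "control"), each = 4))
  degs_sam <- select_degs(ds, mode = "sam", fdr = 0.1, n_perm = 200, seed = 4)
  expect_true(all(rownames(v)[1:5] %in% degs_sam$up))
})

test_that("DEG network adjacency finds planted proximity", {
  sim <- gen_human_datasets(n_datasets = 2, n_genes = 500, n_case = 4,
                            n_control = 4, seed = 6)
  truth <- sim$truth
  net <- gen_network(truth, n_nodes = 500, hub_bias = TRUE, seed = 4)
  pw <- gen_pathways(truth, n_pathways = 15, seed = 5)
  sets <- c(unclass(pw$collection), list(sig_up = truth$up))
  dm <- distance_matrix(net, sets)
  row <- dm$matrix["sig_up", names(pw$collection)]
  ad_adj <- adjacent_pathways(row[is.finite(row)], value = 0.5)
  # the signature itself as "DEGs" reproduces its own selection
  res <- deg_pathway_adjacency(net, truth$up, ad_adj, pw$collection,
                               B = 200, seed = 9, value = 0.5)
  expect_equal(res$ratio, 1)
  expect_lte(res$p, 0.3)
  expect_error(deg_pathway_adjacency(net, truth$up, character(),
                                     pw$collection, B = 200), "empty")
})

test_that("model distance clustering co-locates duplicated models", {
  sim <- gen_human_datasets(n_datasets = 2, n_genes = 400, n_case = 4,
                            n_control = 4, seed = 8)
  truth <- sim$truth
  net <- gen_network(truth, n_nodes = 400, hub_bias = TRUE, seed = 6)
  pw <- gen_pathways(truth, n_pathways = 12, seed = 7)
  set.seed(10)
  nodes <- network_nodes(net)
  m1 <- sample(nodes, 30)
  m2 <- sample(nodes, 30)
  res <- model_distance_clustering(net, list(a = m1, a_dup = m1, b = m2),
                                   pw$collection)
  expect_equal(res$profiles["a", ], res$profiles["a_dup", ])
  ord <- res$order
  expect_equal(abs(which(ord == "a") - which(ord == "a_dup")), 1L)
})

test_that("the report table holds one row per model with per-measure classes", {
  s1 <- list(measure = "expression", model = "m1", tissue = "ctx",
             mean_up = 1, mean_down = -1, p_up = 0.001, p_down = 0.002,
             n_up = 10L, n_down = 10L, class = "strong")
  s2 <- modifyList(s1, list(measure = "pathway", class = "none",
                            p_up = 0.5, p_down = 0.5))
  s3 <- modifyList(s1, list(model = "m2", class = "weak"))
  class(s1) <- class(s2) <- class(s3) <- "model_score"
  rep_tab <- summarize_models(list(s1, s2, s3),
                              network_calls = list("m1 ctx" = "weak"))
  expect_equal(nrow(rep_tab), 2L)
  r1 <- rep_tab[rep_tab$model == "m1", ]
  expect_equal(r1$expression, "strong")
  expect_equal(r1$pathway, "none")
  expect_equal(r1$network, "weak")
  expect_equal(rep_tab[rep_tab$model == "m2", "expression"], "weak")
  expect_equal(rep_tab[rep_tab$model == "m2", "network"], "none")
  # TSV round-trip preserves the table
  dir <- withr::local_tempdir()
  p <- file.path(dir, "report.tsv")
  write.table(rep_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(p, stringsAsFactors = FALSE)
  expect_equal(back, rep_tab)
})
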