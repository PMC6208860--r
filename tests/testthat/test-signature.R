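# Independent oracle for the two-class moderated statistic and its
# permutation q-values, written as plain loops over an explicit
# assignment enumeration.
oracle_sam_two_class <- function(v, labels, s0 = NULL) {
  d_of <- function(z, s0v) {
    apply(v, 1L, function(y) {
      y1 <- y[z == 1]; y2 <- y[z == 0]
      m <- mean(y1) - mean(y2)
      pooled <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) /
        (length(y) - 2)
      s <- sqrt((1 / length(y1) + 1 / length(y2)) * pooled)
      if (s + s0v == 0) 0 else m / (s + s0v)
    })
  }
  z_obs <- as.numeric(labels == "case")
  s_only <- apply(v, 1L, function(y) {
    y1 <- y[z_obs == 1]; y2 <- y[z_obs == 0]
    pooled <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) /
      (length(y) - 2)
    sqrt((1 / length(y1) + 1 / length(y2)) * pooled)
  })
  if (is.null(s0)) s0 <- median(s_only)
  d_obs <- d_of(z_obs, s0)
  combos <- combn(length(labels), sum(z_obs))
  counts <- matrix(0, length(d_obs), ncol(combos))
  for (b in seq_len(ncol(combos))) {
    zb <- numeric(length(labels)); zb[combos[, b]] <- 1
    db <- d_of(zb, s0)
    for (g in seq_along(d_obs))
      counts[g, b] <- sum(abs(db) >= abs(d_obs[g]))
  }
  q <- numeric(length(d_obs))
  for (g in seq_along(d_obs)) {
    den <- sum(abs(d_obs) >= abs(d_obs[g]))
    q[g] <- min(1, median(counts[g, ]) / den)
  }
  ord <- order(abs(d_obs), decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  list(d = unname(d_obs), q = q)
}

test_that("two-class SAM matches an exhaustive enumeration oracle on a 3v3 toy", {
  set.seed(3)
  v <- rand_mat(8, 6)
  v[1, 1:3] <- v[1, 1:3] + 4  # one strongly shifted gene
  v[2, ] <- 5                 # identical in both classes
  labels <- rep(c("case", "control"), each = 3)
  res <- sam_two_class(v, labels, n_perm = 1000, seed = 1)
  oracle <- oracle_sam_two_class(v, labels)
  expect_equal(res$d, oracle$d, tolerance = 1e-12)
  expect_equal(res$q, oracle$q, tolerance = 1e-12)
  expect_equal(res$d[2], 0)
  expect_equal(res$q[2], 1)
  expect_error(sam_two_class(v, c("case", rep("control", 5))), ">= 2 samples")
})

test_that("SAM q-values are monotone in |d| and directions respect the threshold", {
  set.seed(5)
  v <- rand_mat(100, 12)
  v[1:10, 1:6] <- v[1:10, 1:6] + 3
  labels <- rep(c("case", "control"), each = 6)
  res <- sam_two_class(v, labels, n_perm = 300, seed = 2, fdr = 0.05)
  ord <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$direction[res$q >= 0.05] == "none"))
  expect_true(all(res$direction[res$q < 0.05] %in% c("up", "down")))
  expect_true(all(res$d[res$direction == "up"] > 0))
})

test_that("quantitative SAM matches an exhaustive covariate-permutation oracle", {
  set.seed(4)
  n <- 5
  v <- rand_mat(6, n)
  x <- c(60, 65, 72, 80, 88)
  v[1, ] <- 0.1 * x            # exactly linear in the covariate
  v[2, ] <- 7                  # constant gene
  res <- sam_quantitative(v, covariate = x, n_perm = 1000, seed = 1)
  # oracle: all 120 permutations, plain loops
  slope_se <- function(xp, y) {
    fit <- lm(y ~ xp)
    suppressWarnings(c(coef(fit)[2L], summary(fit)$coefficients[2L, 2L]))
  }
  obs <- t(apply(v, 1L, function(y) slope_se(x, y)))
  s0 <- median(obs[, 2L])
  d_obs <- ifelse(obs[, 2L] + s0 > 0, obs[, 1L] / (obs[, 2L] + s0), 0)
  perms <- NULL
  perm_rec <- function(rest, acc) {
    if (!length(rest)) { perms[[length(perms) + 1L]] <<- acc; return() }
    for (r in rest) perm_rec(setdiff(rest, r), c(acc, r))
  }
  perm_rec(seq_len(n), integer())
  counts <- matrix(0, nrow(v), length(perms))
  for (b in seq_along(perms)) {
    db <- apply(v, 1L, function(y) {
      st <- slope_se(x[perms[[b]]], y)
      if (!is.finite(st[2L]) || st[2L] + s0 == 0) 0 else st[1L] / (st[2L] + s0)
    })
    db[!is.finite(db)] <- 0
    counts[, b] <- vapply(abs(d_obs), function(t) sum(abs(db) >= t), numeric(1))
  }
  q <- pmin(1, apply(counts, 1L, median) /
              vapply(abs(d_obs), function(t) sum(abs(d_obs) >= t), numeric(1)))
  ord <- order(abs(d_obs), decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  expect_equal(res$d, unname(d_obs), tolerance = 1e-5)
  expect_equal(res$q, unname(q), tolerance = 1e-5)
  expect_equal(res$d[2], 0)
  expect_equal(which.max(abs(res$d)), 1L)  # noise-free linear gene leads
  expect_error(sam_quantitative(v, covariate = rep(70, n)), "constant")
})

test_that("cross-dataset commonality counts directions separately", {
  mk <- function(genes, d, q, dataset) {
    structure(data.frame(gene = genes, d = d, q = q,
                         direction = ifelse(q < 0.01,
                                            ifelse(d > 0, "up", "down"),
                                            "none")),
              dataset = dataset, class = c("sam_result", "data.frame"))
  }
  r1 <- mk(c("A", "B", "C"), c(2, 2, 2), c(0.005, 0.005, 0.5), "d1")
  r2 <- mk(c("A", "B", "C"), c(2, -2, 2), c(0.5, 0.005, 0.005), "d2")
  r3 <- mk(c("A", "B", "C"), c(2, 2, 2), c(0.005, 0.5, 0.5), "d3")
  up <- select_common(list(r1, r2, r3), fdr = 0.01, min_datasets = 2,
                      direction = "up")
  # A: up in d1 and d3 -> selected; B: up in d1 but down in d2 -> excluded;
  # C: up in only d2 -> not selected
  expect_equal(as.character(up), "A")
  expect_equal(attr(up, "provenance")$A, c("d1", "d3"))
  down <- select_common(list(r1, r2, r3), fdr = 0.01, min_datasets = 2,
                        direction = "down")
  expect_equal(length(down), 0L)
})

test_that("signature refinement subtracts age genes with exact accounting", {
  out <- refine_signature(c("A", "B", "C"), c("D", "E"), c("B"), character())
  expect_setequal(out$signature$up, c("A", "C"))
  expect_equal(out$accounting["up", "common"], 1)
  expect_equal(out$accounting["up", "percent_display"], 33.3)
  # disjoint inputs pass through with zero percentages
  out2 <- refine_signature(c("A"), c("B"), c("X"), c("Y"))
  expect_equal(out2$accounting$percent_common, c(0, 0))
  # refined sets are always disjoint from the age sets
  set.seed(8)
  for (i in 1:10) {
    pool <- sprintf("g%02d", 1:40)
    ad_u <- sample(pool, 10); ad_d <- sample(setdiff(pool, ad_u), 10)
    ag_u <- sample(pool, 8); ag_d <- sample(pool, 8)
    r <- refine_signature(ad_u, ad_d, ag_u, ag_d)
    expect_length(intersect(c(r$signature$up, r$signature$down),
                            union(ag_u, ag_d)), 0)
  }
  expect_warning(refine_signature(c("A"), character(), c("A"), character()),
                 "empty")
})

test_that("published Venn pairs reproduce their printed percentages", {
  expect_equal(venn_percent(282, 748)$percent_display, 27.3)
  expect_equal(venn_percent(795, 844)$percent_display, 48.5)
})

test_that("orthology mapping drops unmapped symbols and counts them", {
  om <- orthology_map(c("App", "Mapt", "Psen1"), c("APP", "MAPT", "PSEN1"))
  m <- map_orthologs(c("App", "Mapt"), om)
  expect_setequal(m, c("APP", "MAPT"))
  m2 <- map_orthologs(c("App", "Nope"), om)
  expect_equal(attr(m2, "dropped"), 1L)
  expect_length(map_orthologs(character(), om), 0)
  inv <- map_orthologs(c("APP"), om, invert = TRUE)
  expect_equal(as.character(inv), "App")
  sig <- gene_signature(c("App"), c("Mapt"))
  msig <- map_orthologs(sig, om)
  expect_equal(msig$up, "APP")
})

test_that("null data yield about the nominal rate of q < 0.01 calls", {
  # global-null calibration: expected selections at q < 0.01 stay below 1%
  rates <- vapply(1:20, function(i) {
    v <- rand_mat(200, 12, seed = 100 + i)
    res <- sam_two_class(v, rep(c("case", "control"), each = 6),
                         n_perm = 200, seed = i)
    mean(res$q < 0.01)
  }, numeric(1))
  expect_lte(mean(rates), 0.01)
})
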