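# Seeded generators for every input the pipeline consumes, with a
# ground-truth sidecar. Defaults emulate the multi-cohort case/control
# study design: several human datasets sharing planted up/down disease
# genes and age-linear genes with dataset-specific batch effects; pooled
# animal-model log-ratio profiles with tunable concordance; a scale-free
# interaction network with optional hub bias for planted up-genes;
# pathway collections with repressor roles; promoters with planted
# motifs.

synthetic_gene_names <- function(n) sprintf("GENE%04d", seq_len(n))
rodent_symbol <- function(human)
  paste0(substr(human, 1L, 1L), tolower(substring(human, 2L)))

#' Generate synthetic human case/control datasets with known truth
#'
#' Log2 values are gene baseline + disease effect (delta, signed, cases
#' only, each planted gene active in a random subset of at least
#' `min_active_datasets` datasets) + age slope times (age - 70) for
#' planted age genes + a dataset-specific per-gene batch offset +
#' Gaussian noise. Ages are uniform on 55-95 so a 65-year cutoff is
#' exercised; sexes are balanced. The background matrix is set so that
#' roughly `frac_background_fail` of genes fail the 1.4-fold filter.
#'
#' @param n_datasets number of cohorts (default 4).
#' @param n_genes gene universe size (default 2000).
#' @param n_case,n_control samples per cohort (default 30 each, a
#'   several-fold scale-down of the public cohorts emulated).
#' @param delta planted two-class effect in within-group SD units
#'   (default 1.5).
#' @param n_disease planted disease genes, half up / half down
#'   (default 100).
#' @param n_age planted age-linear genes, half positive / half negative
#'   slope (default 100).
#' @param age_slope log2 units per year (default 0.02).
#' @param overlap_frac fraction of disease genes also given an age slope
#'   (default 0).
#' @param sigma noise SD in log2 units (default 1).
#' @param batch_sd SD of per-gene per-dataset offsets (default 0.5).
#' @param baseline_mean,baseline_sd gene baseline distribution
#'   (defaults 8, 1).
#' @param frac_background_fail fraction of genes planted to fail the
#'   1.4-fold background filter (default 0.05).
#' @param min_active_datasets minimum cohorts in which each planted
#'   disease gene is active (default 2).
#' @param seed integer master seed.
#' @return List with `datasets` (named list of [expression_dataset()])
#'   and `truth` (class `synthetic_truth`): planted sets, per-gene
#'   effects, slopes, batch offsets, seed.
#' @export
gen_human_datasets <- function(n_datasets = 4L, n_genes = 2000L,
                               n_case = 30L, n_control = 30L,
                               delta = 1.5, n_disease = 100L, n_age = 100L,
                               age_slope = 0.02, overlap_frac = 0,
                               sigma = 1, batch_sd = 0.5,
                               baseline_mean = 8, baseline_sd = 1,
                               frac_background_fail = 0.05,
                               min_active_datasets = 2L, seed = 1L) {
  stopifnot(n_datasets >= 2L, n_genes > n_disease + n_age,
            n_case >= 2L, n_control >= 2L, delta >= 0,
            overlap_frac >= 0, overlap_frac <= 1,
            min_active_datasets <= n_datasets)
  set.seed(substream_seed(seed, "human"))
  genes <- synthetic_gene_names(n_genes)
  up <- genes[seq_len(n_disease %/% 2L)]
  down <- genes[n_disease %/% 2L + seq_len(n_disease - n_disease %/% 2L)]
  n_overlap <- round(overlap_frac * n_disease)
  age_pool <- c(sample(c(up, down), n_overlap),
                genes[n_disease + seq_len(n_age - n_overlap)])
  age_up <- age_pool[seq_len(length(age_pool) %/% 2L)]
  age_down <- setdiff(age_pool, age_up)

  effect <- setNames(numeric(n_genes), genes)
  effect[up] <- delta
  effect[down] <- -delta
  slope <- setNames(numeric(n_genes), genes)
  slope[age_up] <- age_slope
  slope[age_down] <- -age_slope
  baseline <- setNames(rnorm(n_genes, baseline_mean, baseline_sd), genes)

  # which datasets each planted disease gene is active in
  active <- matrix(FALSE, n_genes, n_datasets,
                   dimnames = list(genes, NULL))
  k_choices <- min_active_datasets:n_datasets
  for (g in c(up, down)) {
    k <- if (length(k_choices) == 1L) k_choices else sample(k_choices, 1L)
    active[g, sample.int(n_datasets, k)] <- TRUE
  }

  fail_bg <- sample(genes, round(frac_background_fail * n_genes))
  batch_offsets <- matrix(rnorm(n_genes * n_datasets, 0, batch_sd),
                          n_genes, n_datasets,
                          dimnames = list(genes, NULL))

  datasets <- vector("list", n_datasets)
  labels <- paste0("adset", seq_len(n_datasets))
  for (dset in seq_len(n_datasets)) {
    n <- n_case + n_control
    group <- rep(c("case", "control"), c(n_case, n_control))
    age <- round(runif(n, 55, 95), 1)
    sex <- rep_len(c("M", "F"), n)
    ids <- sprintf("s%02d", seq_len(n))
    vals <- matrix(rnorm(n_genes * n, 0, sigma), n_genes, n,
                   dimnames = list(genes, ids))
    vals <- vals + baseline + batch_offsets[, dset]
    case_idx <- which(group == "case")
    act <- active[, dset]
    vals[act, case_idx] <- vals[act, case_idx] + effect[act]
    vals <- vals + outer(slope, age - 70)
    ratio <- ifelse(genes %in% fail_bg, 1.2, 2.0)
    background <- 2^vals / ratio
    meta <- data.frame(group = group, age = age, sex = sex,
                       batch = labels[dset], row.names = ids)
    datasets[[dset]] <- expression_dataset(vals, meta, background = background)
  }
  names(datasets) <- labels
  truth <- structure(list(
    genes = genes, up = up, down = down,
    age_up = age_up, age_down = age_down,
    effect = effect, slope = slope,
    active = active, fail_background = fail_bg,
    batch_offsets = batch_offsets,
    delta = delta, sigma = sigma, seed = seed), class = "synthetic_truth")
  list(datasets = datasets, truth = truth)
}

#' Generate an animal-model log-ratio profile with tunable concordance
#'
#' Per measured gene,
#' `ratio = rho * planted_effect + sqrt(1 - rho^2) * Normal(0, sigma_m)`,
#' emitted under rodent symbols via the generated orthology map
#' ([gen_orthology()]).
#'
#' @param truth a `synthetic_truth` from [gen_human_datasets()].
#' @param rho concordance with the planted human effects, in `[-1, 1]`.
#' @param n_genes_measured measured universe size (default 1500; the
#'   planted disease genes are always included).
#' @param sigma_m discordant-noise SD (default 0.3).
#' @param seed integer seed.
#' @param model,tissue labels.
#' @return A [log_ratio_profile()] keyed by rodent symbols.
#' @export
gen_animal_model <- function(truth, rho, n_genes_measured = 1500L,
                             sigma_m = 0.3, seed = 1L,
                             model = "synthetic", tissue = "brain") {
  stopifnot(rho >= -1, rho <= 1)
  set.seed(substream_seed(seed, "animal"))
  planted <- c(truth$up, truth$down)
  rest <- setdiff(truth$genes, planted)
  measured <- c(planted,
                sample(rest, min(length(rest),
                                 max(0L, n_genes_measured - length(planted)))))
  ratios <- rho * truth$effect[measured] +
    sqrt(1 - rho^2) * rnorm(length(measured), 0, sigma_m)
  names(ratios) <- rodent_symbol(measured)
  log_ratio_profile(ratios, model = model, tissue = tissue)
}

#' Orthology map for the synthetic gene universe
#'
#' @param truth a `synthetic_truth`.
#' @return An [orthology_map()] from rodent-style symbols to the human
#'   symbols of the synthetic universe.
#' @export
gen_orthology <- function(truth) {
  orthology_map(rodent_symbol(truth$genes), truth$genes)
}

#' Generate a scale-free interaction network over the synthetic genes
#'
#' Preferential-attachment growth; with `hub_bias` the planted up-genes
#' are assigned to high-degree nodes with probability proportional to
#' degree squared (rank-weighted relabeling), reproducing a
#' hub-enriched up-signature.
#'
#' @param truth a `synthetic_truth`.
#' @param n_nodes network size (default 1000; must not exceed the gene
#'   universe).
#' @param m_attach edges added per new node (default 2).
#' @param hub_bias relabel planted up-genes onto hubs (default `FALSE`).
#' @param seed integer seed.
#' @return A [ppi_network()] whose nodes are gene symbols (every edge
#'   tagged `low` throughput).
#' @export
gen_network <- function(truth, n_nodes = 1000L, m_attach = 2L,
                        hub_bias = FALSE, seed = 1L) {
  stopifnot(m_attach >= 1L)
  if (n_nodes <= m_attach) stop("n_nodes must exceed m_attach")
  if (n_nodes > length(truth$genes))
    stop("n_nodes exceeds the synthetic gene universe")
  set.seed(substream_seed(seed, "network"))
  g <- igraph::sample_pa(n_nodes, m = m_attach, directed = FALSE)
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  planted <- intersect(c(truth$up, truth$down), truth$genes)
  others <- setdiff(truth$genes, planted)
  labels <- character(n_nodes)
  node_ids <- seq_len(n_nodes)
  if (hub_bias) {
    w <- deg^2
    up_nodes <- sample(node_ids, length(truth$up), prob = w)
    labels[up_nodes] <- truth$up
    remaining <- setdiff(node_ids, up_nodes)
    down_nodes <- sample(remaining, length(truth$down))
    labels[down_nodes] <- truth$down
    rest_nodes <- setdiff(remaining, down_nodes)
    labels[rest_nodes] <- sample(others, length(rest_nodes))
  } else {
    labels <- sample(truth$genes, n_nodes)
  }
  igraph::V(g)$name <- labels
  edges <- igraph::as_edgelist(g)
  ppi_network(data.frame(a = edges[, 1L], b = edges[, 2L],
                         throughput = "low"))
}

#' Generate a pathway collection with roles and planted disease pathways
#'
#' Random member draws from the synthetic universe; `n_planted_up`
#' pathways are seeded so that at least half their members are planted
#' up-genes (likewise down). Repressor roles are assigned at
#' `frac_repressor` among non-planted members.
#'
#' @param truth a `synthetic_truth`.
#' @param n_pathways number of pathways (default 30).
#' @param size_range member count range (default `c(10, 40)`,
#'   minimum 3).
#' @param frac_repressor fraction of (non-planted) members annotated as
#'   repressors (default 0).
#' @param n_planted_up,n_planted_down pathways seeded with planted
#'   up/down genes (defaults 2 each).
#' @param seed integer seed.
#' @return List with `collection` (a [gene_set_collection()]), `roles`
#'   (a [role_map()]), `planted_up`, `planted_down` (pathway names).
#' @export
gen_pathways <- function(truth, n_pathways = 30L, size_range = c(10L, 40L),
                         frac_repressor = 0, n_planted_up = 2L,
                         n_planted_down = 2L, seed = 1L) {
  stopifnot(size_range[1L] >= 3L, n_pathways >= n_planted_up + n_planted_down)
  set.seed(substream_seed(seed, "pathways"))
  nms <- sprintf("PW%03d", seq_len(n_pathways))
  planted_up <- nms[seq_len(n_planted_up)]
  planted_down <- nms[n_planted_up + seq_len(n_planted_down)]
  sets <- list(); roles_df <- list()
  for (i in seq_len(n_pathways)) {
    sz <- sample(size_range[1L]:size_range[2L], 1L)
    nm <- nms[i]
    if (nm %in% planted_up) {
      n_pl <- ceiling(sz / 2)
      members <- c(sample(truth$up, min(n_pl, length(truth$up))),
                   sample(setdiff(truth$genes, truth$up), sz - min(n_pl, length(truth$up))))
    } else if (nm %in% planted_down) {
      n_pl <- ceiling(sz / 2)
      members <- c(sample(truth$down, min(n_pl, length(truth$down))),
                   sample(setdiff(truth$genes, truth$down), sz - min(n_pl, length(truth$down))))
    } else {
      members <- sample(truth$genes, sz)
    }
    sets[[nm]] <- members
    if (frac_repressor > 0) {
      eligible <- setdiff(members, c(truth$up, truth$down))
      n_rep <- round(frac_repressor * length(eligible))
      if (n_rep > 0)
        roles_df[[nm]] <- data.frame(set = nm,
                                     gene = sample(eligible, n_rep),
                                     role = "repressor")
    }
  }
  roles <- if (length(roles_df)) role_map(do.call(rbind, roles_df)) else role_map()
  list(collection = gene_set_collection(sets), roles = roles,
       planted_up = planted_up, planted_down = planted_down)
}

#' Generate promoters with class-specific planted motifs
#'
#' Promoters are i.i.d. uniform-base sequences of the given length; each
#' gene belongs to one of two motif classes and receives
#' `planting_rate` non-overlapping copies of each of its class's
#' consensus motifs at random positions. The returned PWM set holds one
#' near-deterministic matrix per motif.
#'
#' @param genes character vector of gene symbols.
#' @param classes integer (1/2) class per gene (default: first half
#'   class 1).
#' @param length promoter length in bases (default 2501, a
#'   (-2000, +500] TSS window).
#' @param motifs list of two character vectors of consensus motifs, one
#'   vector per class (default three distinct 8-mers per class, as
#'   co-regulated promoter classes share several binding sites).
#' @param planting_rate copies of each class motif planted per promoter
#'   (default 3).
#' @param seed integer seed.
#' @return List with `promoters` (named character vector), `pwms` (a
#'   [pwm_set()], one per motif), `classes`.
#' @export
gen_promoters <- function(genes,
                          classes = rep(1:2, length.out = length(genes)),
                          length = 2501L,
                          motifs = list(c("TGACGTCA", "GGGCGGAA", "TTCCAGGA"),
                                        c("GGCCAATC", "CACGTGAC", "AATTGCGC")),
                          planting_rate = 3L, seed = 1L) {
  if (is.character(motifs)) motifs <- as.list(motifs)
  stopifnot(base::length(motifs) == 2L,
            all(nchar(unlist(motifs)) < length),
            base::length(classes) == base::length(genes))
  set.seed(substream_seed(seed, "promoters"))
  bases <- c("A", "C", "G", "T")
  promoters <- setNames(character(base::length(genes)), genes)
  for (i in seq_along(genes)) {
    seq_chars <- sample(bases, length, replace = TRUE)
    class_motifs <- motifs[[classes[i]]]
    if (planting_rate > 0) {
      occupied <- logical(length)
      for (motif in class_motifs) {
        L <- nchar(motif)
        planted <- 0L
        while (planted < planting_rate) {
          s <- sample.int(length - L + 1L, 1L)
          span <- s:(s + L - 1L)
          if (any(occupied[span])) next
          seq_chars[span] <- strsplit(motif, "")[[1L]]
          occupied[span] <- TRUE
          planted <- planted + 1L
        }
      }
    }
    promoters[i] <- paste(seq_chars, collapse = "")
  }
  make_pwm <- function(motif) {
    chars <- strsplit(motif, "")[[1L]]
    m <- matrix(1, 4L, base::length(chars),
                dimnames = list(bases, NULL))
    for (j in seq_along(chars)) m[chars[j], j] <- 97
    m
  }
  all_motifs <- unlist(motifs)
  motif_class <- rep(1:2, lengths(motifs))
  pwms <- pwm_set(setNames(lapply(all_motifs, make_pwm),
                           sprintf("TF_c%d_%d", motif_class,
                                   unlist(lapply(lengths(motifs), seq_len)))))
  list(promoters = promoters, pwms = pwms,
       classes = setNames(classes, genes))
}

#' Write the ground-truth sidecar of a synthetic run
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(up = truth$up, down = truth$down,
         age_up = truth$age_up, age_down = truth$age_down,
         fail_background = truth$fail_background,
         delta = truth$delta, sigma = truth$sigma, seed = truth$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
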