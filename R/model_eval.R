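# Scoring animal-model expression profiles against the human signature
# by signature-gene expression, pathway activity and network distance,
# with strong/weak/none classification.

#' Log-ratio profile of a model versus matched control
#'
#' Per gene, mean model log2 intensity minus mean control log2
#' intensity, restricted to the shared gene universe (and to genes
#' passing the background filter in both datasets when backgrounds are
#' present). Rodent symbols are optionally mapped to human orthologs
#' (unmapped genes dropped, duplicates collapsing by mean).
#'
#' @param model_ds,control_ds [expression_dataset()]s.
#' @param orthology optional [orthology_map()] applied to the result.
#' @param background_factor fold threshold for the background filter
#'   (default 1.4; applied only when backgrounds are present).
#' @param min_universe minimum shared universe size (default 100).
#' @param model,tissue labels for the profile.
#' @return A [log_ratio_profile()].
#' @export
model_log_ratios <- function(model_ds, control_ds, orthology = NULL,
                             background_factor = 1.4, min_universe = 100L,
                             model = "model", tissue = "") {
  if (!is.null(model_ds$background))
    model_ds <- filter_background(model_ds, background_factor)
  if (!is.null(control_ds$background))
    control_ds <- filter_background(control_ds, background_factor)
  shared <- intersect(rownames(model_ds$values), rownames(control_ds$values))
  if (!length(shared)) stop("empty shared gene universe")
  if (length(shared) < min_universe)
    warning("shared universe has only ", length(shared), " genes")
  ratios <- rowMeans(model_ds$values[shared, , drop = FALSE]) -
    rowMeans(control_ds$values[shared, , drop = FALSE])
  if (!is.null(orthology)) {
    hit <- names(ratios) %in% names(orthology)
    if (any(!hit))
      message(sum(!hit), " gene(s) without a human ortholog dropped")
    ratios <- ratios[hit]
    human <- unname(orthology[names(ratios)])
    ratios <- vapply(split(ratios, human), mean, numeric(1))
  }
  log_ratio_profile(ratios, model = model, tissue = tissue)
}

#' Map a log-ratio profile to human symbols
#'
#' Renames the genes of a [log_ratio_profile()] through an
#' [orthology_map()]; unmapped genes are dropped (counted in a message)
#' and rodent genes sharing one human ortholog collapse by mean.
#'
#' @param profile a [log_ratio_profile()] keyed by rodent symbols.
#' @param om an [orthology_map()].
#' @return A [log_ratio_profile()] keyed by human symbols.
#' @export
map_profile_orthologs <- function(profile, om) {
  r <- profile$ratios
  hit <- names(r) %in% names(om)
  if (any(!hit))
    message(sum(!hit), " gene(s) without a human ortholog dropped")
  r <- r[hit]
  human <- unname(om[names(r)])
  r <- vapply(split(r, human), mean, numeric(1))
  log_ratio_profile(r, model = profile$model, tissue = profile$tissue)
}

# Null distribution of means of random gene sets of a given size.
null_set_means <- function(values, size, B) {
  n <- length(values)
  vapply(seq_len(B), function(b) mean(values[sample.int(n, size)]),
         numeric(1))
}

#' Score a model profile against the human signature by expression
#'
#' The observed statistics are the mean log2 ratio over mapped up-genes
#' and mapped down-genes. The null draws `B` equal-sized random gene
#' sets from the profile universe; `p_up` is the proportion of draws
#' with mean at least the observed up-mean, `p_down` the proportion
#' with mean at most the observed down-mean (one-sided in the expected
#' direction per sign). Classification: both p <= 0.01 is strong,
#' both p <= 0.05 weak, otherwise none.
#'
#' @param profile a [log_ratio_profile()].
#' @param sig a [gene_signature()] (human symbols; map the profile with
#'   an orthology first).
#' @param B number of null draws (default 1000; < 100 warns).
#' @param seed integer seed.
#' @param alpha_strong,alpha_weak classification thresholds.
#' @param min_fraction minimum fraction of each direction that must be
#'   measured (default 0.2; logged when violated).
#' @return A `model_score` (measure `"expression"`).
#' @export
score_expression <- function(profile, sig, B = 1000L, seed = 1L,
                             alpha_strong = 0.01, alpha_weak = 0.05,
                             min_fraction = 0.2) {
  if (B < 100L) warning("B < 100 gives unstable p-values")
  r <- profile$ratios
  up <- intersect(sig$up, names(r))
  down <- intersect(sig$down, names(r))
  if (length(up) < min_fraction * length(sig$up) ||
      length(down) < min_fraction * length(sig$down))
    message("signature coverage below ", min_fraction,
            " of a direction in the model universe")
  if (!length(up) || !length(down)) {
    warning("a signature direction is entirely unmeasured; class undefined")
    return(model_score("expression", profile$model, profile$tissue,
                       if (length(up)) mean(r[up]) else NA_real_,
                       if (length(down)) mean(r[down]) else NA_real_,
                       NA_real_, NA_real_, alpha_strong, alpha_weak,
                       length(up), length(down)))
  }
  mean_up <- mean(r[up]); mean_down <- mean(r[down])
  set.seed(seed)
  null_up <- null_set_means(r, length(up), B)
  null_down <- null_set_means(r, length(down), B)
  p_up <- mean(null_up >= mean_up)
  p_down <- mean(null_down <= mean_down)
  model_score("expression", profile$model, profile$tissue,
              mean_up, mean_down, p_up, p_down, alpha_strong, alpha_weak,
              length(up), length(down))
}

#' Score a model by pathway-activity concordance
#'
#' The observed statistics are the model's mean activity over the
#' human-up pathways and over the human-down pathways; the null
#' resamples equal-sized pathway sets from all pathways measured in the
#' model. p-values and classification follow [score_expression()].
#'
#' @param model_activity named numeric vector of the model's pathway
#'   activities.
#' @param human_up,human_down names of human differentially activated
#'   pathways per direction.
#' @param B number of draws (default 1000).
#' @param seed integer seed.
#' @param alpha_strong,alpha_weak classification thresholds.
#' @param min_pathways minimum measurable human pathways (default 5).
#' @param model,tissue labels.
#' @return A `model_score` (measure `"pathway"`).
#' @export
score_pathways <- function(model_activity, human_up, human_down,
                           B = 1000L, seed = 1L,
                           alpha_strong = 0.01, alpha_weak = 0.05,
                           min_pathways = 5L, model = "model", tissue = "") {
  model_activity <- model_activity[is.finite(model_activity)]
  up <- intersect(human_up, names(model_activity))
  down <- intersect(human_down, names(model_activity))
  if (length(up) + length(down) < min_pathways)
    stop("fewer than ", min_pathways,
         " human differential pathways measurable in the model")
  mean_up <- mean(model_activity[up]); mean_down <- mean(model_activity[down])
  set.seed(seed)
  null_up <- null_set_means(model_activity, length(up), B)
  null_down <- null_set_means(model_activity, length(down), B)
  p_up <- mean(null_up >= mean_up)
  p_down <- mean(null_down <= mean_down)
  model_score("pathway", model, tissue, mean_up, mean_down, p_up, p_down,
              alpha_strong, alpha_weak, length(up), length(down))
}

#' Select differentially expressed genes of a model
#'
#' Fold mode keeps genes with `|log2 ratio| >= log2(threshold)`
#' (inclusive boundary); SAM mode delegates to [sam_two_class()] on a
#' case/control dataset at the given FDR.
#'
#' @param x a [log_ratio_profile()] (fold mode) or an
#'   [expression_dataset()] (sam mode).
#' @param mode `"fold"` or `"sam"`.
#' @param threshold linear fold threshold (default 2).
#' @param fdr SAM q-value threshold (default 0.1).
#' @param n_perm,seed SAM permutation controls.
#' @return List with `up` and `down` symbol sets.
#' @export
select_degs <- function(x, mode = c("fold", "sam"), threshold = 2,
                        fdr = 0.1, n_perm = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "fold") {
    stopifnot(inherits(x, "log_ratio_profile"))
    cut <- log2(threshold)
    r <- x$ratios
    list(up = names(r)[r >= cut], down = names(r)[r <= -cut])
  } else {
    stopifnot(inherits(x, "expression_dataset"))
    res <- sam_two_class(x, n_perm = n_perm, seed = seed, fdr = fdr)
    list(up = res$gene[res$direction == "up"],
         down = res$gene[res$direction == "down"])
  }
}

#' DEG-adjacent versus signature-adjacent pathway overlap
#'
#' Computes the DEG set's adjacent-pathway selection (same threshold
#' mode as the signature's), then the ratio
#' `|DEG-adjacent n AD-adjacent| / |AD-adjacent|`, with a permutation p
#' from `B` equal-sized random gene sets drawn from the network.
#'
#' @param net a [ppi_network()].
#' @param degs character vector of model DEG symbols.
#' @param ad_adjacent character vector of signature-adjacent pathway
#'   names.
#' @param pathways a [gene_set_collection()] of all pathways.
#' @param B permutation draws (default 1000).
#' @param seed integer seed.
#' @param threshold_mode,value see [adjacent_pathways()].
#' @param coverage_min see [set_distance()].
#' @return List with `ratio`, `p`, `deg_adjacent`, `null` (numeric
#'   vector of null ratios).
#' @export
deg_pathway_adjacency <- function(net, degs, ad_adjacent, pathways,
                                  B = 1000L, seed = 1L,
                                  threshold_mode = "percentile",
                                  value = 0.9, coverage_min = 0.5) {
  if (!length(ad_adjacent)) stop("empty signature-adjacent pathway set")
  nodes <- network_nodes(net)
  mapped <- intersect(unique(degs), nodes)
  if (length(mapped) / length(unique(degs)) <= coverage_min)
    stop("DEG set fails network coverage")
  path_nodes <- lapply(pathways, function(s) intersect(unique(s), nodes))
  path_nodes <- path_nodes[lengths(path_nodes) > 0L]
  all_path_genes <- unique(unlist(path_nodes))
  Dfull <- igraph::distances(net$graph, to = all_path_genes)
  set_to_pathways <- function(members) {
    vapply(path_nodes, function(pn) {
      d <- as.vector(Dfull[members, pn, drop = FALSE])
      d <- d[is.finite(d)]
      if (length(d)) mean(d) else NA_real_
    }, numeric(1))
  }
  obs_sel <- adjacent_pathways(set_to_pathways(mapped),
                               threshold_mode = threshold_mode, value = value)
  ratio <- length(intersect(obs_sel, ad_adjacent)) / length(ad_adjacent)
  set.seed(seed)
  null <- vapply(seq_len(B), function(b) {
    draw <- sample(nodes, length(mapped))
    sel <- suppressWarnings(
      adjacent_pathways(set_to_pathways(draw),
                        threshold_mode = threshold_mode, value = value))
    length(intersect(sel, ad_adjacent)) / length(ad_adjacent)
  }, numeric(1))
  list(ratio = ratio, p = mean(null >= ratio), deg_adjacent = obs_sel,
       null = null)
}

#' Cluster models by their network distance profiles
#'
#' Each gene set (model DEG sets plus signature sets) is summarized by
#' its vector of mean shortest-path distances to the pathways; sets are
#' then clustered by average linkage on `1 - Pearson` correlation of
#' those profiles.
#'
#' @param net a [ppi_network()].
#' @param sets named list of gene-symbol sets (>= 3 passing coverage).
#' @param pathways a [gene_set_collection()].
#' @param coverage_min see [set_distance()].
#' @return List with `profiles` (sets x pathways distance matrix),
#'   `hclust`, `order` (labels in display order), `dropped`.
#' @export
model_distance_clustering <- function(net, sets, pathways,
                                      coverage_min = 0.5) {
  nodes <- network_nodes(net)
  cov <- vapply(sets, function(s)
    length(intersect(unique(s), nodes)) / length(unique(s)), numeric(1))
  dropped <- names(sets)[cov <= coverage_min]
  sets <- sets[cov > coverage_min]
  if (length(sets) < 3L) stop("fewer than 3 sets pass coverage")
  path_nodes <- lapply(pathways, function(s) intersect(unique(s), nodes))
  path_nodes <- path_nodes[lengths(path_nodes) > 0L]
  profiles <- t(vapply(sets, function(s) {
    m <- intersect(unique(s), nodes)
    D <- igraph::distances(net$graph, v = m)
    vapply(path_nodes, function(pn) {
      d <- as.vector(D[, pn, drop = FALSE])
      d <- d[is.finite(d)]
      if (length(d)) mean(d) else NA_real_
    }, numeric(1))
  }, numeric(length(path_nodes))))
  cc <- suppressWarnings(cor(t(profiles), use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "average")
  list(profiles = profiles, hclust = hc,
       order = rownames(profiles)[hc$order], dropped = dropped)
}

#' Summarize model scores into a report table
#'
#' One row per model/tissue with the strong/weak/none class for each
#' measure (expression, pathway, network).
#'
#' @param scores list of `model_score` objects.
#' @param network_calls optional named list/vector of network-measure
#'   classes per `model tissue` key.
#' @return data.frame with columns `model`, `tissue`, `expression`,
#'   `pathway`, `network`.
#' @export
summarize_models <- function(scores, network_calls = NULL) {
  stopifnot(length(scores) >= 1L)
  keys <- unique(vapply(scores, function(s)
    paste(s$model, s$tissue, sep = "\r"), character(1)))
  out <- data.frame(
    model = vapply(strsplit(keys, "\r"), `[`, character(1), 1L),
    tissue = vapply(strsplit(keys, "\r"), function(x)
      if (length(x) > 1L) x[2L] else "", character(1)),
    expression = "none", pathway = "none", network = "none",
    stringsAsFactors = FALSE)
  rownames(out) <- keys
  for (s in scores) {
    key <- paste(s$model, s$tissue, sep = "\r")
    if (s$measure %in% c("expression", "pathway") && !is.na(s$class))
      out[key, s$measure] <- s$class
  }
  if (!is.null(network_calls)) {
    for (nm in names(network_calls)) {
      key <- sub(" ", "\r", nm)
      if (key %in% rownames(out)) out[key, "network"] <- network_calls[[nm]]
    }
  }
  rownames(out) <- NULL
  out
}
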