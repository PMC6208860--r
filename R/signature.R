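# SAM-style gene selection with permutation FDR, cross-dataset
# commonality, and construction of the final disease signature by
# subtracting age-associated genes.

# Moderated two-class statistics for one labeling. `z` is the 0/1 case
# indicator. Returns list(d, s) given a fixed fudge factor s0 (NULL ->
# compute s only).
sam_stats_two_class <- function(v, z, s0 = 0) {
  n1 <- sum(z); n2 <- sum(1 - z); n <- n1 + n2
  sum1 <- v %*% z; sum2 <- v %*% (1 - z)
  m1 <- sum1 / n1; m2 <- sum2 / n2
  sq <- v^2
  ss1 <- sq %*% z - n1 * m1^2
  ss2 <- sq %*% (1 - z) - n2 * m2^2
  pooled <- pmax(ss1 + ss2, 0) / (n - 2)
  s <- sqrt((1 / n1 + 1 / n2) * pooled)
  denom <- s + s0
  d <- ifelse(denom > 0, (m1 - m2) / denom, 0)
  list(d = as.vector(d), s = as.vector(s))
}

# Permutation q-values from observed |d| and a genes x n_perm null
# matrix: q(d*) = median_b #{|d_b| >= |d*|} / #{|d_obs| >= |d*|},
# clipped to [0, 1] and made monotone non-increasing in |d|.
sam_qvalues <- function(d_obs, d_perm) {
  a_obs <- abs(d_obs)
  n_genes <- length(a_obs)
  sorted_obs <- sort(a_obs)
  den <- n_genes - findInterval(a_obs, sorted_obs, left.open = TRUE)
  counts <- matrix(0, n_genes, ncol(d_perm))
  for (b in seq_len(ncol(d_perm))) {
    sp <- sort(abs(d_perm[, b]))
    counts[, b] <- n_genes - findInterval(a_obs, sp, left.open = TRUE)
  }
  num <- apply(counts, 1L, median)
  q <- pmin(pmax(num / den, 0), 1)
  ord <- order(a_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  q
}

sam_result <- function(genes, d, q, fdr, dataset, response) {
  direction <- rep("none", length(d))
  direction[q < fdr & d > 0] <- "up"
  direction[q < fdr & d < 0] <- "down"
  structure(data.frame(gene = genes, d = d, q = q, direction = direction,
                       stringsAsFactors = FALSE),
            dataset = dataset, response = response, fdr = fdr,
            class = c("sam_result", "data.frame"))
}

#' Two-class SAM selection with permutation FDR
#'
#' Per gene, the moderated statistic is
#' `d = (mean_case - mean_control) / (s + s0)` where `s` is the pooled
#' standard error and `s0` the median of all gene-wise `s` (the fudge
#' factor). The permutation null shuffles class labels; when the exact
#' assignment space (`choose(n, n_case)`) is no larger than `n_perm` it
#' is enumerated exhaustively. q-values are
#' `median_b #\{|d_b| >= |d*|\} / #\{|d_obs| >= |d*|\}`, clipped to
#' `[0, 1]` and made monotone.
#'
#' @param ds an [expression_dataset()] (groups define the classes) or a
#'   numeric matrix.
#' @param labels optional case/control labels when `ds` is a matrix.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @param fdr threshold used to fill the direction column (default 0.01).
#' @param s0 optional fixed fudge factor; default median of gene-wise
#'   standard errors.
#' @return A `sam_result` data.frame with columns `gene`, `d`, `q`,
#'   `direction`.
#' @export
sam_two_class <- function(ds, labels = NULL, n_perm = 1000L, seed = 1L,
                          fdr = 0.01, s0 = NULL) {
  if (inherits(ds, "expression_dataset")) {
    v <- ds$values
    labels <- ds$meta$group
    dataset <- ds$meta$batch[1L]
  } else {
    v <- as.matrix(ds)
    dataset <- "matrix"
  }
  if (is.null(labels)) stop("class labels required")
  z <- as.numeric(labels == "case")
  n1 <- sum(z); n2 <- sum(1 - z); n <- length(z)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  obs <- sam_stats_two_class(v, z, s0 = 0)
  if (is.null(s0)) s0 <- median(obs$s)
  d_obs <- sam_stats_two_class(v, z, s0 = s0)$d

  exhaustive <- choose(n, n1) <= n_perm
  if (exhaustive) {
    assigns <- combn(n, n1)
  } else {
    set.seed(seed)
    assigns <- replicate(n_perm, sample.int(n, n1))
  }
  d_perm <- matrix(0, nrow(v), ncol(assigns))
  for (b in seq_len(ncol(assigns))) {
    zb <- numeric(n); zb[assigns[, b]] <- 1
    d_perm[, b] <- sam_stats_two_class(v, zb, s0 = s0)$d
  }
  q <- sam_qvalues(d_obs, d_perm)
  sam_result(rownames(v), d_obs, q, fdr, dataset, "two-class")
}

#' Quantitative-response SAM selection with permutation FDR
#'
#' Per gene, the statistic is the regression slope of expression on the
#' covariate divided by (slope standard error + s0). The permutation
#' null shuffles covariate values across samples; all `n!` permutations
#' are enumerated when that is no larger than `n_perm`.
#'
#' @param ds an [expression_dataset()] or numeric matrix.
#' @param covariate numeric covariate per sample; defaults to `age` from
#'   the dataset metadata (samples with missing age dropped).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param fdr threshold used to fill the direction column (default 0.01).
#' @param s0 optional fixed fudge factor; default median of slope
#'   standard errors.
#' @return A `sam_result` data.frame.
#' @export
sam_quantitative <- function(ds, covariate = NULL, n_perm = 1000L, seed = 1L,
                             fdr = 0.01, s0 = NULL) {
  if (inherits(ds, "expression_dataset")) {
    v <- ds$values
    if (is.null(covariate)) covariate <- ds$meta$age
    dataset <- ds$meta$batch[1L]
  } else {
    v <- as.matrix(ds)
    dataset <- "matrix"
  }
  keep <- !is.na(covariate)
  v <- v[, keep, drop = FALSE]
  x <- covariate[keep]
  n <- length(x)
  if (n < 4L) stop("need >= 4 samples with the covariate")
  if (sd(x) == 0) stop("constant covariate")

  slope_stats <- function(xp) {
    xc <- xp - mean(xp)
    sxx <- sum(xc^2)
    slope <- as.vector(v %*% xc) / sxx
    yc2 <- rowSums(v^2) - n * rowMeans(v)^2
    rss <- pmax(yc2 - slope^2 * sxx, 0)
    se <- sqrt(rss / (n - 2) / sxx)
    list(slope = slope, se = se)
  }
  obs <- slope_stats(x)
  if (is.null(s0)) s0 <- median(obs$se)
  denom <- obs$se + s0
  d_obs <- ifelse(denom > 0, obs$slope / denom, 0)

  if (factorial(n) <= n_perm) {
    perms <- all_permutations(n)
  } else {
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  d_perm <- matrix(0, nrow(v), nrow(perms))
  for (b in seq_len(nrow(perms))) {
    st <- slope_stats(x[perms[b, ]])
    db <- st$slope / (st$se + s0)
    db[!is.finite(db)] <- 0
    d_perm[, b] <- db
  }
  q <- sam_qvalues(d_obs, d_perm)
  sam_result(rownames(v), d_obs, q, fdr, dataset, "quantitative")
}

#' Select genes commonly regulated across datasets
#'
#' A gene is selected in a direction when it reaches `q < fdr` with the
#' matching sign of `d` in at least `min_datasets` datasets and is never
#' selected in the opposite direction in any dataset (conservative
#' direction-specific counting).
#'
#' @param results list of `sam_result` objects (one per dataset).
#' @param fdr q-value threshold (e.g. 0.01, or 0.001 for the stringent
#'   datasets).
#' @param min_datasets minimum number of supporting datasets (default 2).
#' @param direction `"up"` or `"down"`.
#' @param fdr_per_dataset optional numeric vector of per-dataset
#'   thresholds overriding `fdr` (the study design applies a stricter
#'   threshold to its two largest cohorts).
#' @return Character vector of selected symbols, with a `provenance`
#'   attribute (named list of supporting dataset labels).
#' @export
select_common <- function(results, fdr = 0.01, min_datasets = 2L,
                          direction = c("up", "down"),
                          fdr_per_dataset = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(results) >= 2L)
  if (is.null(fdr_per_dataset)) fdr_per_dataset <- rep(fdr, length(results))
  stopifnot(length(fdr_per_dataset) == length(results))
  labels <- vapply(seq_along(results), function(i)
    attr(results[[i]], "dataset") %||% paste0("ds", i), character(1))
  up_sets <- vector("list", length(results))
  down_sets <- vector("list", length(results))
  for (i in seq_along(results)) {
    r <- results[[i]]
    sel <- r$q < fdr_per_dataset[i]
    up_sets[[i]] <- r$gene[sel & r$d > 0]
    down_sets[[i]] <- r$gene[sel & r$d < 0]
  }
  this_sets <- if (direction == "up") up_sets else down_sets
  other <- unique(unlist(if (direction == "up") down_sets else up_sets))
  tab <- table(unlist(this_sets))
  genes <- names(tab)[tab >= min_datasets]
  genes <- setdiff(genes, other)
  provenance <- lapply(setNames(genes, genes), function(g)
    labels[vapply(this_sets, function(s) g %in% s, logical(1))])
  structure(sort(genes), provenance = provenance)
}

#' Refine a disease signature by removing age-associated genes
#'
#' The final up set is `ad_up` minus all age-associated genes (either
#' direction), likewise for down. The accounting reports, per direction,
#' the number of common genes, the final count, and the percentage
#' `common / (common + final)`; `percent_display` truncates to one
#' decimal place (the convention under which the published pairs
#' 282/748 and 795/844 print as 27.3 and 48.5).
#'
#' @param ad_up,ad_down initial disease gene sets.
#' @param age_up,age_down age-associated gene sets.
#' @param provenance optional provenance list passed through to the
#'   signature.
#' @return List with `signature` (a [gene_signature()]) and `accounting`
#'   (data.frame, one row per direction: `initial`, `common`, `final`,
#'   `percent_common`, `percent_display`).
#' @export
refine_signature <- function(ad_up, ad_down, age_up, age_down,
                             provenance = NULL) {
  ad_up <- unique(ad_up); ad_down <- unique(ad_down)
  age <- union(age_up, age_down)
  final_up <- setdiff(ad_up, age)
  final_down <- setdiff(ad_down, age)
  if (!length(final_up) && !length(final_down))
    warning("refined signature is empty")
  account_row <- function(initial, final) {
    common <- length(initial) - length(final)
    tot <- common + length(final)
    pct <- if (tot > 0) 100 * common / tot else 0
    data.frame(initial = length(initial), common = common,
               final = length(final), percent_common = pct,
               percent_display = trunc(pct * 10) / 10)
  }
  accounting <- rbind(up = account_row(ad_up, final_up),
                      down = account_row(ad_down, final_down))
  accounting$direction <- rownames(accounting)
  list(signature = gene_signature(final_up, final_down, provenance),
       accounting = accounting)
}

#' Venn accounting percentage from raw counts
#'
#' Convenience wrapper for the common/(common+final) percentage used in
#' the signature accounting, with the same one-decimal display
#' truncation.
#'
#' @param common number of genes shared with the age-associated sets.
#' @param final number of genes retained in the final signature.
#' @return List with `percent` (exact) and `percent_display` (one
#'   decimal, truncated).
#' @export
venn_percent <- function(common, final) {
  pct <- 100 * common / (common + final)
  list(percent = pct, percent_display = trunc(pct * 10) / 10)
}

#' Translate gene symbols through an orthology map
#'
#' Rodent symbols are mapped to their human ortholog (or the reverse with
#' `invert = TRUE`); symbols absent from the map are dropped and counted.
#'
#' @param x character vector of symbols or a [gene_signature()].
#' @param om an [orthology_map()].
#' @param invert map human symbols back to rodent symbols (one human
#'   symbol may expand to several rodent symbols).
#' @return Mapped unique symbol set (or [gene_signature()]), with a
#'   `dropped` attribute giving the number of unmapped input symbols.
#' @export
map_orthologs <- function(x, om, invert = FALSE) {
  map_set <- function(symbols) {
    if (invert) {
      hit <- as.vector(om) %in% symbols
      mapped <- names(om)[hit]
      dropped <- sum(!symbols %in% as.vector(om))
    } else {
      hit <- symbols %in% names(om)
      mapped <- unname(om[symbols[hit]])
      dropped <- sum(!hit)
    }
    structure(unique(mapped), dropped = dropped)
  }
  if (inherits(x, "gene_signature")) {
    up <- map_set(x$up); down <- map_set(x$down)
    both <- intersect(up, down)
    if (length(both)) {
      warning("symbols mapping into both directions dropped: ",
              paste(both, collapse = ", "))
      up <- setdiff(up, both); down <- setdiff(down, both)
    }
    out <- gene_signature(up, down)
    attr(out, "dropped") <- attr(up, "dropped") + attr(down, "dropped")
    return(out)
  }
  map_set(x)
}
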