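# Repressor-weighted pathway activity and its permutation significance.

#' Pathway activity score
#'
#' The activity of a pathway is the linear sum of log2 expression ratios
#' of its measured members, with weight -1 for genes acting as repressors
#' of the pathway and +1 otherwise, normalized by the number of measured
#' members:
#' `A = sum(w_g * r_g) / |P intersect universe|`.
#'
#' @param log_ratios named numeric vector of log2 ratios (gene universe =
#'   its names).
#' @param members character vector of pathway member symbols.
#' @param repressors character vector of member symbols weighted -1
#'   (default none; unannotated genes are activators).
#' @param nominal_size normalize by the nominal pathway size instead of
#'   the measured member count (default `FALSE`).
#' @return Numeric activity (`NA` with a warning when no member is
#'   measured).
#' @export
activity_score <- function(log_ratios, members, repressors = character(),
                           nominal_size = FALSE) {
  present <- intersect(members, names(log_ratios))
  if (!length(present)) {
    warning("no pathway members measured")
    return(NA_real_)
  }
  w <- ifelse(present %in% repressors, -1, 1)
  denom <- if (nominal_size) length(unique(members)) else length(present)
  sum(w * log_ratios[present]) / denom
}

#' Per-sample pathway activity matrix
#'
#' Log2 ratios per sample are taken relative to the control-group mean of
#' each gene; activity is then computed per pathway per sample.
#'
#' @param ds an [expression_dataset()] with control samples.
#' @param collection a [gene_set_collection()].
#' @param roles a [role_map()] (optional).
#' @param nominal_size see [activity_score()].
#' @return Object of class `activity_result`: `activity` (pathways x
#'   samples matrix), `size_used` (measured member count per pathway),
#'   `unmeasured` (names of pathways with no measured member, rows `NA`).
#' @export
activity_matrix <- function(ds, collection, roles = role_map(),
                            nominal_size = FALSE) {
  ctrl <- ds$meta$group == "control"
  if (!any(ctrl)) stop("no control samples")
  ref <- rowMeans(ds$values[, ctrl, drop = FALSE])
  ratios <- sweep(ds$values, 1L, ref, "-")
  act <- matrix(NA_real_, length(collection), ncol(ratios),
                dimnames = list(names(collection), colnames(ratios)))
  size_used <- integer(length(collection))
  names(size_used) <- names(collection)
  for (nm in names(collection)) {
    present <- intersect(collection[[nm]], rownames(ratios))
    size_used[nm] <- length(present)
    if (!length(present)) next
    w <- ifelse(present %in% set_repressors(roles, nm), -1, 1)
    denom <- if (nominal_size) length(collection[[nm]]) else length(present)
    act[nm, ] <- as.vector(crossprod(ratios[present, , drop = FALSE], w)) / denom
  }
  structure(list(activity = act, size_used = size_used,
                 unmeasured = names(collection)[size_used == 0L]),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("activity_result: %d pathways x %d samples (%d unmeasured)\n",
              nrow(x$activity), ncol(x$activity), length(x$unmeasured)))
  invisible(x)
}

#' Gene-set permutation p-value for a pathway activity
#'
#' The null is built by drawing `B` random gene sets of the same measured
#' size from the gene universe (without replacement within a draw) and
#' recomputing the score with default (activator) roles; the p-value is
#' the plain proportion of null scores at least as extreme as the
#' observed score on the requested side.
#'
#' @param log_ratios named numeric vector of log2 ratios, or an
#'   [expression_dataset()] (ratios = case-mean minus control-mean).
#' @param members pathway member symbols.
#' @param repressors repressor member symbols for the observed score.
#' @param B number of null draws (>= 100; default 1000).
#' @param seed integer seed.
#' @param side `"greater"`, `"less"` or `"two-sided"`.
#' @param add_one add-one correction `(k + 1) / (B + 1)` (default off,
#'   plain proportion).
#' @return List with `p`, `observed`, `null` (numeric vector of length
#'   `B`), `size`.
#' @export
permutation_p <- function(log_ratios, members, repressors = character(),
                          B = 1000L, seed = 1L,
                          side = c("greater", "less", "two-sided"),
                          add_one = FALSE) {
  side <- match.arg(side)
  if (inherits(log_ratios, "expression_dataset")) {
    ds <- log_ratios
    case <- ds$meta$group == "case"; ctrl <- ds$meta$group == "control"
    if (!any(case) || !any(ctrl)) stop("need both case and control samples")
    log_ratios <- rowMeans(ds$values[, case, drop = FALSE]) -
      rowMeans(ds$values[, ctrl, drop = FALSE])
  }
  if (B < 100L) stop("B must be >= 100")
  universe <- names(log_ratios)
  size <- length(intersect(members, universe))
  if (size == 0L) stop("no pathway members measured")
  if (length(unique(members)) > length(universe))
    stop("pathway larger than the measured universe")
  observed <- activity_score(log_ratios, members, repressors)
  set.seed(seed)
  null <- vapply(seq_len(B), function(b)
    mean(log_ratios[sample.int(length(universe), size)]), numeric(1))
  k <- switch(side,
              greater = sum(null >= observed),
              less = sum(null <= observed),
              `two-sided` = sum(abs(null) >= abs(observed)))
  p <- if (add_one) (k + 1) / (B + 1) else k / B
  list(p = p, observed = observed, null = null, size = size)
}

#' Differentially activated pathways between two groups
#'
#' For each pathway the observed statistic is the case-minus-control
#' difference in mean activity; the null shuffles group labels `B` times.
#' Pathways with two-sided permutation `p < alpha` are selected, with
#' direction given by the sign of the observed difference.
#'
#' @param act an `activity_result` from [activity_matrix()].
#' @param groups character vector of `"case"`/`"control"` per sample
#'   (column of the activity matrix).
#' @param alpha selection threshold (default 0.05).
#' @param B number of label shuffles (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `pathway`, `diff`, `p`, `direction`,
#'   `selected`.
#' @export
differential_pathways <- function(act, groups, alpha = 0.05, B = 1000L,
                                  seed = 1L) {
  a <- act$activity
  stopifnot(length(groups) == ncol(a))
  case <- groups == "case"; ctrl <- groups == "control"
  if (sum(case) < 2L || sum(ctrl) < 2L) stop("each group needs >= 2 samples")
  measured <- rowSums(is.na(a)) == 0L
  a <- a[measured, , drop = FALSE]
  obs <- rowMeans(a[, case, drop = FALSE]) - rowMeans(a[, ctrl, drop = FALSE])
  set.seed(seed)
  exceed <- integer(nrow(a))
  n <- ncol(a)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    diff_b <- rowMeans(a[, case[perm], drop = FALSE]) -
      rowMeans(a[, ctrl[perm], drop = FALSE])
    exceed <- exceed + (abs(diff_b) >= abs(obs))
  }
  p <- exceed / B
  data.frame(pathway = rownames(a), diff = unname(obs), p = unname(p),
             direction = ifelse(obs >= 0, "up", "down"),
             selected = unname(p < alpha),
             stringsAsFactors = FALSE)
}
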