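# Promoter PWM scanning, binding-site frequency matrices, Jaccard
# clustering, and the cluster-versus-direction association test.

BASE_INDEX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# Column log-probabilities with pseudo-count 0.01 added to every cell
# before normalization.
pwm_log_probs <- function(pwm) {
  m <- pwm + 0.01
  log(sweep(m, 2L, colSums(m), "/"))
}

#' Relative PWM score of one sequence window
#'
#' The raw score is the sum over positions of the log probability of the
#' matched base (column probabilities with a 0.01 pseudo-count); `N`
#' scores as the column minimum. The relative score rescales raw to
#' `(raw - min_possible) / (max_possible - min_possible)` in `[0, 1]`.
#' A fully uniform PWM (max = min) scores 1 with a warning.
#'
#' @param window character sequence of exactly the motif length (A, C,
#'   G, T, N).
#' @param pwm 4 x L nonnegative matrix, rows A, C, G, T.
#' @return Relative score in `[0, 1]`.
#' @export
pwm_relative_score <- function(window, pwm) {
  L <- ncol(pwm)
  chars <- strsplit(toupper(window), "")[[1L]]
  if (length(chars) != L) stop("window length must equal motif length")
  lp <- pwm_log_probs(pwm)
  col_min <- apply(lp, 2L, min)
  col_max <- apply(lp, 2L, max)
  raw <- sum(vapply(seq_len(L), function(i) {
    if (chars[i] == "N") col_min[i] else lp[BASE_INDEX[[chars[i]]], i]
  }, numeric(1)))
  denom <- sum(col_max) - sum(col_min)
  if (denom == 0) {
    warning("degenerate PWM: all windows score equally; relative score 1")
    return(1)
  }
  (raw - sum(col_min)) / denom
}

# Vectorized relative scores of all windows of a sequence (integer-coded;
# N = 5). Returns numeric(0) when the sequence is shorter than the motif.
scan_scores <- function(codes, pwm) {
  L <- ncol(pwm)
  n <- length(codes)
  if (n < L) return(numeric(0))
  lp <- pwm_log_probs(pwm)
  col_min <- apply(lp, 2L, min)
  col_max <- apply(lp, 2L, max)
  lp5 <- rbind(lp, col_min)  # row 5 scores N at the column minimum
  starts <- seq_len(n - L + 1L)
  raw <- numeric(length(starts))
  for (j in seq_len(L)) raw <- raw + lp5[cbind(codes[starts + j - 1L], j)]
  denom <- sum(col_max) - sum(col_min)
  if (denom == 0) return(rep(1, length(starts)))
  (raw - sum(col_min)) / denom
}

encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  codes <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) stop("sequence contains non-ACGTN characters")
  codes
}

revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)  # A<->T, C<->G, N->N
  rev(comp[codes])
}

#' Count PWM matches in a promoter
#'
#' Slides the motif one base at a time and counts windows with relative
#' score at or above `min_rel` on the forward sequence and, with
#' `strands = "both"`, on the reverse complement. Overlapping matches
#' all count.
#'
#' @param promoter promoter sequence (A, C, G, T, N).
#' @param pwm 4 x L matrix, rows A, C, G, T.
#' @param min_rel relative-score threshold (default 0.9).
#' @param strands `"both"` (default) or `"forward"`.
#' @return Integer match count.
#' @export
count_matches <- function(promoter, pwm, min_rel = 0.9,
                          strands = c("both", "forward")) {
  strands <- match.arg(strands)
  codes <- encode_seq(promoter)
  n <- sum(scan_scores(codes, pwm) >= min_rel)
  if (strands == "both")
    n <- n + sum(scan_scores(revcomp_codes(codes), pwm) >= min_rel)
  as.integer(n)
}

#' Binding-site frequency matrix over promoters and PWMs
#'
#' @param promoters named character vector of promoter sequences (names =
#'   gene symbols).
#' @param pwms a [pwm_set()].
#' @param min_rel relative-score threshold (default 0.9).
#' @param strands see [count_matches()].
#' @return Object of class `tfbs_frequency_matrix`: integer matrix genes
#'   x TFs with `min_rel` and `strands` attributes.
#' @export
frequency_matrix <- function(promoters, pwms, min_rel = 0.9,
                             strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(length(promoters) >= 1L, length(pwms) >= 1L)
  counts <- matrix(0L, length(promoters), length(pwms),
                   dimnames = list(names(promoters), names(pwms)))
  for (g in seq_along(promoters)) {
    codes <- tryCatch(encode_seq(promoters[[g]]), error = function(e)
      stop("promoter ", names(promoters)[g], ": ", conditionMessage(e)))
    rc <- if (strands == "both") revcomp_codes(codes) else NULL
    for (t in seq_along(pwms)) {
      n <- sum(scan_scores(codes, pwms[[t]]) >= min_rel)
      if (!is.null(rc)) n <- n + sum(scan_scores(rc, pwms[[t]]) >= min_rel)
      counts[g, t] <- as.integer(n)
    }
  }
  structure(counts, min_rel = min_rel, strands = strands,
            class = c("tfbs_frequency_matrix", class(counts)))
}

#' Jaccard-similarity clustering of binding profiles
#'
#' Counts are binarized (presence/absence), pairwise Jaccard similarity
#' `J = |X n Y| / |X u Y|` is computed (pairs of genes with no binding
#' sites at all get `J = 1`), and average-linkage hierarchical
#' clustering on distance `1 - J` is cut into `k` clusters.
#'
#' @param freq a genes x TFs count matrix (e.g. from
#'   [frequency_matrix()]).
#' @param k number of clusters (default 2).
#' @return List with `cluster` (named integer vector), `similarity`
#'   (genes x genes Jaccard matrix) and `hclust`.
#' @export
jaccard_cluster <- function(freq, k = 2L) {
  B <- (unclass(freq) > 0) * 1L
  if (nrow(B) < 2L) stop("need >= 2 genes to cluster")
  inter <- tcrossprod(B)
  row_sum <- rowSums(B)
  un <- outer(row_sum, row_sum, "+") - inter
  J <- ifelse(un > 0, inter / un, 1)
  dimnames(J) <- list(rownames(B), rownames(B))
  diag(J) <- 1
  hc <- hclust(as.dist(1 - J), method = "average")
  cl <- cutree(hc, k = k)
  list(cluster = cl, similarity = J, hclust = hc)
}

#' Association between promoter clusters and signature direction
#'
#' Yates-corrected chi-squared test on the 2 x 2 table of cluster
#' membership versus up/down direction.
#'
#' @param clusters named vector of cluster labels (2 levels).
#' @param directions named vector of `"up"`/`"down"` per gene.
#' @return List with `statistic`, `p`, `table`, `available` (`FALSE`
#'   with a zero margin).
#' @export
cluster_direction_test <- function(clusters, directions) {
  genes <- intersect(names(clusters), names(directions))
  tab <- table(cluster = factor(clusters[genes]),
               direction = factor(directions[genes]))
  if (!all(dim(tab) == c(2L, 2L)) || any(rowSums(tab) == 0) ||
      any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p = NA_real_, table = tab,
                available = FALSE))
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab,
       available = TRUE)
}
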