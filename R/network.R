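# PPI-topology characterization of gene sets: degree-proportion
# profiles, set-to-set mean shortest-path distances, size-adjusted
# permutation baselines, and selection of signature-adjacent pathways.

#' Degree-proportion profile of a gene set
#'
#' Walks node degrees in increasing order, accumulating genes until a bin
#' holds at least `min_count` network genes (genes at a sparse degree
#' value are added to the genes measured at the next degree value), then
#' emits the proportion of bin genes belonging to the set. The trailing
#' bin may hold fewer than `min_count` genes. A generalized linear trend
#' of the proportion on the representative degree, weighted by the
#' number of network genes per bin, summarizes the profile.
#'
#' @param net a [ppi_network()].
#' @param geneset character vector of gene symbols.
#' @param min_count minimum network genes per bin (default 10).
#' @return Object of class `degree_profile`: data.frame `bins` (columns
#'   `k`, `n_set`, `n_net`, `prop`), `slope` (proportion per degree
#'   unit) and `n_mapped`.
#' @export
degree_profile <- function(net, geneset, min_count = 10L) {
  nodes <- network_nodes(net)
  mapped <- intersect(geneset, nodes)
  if (!length(mapped)) stop("gene set does not intersect the network")
  deg <- igraph::degree(net$graph)
  in_set <- names(deg) %in% mapped
  ks <- sort(unique(deg))
  bins <- list()
  acc_set <- 0L; acc_net <- 0L
  for (k in ks) {
    at_k <- deg == k
    acc_set <- acc_set + sum(in_set & at_k)
    acc_net <- acc_net + sum(at_k)
    if (acc_net >= min_count) {
      bins[[length(bins) + 1L]] <- data.frame(k = k, n_set = acc_set,
                                              n_net = acc_net)
      acc_set <- 0L; acc_net <- 0L
    }
  }
  if (acc_net > 0L)
    bins[[length(bins) + 1L]] <- data.frame(k = max(ks), n_set = acc_set,
                                            n_net = acc_net)
  bins <- do.call(rbind, bins)
  bins$prop <- bins$n_set / bins$n_net
  slope <- NA_real_
  if (nrow(bins) >= 2L) {
    fit <- suppressWarnings(
      glm(prop ~ k, data = bins, weights = bins$n_net))
    slope <- unname(coef(fit)[2L])
  }
  structure(list(bins = bins, slope = slope, n_mapped = length(mapped),
                 min_count = min_count),
            class = "degree_profile")
}

#' @export
print.degree_profile <- function(x, ...) {
  cat(sprintf("degree_profile: %d bins over %d mapped genes, slope %.3f\n",
              nrow(x$bins), x$n_mapped, x$slope))
  invisible(x)
}

#' Mean shortest-path distance between two gene sets
#'
#' Unweighted shortest path lengths are computed for every cross pair of
#' mapped genes; unreachable pairs are excluded from the mean (and
#' counted) unless `impute_unreachable` replaces them with network
#' diameter + 1. A record is rejected (no value) when either set's
#' mapped fraction is not strictly greater than `coverage_min`.
#'
#' @param net a [ppi_network()].
#' @param setA,setB character vectors of symbols.
#' @param coverage_min required mapped fraction, strict (default 0.5).
#' @param impute_unreachable impute unreachable pairs as diameter + 1
#'   instead of excluding them (default `FALSE`).
#' @return Object of class `set_distance`: `mean`, `n_pairs`,
#'   `n_unreachable`, `coverage` (length 2), `rejected`.
#' @export
set_distance <- function(net, setA, setB, coverage_min = 0.5,
                         impute_unreachable = FALSE) {
  stopifnot(length(setA) >= 1L, length(setB) >= 1L)
  nodes <- network_nodes(net)
  mA <- intersect(unique(setA), nodes)
  mB <- intersect(unique(setB), nodes)
  coverage <- c(A = length(mA) / length(unique(setA)),
                B = length(mB) / length(unique(setB)))
  if (coverage[1L] <= coverage_min || coverage[2L] <= coverage_min)
    return(structure(list(mean = NA_real_, n_pairs = 0L, n_unreachable = 0L,
                          coverage = coverage, rejected = TRUE),
                     class = "set_distance"))
  D <- igraph::distances(net$graph, v = mA, to = mB)
  d <- as.vector(D)
  unreachable <- !is.finite(d)
  if (impute_unreachable && any(unreachable)) {
    diam <- igraph::diameter(net$graph, unconnected = TRUE)
    d[unreachable] <- diam + 1
    unreachable <- rep(FALSE, length(d))
  }
  finite <- d[!unreachable]
  structure(list(mean = if (length(finite)) mean(finite) else NA_real_,
                 n_pairs = length(finite),
                 n_unreachable = sum(unreachable),
                 coverage = coverage, rejected = FALSE),
            class = "set_distance")
}

#' @export
print.set_distance <- function(x, ...) {
  if (x$rejected)
    cat("set_distance: rejected (coverage below threshold)\n")
  else
    cat(sprintf("set_distance: mean %.3f over %d pairs (%d unreachable)\n",
                x$mean, x$n_pairs, x$n_unreachable))
  invisible(x)
}

# Mean within-set distance, excluding self-pairs. NA for singletons.
within_set_distance <- function(net, set) {
  nodes <- network_nodes(net)
  m <- intersect(unique(set), nodes)
  if (length(m) < 2L) return(NA_real_)
  D <- igraph::distances(net$graph, v = m, to = m)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d)]
  if (length(d)) mean(d) else NA_real_
}

#' Distance matrix over named gene sets
#'
#' Symmetric matrix of mean cross-pair shortest-path distances between
#' every pair of sets; the diagonal holds the within-set mean excluding
#' self-pairs. Sets failing the coverage rule are dropped with a
#' message. A hierarchical ordering of the rows (average linkage on
#' 1 - Pearson correlation of matrix rows) is returned for display.
#'
#' @param net a [ppi_network()].
#' @param collections named list of symbol vectors (e.g. pathways plus
#'   signature up/down sets).
#' @param coverage_min see [set_distance()].
#' @return Object of class `set_distance_matrix`: `matrix`, `order`
#'   (display order of labels), `dropped` (labels failing coverage).
#' @export
distance_matrix <- function(net, collections, coverage_min = 0.5) {
  nodes <- network_nodes(net)
  cov <- vapply(collections, function(s)
    length(intersect(unique(s), nodes)) / length(unique(s)), numeric(1))
  dropped <- names(collections)[cov <= coverage_min]
  if (length(dropped))
    message("sets dropped for coverage <= ", coverage_min, ": ",
            paste(dropped, collapse = ", "))
  collections <- collections[cov > coverage_min]
  if (length(collections) < 2L) stop("fewer than 2 sets pass coverage")
  labs <- names(collections)
  n <- length(labs)
  M <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  mapped <- lapply(collections, function(s) intersect(unique(s), nodes))
  for (i in seq_len(n)) {
    Di <- igraph::distances(net$graph, v = mapped[[i]])
    for (j in i:n) {
      if (i == j) {
        D <- Di[, mapped[[i]], drop = FALSE]
        d <- D[upper.tri(D)]
        d <- d[is.finite(d)]
        M[i, i] <- if (length(d)) mean(d) else NA_real_
      } else {
        d <- as.vector(Di[, mapped[[j]], drop = FALSE])
        d <- d[is.finite(d)]
        M[i, j] <- M[j, i] <- if (length(d)) mean(d) else NA_real_
      }
    }
  }
  ord <- seq_len(n)
  if (n >= 3L) {
    rows_ok <- rowSums(is.na(M)) < n
    cc <- suppressWarnings(cor(t(M[, rows_ok, drop = FALSE]),
                               use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    hc <- hclust(as.dist(1 - cc), method = "average")
    ord <- hc$order
  }
  structure(list(matrix = M, order = ord, labels = labs, dropped = dropped),
            class = "set_distance_matrix")
}

#' Size-adjusted null distance distributions
#'
#' For each requested set size, draws `B` random node sets and measures
#' their mean shortest-path distance to a fixed reference set,
#' quantifying how set size alone moves the distance.
#'
#' @param net a [ppi_network()].
#' @param sizes integer vector of set sizes (each <= node count).
#' @param reference character vector of reference-set symbols.
#' @param B draws per size (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return data.frame with one row per size (`size`, `mean`, `sd`) and a
#'   `distributions` attribute (named list of the `B` draws per size).
#' @export
size_adjusted_null <- function(net, sizes, reference, B = 1000L, seed = 1L) {
  nodes <- network_nodes(net)
  stopifnot(all(sizes >= 1L), all(sizes <= length(nodes)))
  if (B < 100L) warning("B < 100 gives an unstable null")
  ref <- intersect(unique(reference), nodes)
  if (!length(ref)) stop("reference set not in network")
  Dref <- igraph::distances(net$graph, v = ref)
  set.seed(seed)
  dists <- lapply(setNames(sizes, paste0("size_", sizes)), function(sz) {
    vapply(seq_len(B), function(b) {
      draw <- sample(nodes, sz)
      d <- as.vector(Dref[, draw, drop = FALSE])
      d <- d[is.finite(d)]
      if (length(d)) mean(d) else NA_real_
    }, numeric(1))
  })
  out <- data.frame(size = sizes,
                    mean = vapply(dists, mean, numeric(1), na.rm = TRUE),
                    sd = vapply(dists, sd, numeric(1), na.rm = TRUE))
  attr(out, "distributions") <- dists
  out
}

#' Select pathways adjacent to a gene set from its distance row
#'
#' Distances are converted to similarity (`-distance`); in percentile
#' mode the closest `value` fraction of pathways is retained, in
#' absolute mode pathways with similarity strictly above `value` are
#' retained.
#'
#' @param distances named numeric vector of set-to-pathway mean
#'   distances.
#' @param threshold_mode `"percentile"` (default) or `"absolute"`.
#' @param value retained fraction (percentile mode) or similarity cut
#'   (absolute mode).
#' @return Character vector of selected pathway names (closest first).
#' @export
adjacent_pathways <- function(distances, threshold_mode = c("percentile",
                                                            "absolute"),
                              value = 0.9) {
  threshold_mode <- match.arg(threshold_mode)
  distances <- distances[is.finite(distances)]
  if (!length(distances)) {
    warning("no finite distances: empty selection")
    return(character())
  }
  ord <- order(distances)
  if (threshold_mode == "percentile") {
    n_keep <- floor(value * length(distances) + 1e-9)
    sel <- names(distances)[ord][seq_len(n_keep)]
  } else {
    sel <- names(distances)[ord][(-distances[ord]) > value]
  }
  if (!length(sel)) warning("empty adjacent-pathway selection")
  sel
}

#' Compare node degrees of two gene sets
#'
#' Two-sample Student's t test (equal variances) on the network degrees
#' of the two sets.
#'
#' @param net a [ppi_network()].
#' @param setA,setB character vectors mapping to >= 3 nodes each.
#' @return List with `t`, `p`, `mean_A`, `mean_B`, `available`
#'   (`FALSE` when the pooled variance is degenerate).
#' @export
degree_compare <- function(net, setA, setB) {
  deg <- igraph::degree(net$graph)
  dA <- deg[intersect(unique(setA), names(deg))]
  dB <- deg[intersect(unique(setB), names(deg))]
  if (length(dA) < 3L || length(dB) < 3L)
    stop("each set must map to >= 3 network nodes")
  if (sd(dA) + sd(dB) == 0)
    return(list(t = NA_real_, p = NA_real_, mean_A = mean(dA),
                mean_B = mean(dB), available = FALSE))
  tt <- t.test(dA, dB, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_A = mean(dA), mean_B = mean(dB), available = TRUE)
}
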