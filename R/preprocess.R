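# Probe filtering, normalization, merging, batch standardization,
# covariate adjustment, and age-correlation diagnostics.

#' Filter genes by signal over local background
#'
#' Retains genes whose linear-scale signal (`2^log2 value`) exceeds
#' `factor` times the local background in every sample.
#'
#' @param ds an [expression_dataset()] with a background matrix.
#' @param factor positive fold-change threshold over background
#'   (default 1.4).
#' @return The filtered [expression_dataset()], gene order preserved.
#' @export
filter_background <- function(ds, factor = 1.4) {
  if (is.null(ds$background)) stop("dataset has no background matrix")
  stopifnot(factor >= 0)
  keep <- rowSums(2^ds$values > factor * ds$background) == ncol(ds$values)
  if (!any(keep)) stop("no genes pass the background filter")
  expression_dataset(ds$values[keep, , drop = FALSE], ds$meta,
                     background = ds$background[keep, , drop = FALSE])
}

#' Quantile-normalize an expression matrix
#'
#' After normalization every column shares the identical sorted value
#' vector (the row-wise mean of the sorted columns); tied values within a
#' column receive the mean of their tied quantile values. Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param values numeric matrix (genes x samples), no missing values.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing values not supported")
  if (ncol(values) < 2L) {
    warning("single column: returned unchanged")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Merge expression datasets on their common gene universe
#'
#' Gene universe is the intersection of gene ids; the batch label of each
#' sample becomes its source dataset label and sample ids are uniquified
#' with a dataset prefix.
#'
#' @param datasets list of [expression_dataset()]s (length >= 2).
#' @param labels optional character vector of dataset labels (defaults to
#'   the names of `datasets` or `ds1`, `ds2`, ...).
#' @return A merged [expression_dataset()] (no background matrix).
#' @export
merge_datasets <- function(datasets, labels = NULL) {
  stopifnot(length(datasets) >= 2L)
  if (is.null(labels))
    labels <- names(datasets) %||% paste0("ds", seq_along(datasets))
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  if (!length(common)) stop("empty gene intersection across datasets")
  mats <- vector("list", length(datasets))
  metas <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    m <- d$values[common, , drop = FALSE]
    colnames(m) <- paste(labels[i], colnames(m), sep = ".")
    meta <- d$meta
    rownames(meta) <- colnames(m)
    meta$batch <- labels[i]
    mats[[i]] <- m
    metas[[i]] <- meta
  }
  expression_dataset(do.call(cbind, mats), do.call(rbind, metas))
}

#' Standardize batch location and scale per gene
#'
#' Within each batch every gene is centered and scaled to unit variance,
#' then rescaled to the pooled per-gene mean and standard deviation.
#' Genes with zero variance within a batch are centered to the pooled
#' mean only (no scaling). This is a documented simplification of
#' empirical-Bayes batch correction; switch it off by skipping the call.
#'
#' @param ds an [expression_dataset()] with >= 2 samples per batch.
#' @return A batch-standardized [expression_dataset()].
#' @export
batch_standardize <- function(ds) {
  batches <- ds$meta$batch
  sizes <- table(batches)
  if (any(sizes < 2L))
    stop("batch of size 1: ", paste(names(sizes)[sizes < 2L], collapse = ", "))
  v <- ds$values
  pooled_mean <- rowMeans(v)
  pooled_sd <- apply(v, 1L, sd)
  out <- v
  for (b in unique(batches)) {
    idx <- which(batches == b)
    sub <- v[, idx, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1L, sd)
    z <- sweep(sub, 1L, m, "-")
    scale_ok <- s > 0
    z[scale_ok, ] <- sweep(z[scale_ok, , drop = FALSE], 1L,
                           s[scale_ok], "/") * pooled_sd[scale_ok]
    out[, idx] <- sweep(z, 1L, pooled_mean, "+")
  }
  expression_dataset(out, ds$meta, background = ds$background)
}

#' Adjust expression for age and sex by robust regression
#'
#' Per gene, fits a robust linear model (iteratively reweighted least
#' squares with Huber weights, tuning constant 1.345, at most 50
#' iterations, tolerance 1e-6) of expression on age and a sex indicator,
#' and returns residuals plus the gene's intercept. Samples with missing
#' covariates are dropped with a message. Genes fitting exactly (zero
#' residual scale) fall back to ordinary least squares.
#'
#' @param ds an [expression_dataset()].
#' @param covariates character subset of `c("age", "sex")`.
#' @return An [expression_dataset()] of adjusted values (covariate-complete
#'   samples only).
#' @export
adjust_covariates_robust <- function(ds, covariates = c("age", "sex")) {
  covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  keep <- rep(TRUE, ncol(ds$values))
  if ("age" %in% covariates) keep <- keep & !is.na(ds$meta$age)
  if ("sex" %in% covariates) keep <- keep & !is.na(ds$meta$sex)
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped for missing covariates: ",
            paste(colnames(ds$values)[!keep], collapse = ", "))
  v <- ds$values[, keep, drop = FALSE]
  meta <- ds$meta[keep, , drop = FALSE]
  df <- data.frame(row.names = rownames(meta))
  if ("age" %in% covariates) df$age <- meta$age
  if ("sex" %in% covariates && length(unique(meta$sex)) > 1L)
    df$sex <- factor(meta$sex)
  X <- if (ncol(df)) model.matrix(~ ., df) else
    matrix(1, nrow(meta), 1L, dimnames = list(rownames(meta), "(Intercept)"))
  if (nrow(X) <= ncol(X))
    stop("fewer samples than model parameters")
  out <- v
  for (g in seq_len(nrow(v))) {
    y <- v[g, ]
    fit <- tryCatch(
      MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                maxit = 50, acc = 1e-6),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(sum(residuals(fit))))
      fit <- stats::lm.fit(X, y)
    out[g, ] <- residuals(fit) + coef(fit)[["(Intercept)"]]
  }
  expression_dataset(out, meta,
                     background = if (is.null(ds$background)) NULL else
                       ds$background[, keep, drop = FALSE])
}

#' Age-ordered correlation profile of control samples
#'
#' Sorts control samples by ascending age, computes the full pairwise
#' Pearson correlation matrix, summarizes each sample by the mean of its
#' correlations with all other samples, and moving-averages that summary
#' over a centered window. Also reports the two-sample Student's t
#' statistic comparing per-sample coefficients of samples aged below
#' versus at-or-above the cutoff (old minus young).
#'
#' @param ds an [expression_dataset()]; only control samples with known
#'   age are used.
#' @param window odd moving-average window width in samples.
#' @param age_cutoff age threshold in years (default 65).
#' @return Object of class `correlation_profile`: `sample_ids`, `ages`,
#'   `cor_matrix`, `mean_cor`, `smoothed`, `window`, `t_stat`, `p_value`,
#'   `t_available`.
#' @export
age_correlation_profile <- function(ds, window = 5L, age_cutoff = 65) {
  keep <- ds$meta$group == "control" & !is.na(ds$meta$age)
  if (sum(keep) < 3L) stop("need >= 3 aged control samples")
  v <- ds$values[, keep, drop = FALSE]
  ages <- ds$meta$age[keep]
  ord <- order(ages)
  v <- v[, ord, drop = FALSE]
  ages <- ages[ord]
  cm <- suppressWarnings(cor(v))
  cm[!is.finite(cm)] <- 1  # constant samples correlate trivially
  diag(cm) <- 1
  n <- ncol(v)
  mean_cor <- (rowSums(cm) - 1) / (n - 1)
  smoothed <- setNames(moving_average(mean_cor, window), names(mean_cor))
  old <- ages >= age_cutoff
  t_stat <- NA_real_; p_value <- NA_real_; available <- FALSE
  if (sum(old) >= 3L && sum(!old) >= 3L &&
      sd(mean_cor[old]) + sd(mean_cor[!old]) > 0) {
    tt <- t.test(mean_cor[old], mean_cor[!old], var.equal = TRUE)
    t_stat <- unname(tt$statistic); p_value <- tt$p.value; available <- TRUE
  }
  structure(list(sample_ids = colnames(v), ages = ages, cor_matrix = cm,
                 mean_cor = mean_cor, smoothed = smoothed, window = window,
                 t_stat = t_stat, p_value = p_value, t_available = available),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile: %d samples, ages %.0f-%.0f, window %d\n",
              length(x$ages), min(x$ages), max(x$ages), x$window))
  if (x$t_available)
    cat(sprintf("  old-vs-young t = %.3f (p = %.3g)\n", x$t_stat, x$p_value))
  else cat("  old-vs-young t: unavailable\n")
  invisible(x)
}
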