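# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' draws from its own named substream so that adding a stage never
#' perturbs the draws of another.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) %% 2147480000 + 31L * h) %% 2147483646)
}

# Enumerate all permutations of 1..n (n small). Returns a matrix with one
# permutation per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Centered moving average with shrinking windows at the edges; length
# preserved. `window` must be odd.
moving_average <- function(x, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Write a data.frame as TSV with stable formatting (byte-reproducible).
write_tsv_stable <- function(df, path, row_names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
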