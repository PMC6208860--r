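# Core S3 containers. Plain lists/matrices with validators, in the style
# of limma's MAList/EList objects.

#' Construct an expression dataset
#'
#' A log2 intensity matrix (genes x samples) with per-sample metadata and
#' an optional linear-scale local-background matrix of the same shape.
#'
#' @param values numeric matrix of log2 intensities, rownames = gene
#'   symbols, colnames = sample ids.
#' @param meta data.frame with one row per sample and columns
#'   `group` (`"case"`/`"control"`), `age` (years, `NA` allowed),
#'   `sex` (`"M"`/`"F"`/`NA`) and `batch` (dataset label).
#' @param background optional numeric matrix, same shape as `values`,
#'   strictly positive linear-scale local background.
#' @return An object of class `expression_dataset` with elements
#'   `values`, `meta` and `background`.
#' @export
expression_dataset <- function(values, meta, background = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  meta <- as.data.frame(meta)
  required <- c("group", "age", "sex", "batch")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(rownames(meta)) || !setequal(rownames(meta), colnames(values)))
    stop("metadata rows must match sample ids exactly; missing: ",
         paste(setdiff(colnames(values), rownames(meta)), collapse = ", "))
  meta <- meta[colnames(values), , drop = FALSE]
  bad_group <- !meta$group %in% c("case", "control")
  if (any(bad_group))
    stop("group must be case/control; offending samples: ",
         paste(rownames(meta)[bad_group], collapse = ", "))
  if (any(!is.na(meta$age) & meta$age < 0)) stop("negative ages")
  if (any(!is.na(meta$sex) & !meta$sex %in% c("M", "F")))
    stop("sex must be M, F or NA")
  if (!is.null(background)) {
    background <- as.matrix(background)
    if (!identical(dim(background), dim(values)))
      stop("background matrix shape differs from expression matrix")
    if (any(background <= 0)) stop("background must be strictly positive")
    dimnames(background) <- dimnames(values)
  }
  structure(list(values = values, meta = meta, background = background),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d case / %d control), batches: %s\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$group == "case"), sum(x$meta$group == "control"),
              paste(unique(x$meta$batch), collapse = ", ")))
  if (!is.null(x$background)) cat("  background matrix present\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene symbols). Empty
#'   member tokens are dropped; duplicated members collapse.
#' @return Object of class `gene_set_collection` (a named list).
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  sets <- lapply(sets, function(s) unique(s[nzchar(s)]))
  if (any(lengths(sets) < 1L)) stop("empty gene set(s): ",
                                    paste(names(sets)[lengths(sets) < 1L], collapse = ", "))
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Construct a role map (activator/repressor annotation)
#'
#' Maps (set name, gene) pairs to a role. Genes without an entry default
#' to activator (weight +1); repressors are weighted -1 in pathway
#' activity.
#'
#' @param df data.frame with columns `set`, `gene`, `role`
#'   (`"activator"`/`"repressor"`). May be empty.
#' @param collection optional [gene_set_collection()] to validate that
#'   every annotated pair refers to a member of that set.
#' @return Object of class `role_map`.
#' @export
role_map <- function(df = data.frame(set = character(), gene = character(),
                                     role = character()),
                     collection = NULL) {
  df <- as.data.frame(df)
  stopifnot(all(c("set", "gene", "role") %in% names(df)))
  if (any(!df$role %in% c("activator", "repressor")))
    stop("roles must be activator or repressor")
  if (!is.null(collection)) {
    for (i in seq_len(nrow(df))) {
      if (!df$set[i] %in% names(collection) ||
          !df$gene[i] %in% collection[[df$set[i]]])
        stop(sprintf("role annotation for gene %s not in set %s",
                     df$gene[i], df$set[i]))
    }
  }
  structure(df[c("set", "gene", "role")], class = c("role_map", "data.frame"))
}

#' Repressor genes of one set
#'
#' @param roles a [role_map()].
#' @param set set name.
#' @return Character vector of repressor gene symbols (possibly empty).
#' @export
set_repressors <- function(roles, set) {
  if (is.null(roles) || nrow(roles) == 0L) return(character())
  roles$gene[roles$set == set & roles$role == "repressor"]
}

#' Construct a PPI network
#'
#' Undirected simple graph over gene symbols; self-loops and duplicate
#' edges (either orientation) are removed. Every retained node has
#' degree >= 1.
#'
#' @param edges data.frame with columns `a`, `b` (symbols) and optionally
#'   `throughput` (`"low"`/`"high"`/`"unknown"`).
#' @return Object of class `ppi_network` wrapping an igraph graph.
#' @export
ppi_network <- function(edges) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("a", "b") %in% names(edges)))
  if (!"throughput" %in% names(edges)) edges$throughput <- "unknown"
  edges$throughput[!edges$throughput %in% c("low", "high")] <- "unknown"
  keep <- edges$a != edges$b
  edges <- edges[keep, , drop = FALSE]
  key <- ifelse(edges$a < edges$b,
                paste(edges$a, edges$b, sep = "\r"),
                paste(edges$b, edges$a, sep = "\r"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  if (nrow(edges) == 0L) stop("no edges remain after filtering")
  g <- igraph::graph_from_data_frame(edges[c("a", "b")], directed = FALSE)
  igraph::E(g)$throughput <- edges$throughput
  structure(list(graph = g), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Nodes of a PPI network
#' @param net a [ppi_network()].
#' @return Character vector of gene symbols.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Construct a PWM set
#'
#' @param pwms named list of 4 x L nonnegative matrices with rows
#'   A, C, G, T (counts or probabilities; each column must have positive
#'   sum).
#' @return Object of class `pwm_set`.
#' @export
pwm_set <- function(pwms) {
  if (is.null(names(pwms)) || any(!nzchar(names(pwms))))
    stop("every PWM needs a TF name")
  pwms <- lapply(pwms, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != 4L) stop("PWM must have 4 rows (A,C,G,T)")
    if (ncol(m) < 1L) stop("PWM must have length >= 1")
    if (any(m < 0)) stop("PWM entries must be nonnegative")
    if (any(colSums(m) <= 0)) stop("PWM column with zero sum")
    rownames(m) <- c("A", "C", "G", "T")
    m
  })
  structure(pwms, class = "pwm_set")
}

#' Construct an orthology map
#'
#' @param rodent character vector of rodent symbols.
#' @param human character vector of human symbols (same length).
#' @return Named character vector (rodent -> human) of class
#'   `orthology_map`. Many rodent symbols may map to one human symbol;
#'   conflicting duplicate rodent entries are an error.
#' @export
orthology_map <- function(rodent, human) {
  stopifnot(length(rodent) == length(human))
  if (any(!nzchar(rodent)) || any(!nzchar(human)) ||
      any(is.na(rodent)) || any(is.na(human)))
    stop("empty symbol in orthology map")
  df <- unique(data.frame(rodent = rodent, human = human))
  if (anyDuplicated(df$rodent))
    stop("conflicting orthology for: ",
         paste(unique(df$rodent[duplicated(df$rodent)]), collapse = ", "))
  structure(setNames(df$human, df$rodent), class = "orthology_map")
}

#' Construct a gene signature
#'
#' Disjoint up/down symbol sets, optionally with per-gene provenance
#' (which datasets supported each gene).
#'
#' @param up,down character vectors of gene symbols.
#' @param provenance optional named list, gene -> character vector of
#'   supporting dataset labels.
#' @return Object of class `gene_signature`.
#' @export
gene_signature <- function(up, down, provenance = NULL) {
  up <- unique(up); down <- unique(down)
  if (length(intersect(up, down)))
    stop("up and down sets overlap: ",
         paste(head(intersect(up, down)), collapse = ", "))
  structure(list(up = up, down = down, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d up, %d down\n", length(x$up), length(x$down)))
  invisible(x)
}

#' Construct an animal-model log-ratio profile
#'
#' @param ratios named numeric vector, gene -> log2 ratio vs matched
#'   control.
#' @param universe character vector of measured genes (must contain the
#'   names of `ratios`).
#' @param model,tissue labels.
#' @return Object of class `log_ratio_profile`.
#' @export
log_ratio_profile <- function(ratios, universe = names(ratios),
                              model = "model", tissue = "") {
  if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
    stop("ratios must be named by gene symbol")
  if (any(!is.finite(ratios))) stop("non-finite log ratios")
  if (!all(names(ratios) %in% universe))
    stop("ratio genes missing from measured universe")
  structure(list(model = model, tissue = tissue,
                 ratios = ratios, universe = unique(universe)),
            class = "log_ratio_profile")
}

#' @export
print.log_ratio_profile <- function(x, ...) {
  cat(sprintf("log_ratio_profile: %s %s, %d genes (universe %d)\n",
              x$model, x$tissue, length(x$ratios), length(x$universe)))
  invisible(x)
}

#' Classify a model score from its permutation p-values
#'
#' `strong` requires p <= alpha_strong in both directions, `weak`
#' requires p <= alpha_weak in both directions (and not strong),
#' otherwise `none`.
#'
#' @param p_up,p_down one-sided permutation p-values.
#' @param alpha_strong,alpha_weak thresholds (defaults 0.01 and 0.05).
#' @return `"strong"`, `"weak"` or `"none"` (`NA` if either p is `NA`).
#' @export
classify_model <- function(p_up, p_down, alpha_strong = 0.01, alpha_weak = 0.05) {
  if (is.na(p_up) || is.na(p_down)) return(NA_character_)
  if (p_up <= alpha_strong && p_down <= alpha_strong) return("strong")
  if (p_up <= alpha_weak && p_down <= alpha_weak) return("weak")
  "none"
}

# Internal constructor for model scores.
model_score <- function(measure, model, tissue, mean_up, mean_down,
                        p_up, p_down, alpha_strong = 0.01, alpha_weak = 0.05,
                        n_up = NA_integer_, n_down = NA_integer_) {
  structure(list(measure = measure, model = model, tissue = tissue,
                 mean_up = mean_up, mean_down = mean_down,
                 p_up = p_up, p_down = p_down,
                 n_up = n_up, n_down = n_down,
                 class = classify_model(p_up, p_down, alpha_strong, alpha_weak)),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("model_score [%s] %s %s: mean_up=%.3f (p=%.3g), mean_down=%.3f (p=%.3g) -> %s\n",
              x$measure, x$model, x$tissue, x$mean_up, x$p_up,
              x$mean_down, x$p_down, x$class))
  invisible(x)
}
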