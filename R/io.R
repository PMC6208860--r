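# Readers and writers for every external format the pipeline touches.
# All formats are plain text: tab-delimited matrices, GMT, BioGRID-like
# edge lists, JASPAR PWM blocks, FASTA and two-column orthology tables.

#' Read a tab-delimited expression matrix plus sample metadata
#'
#' The matrix file has gene symbols in the first column and one column of
#' log2 intensities per sample; the metadata file is tab-delimited with a
#' `sample_id` column plus `group`, `age`, `sex`, `batch`. Duplicate gene
#' symbols are collapsed by the per-gene mean of log2 values.
#'
#' @param path expression matrix file.
#' @param meta_path metadata file.
#' @param background_path optional file with a linear-scale background
#'   matrix of identical layout.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, meta_path, background_path = NULL) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs >= 1 sample column")
  genes <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    col <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(col) & !is.na(mat[, j]) & mat[, j] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value at gene %s, sample %s",
                   genes[bad[1L]], colnames(mat)[j]))
    mat[, j] <- col
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  mat <- collapse_duplicate_genes(mat)

  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata needs a sample_id column")
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(meta$sample_id, colnames(mat))
  if (length(unknown))
    stop("metadata lists unknown sample(s): ", paste(unknown, collapse = ", "))
  rownames(meta) <- meta$sample_id

  background <- NULL
  if (!is.null(background_path)) {
    braw <- read.delim(background_path, check.names = FALSE,
                       stringsAsFactors = FALSE)
    background <- as.matrix(braw[, -1L, drop = FALSE])
    storage.mode(background) <- "double"
    rownames(background) <- as.character(braw[[1L]])
    background <- collapse_duplicate_genes(background)
    if (!setequal(rownames(background), rownames(mat)))
      stop("background matrix gene ids differ from expression matrix")
    background <- background[rownames(mat), colnames(mat), drop = FALSE]
  }
  expression_dataset(mat, meta[, c("group", "age", "sex", "batch")],
                     background = background)
}

# Collapse duplicated rownames by per-gene mean.
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  out <- rowsum(mat, group = rownames(mat), reorder = FALSE) /
    as.vector(table(rownames(mat))[unique(rownames(mat))])
  out[unique(rownames(mat)), , drop = FALSE]
}

#' Write an expression dataset to TSV files
#'
#' @param ds an [expression_dataset()].
#' @param path expression matrix output file.
#' @param meta_path metadata output file.
#' @param background_path optional background output file.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, meta_path,
                                   background_path = NULL) {
  df <- data.frame(gene = rownames(ds$values), ds$values,
                   check.names = FALSE)
  write_tsv_stable(df, path)
  meta <- data.frame(sample_id = rownames(ds$meta), ds$meta,
                     check.names = FALSE)
  write_tsv_stable(meta, meta_path)
  if (!is.null(background_path) && !is.null(ds$background)) {
    bdf <- data.frame(gene = rownames(ds$background), ds$background,
                      check.names = FALSE)
    write_tsv_stable(bdf, background_path)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited `name`, `description`,
#' then members. Empty member tokens are dropped and duplicated members
#' stored once.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    sets[[fields[1L]]] <- fields[-(1:2)]
  }
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @param descriptions optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(collection, path, descriptions = NULL) {
  lines <- vapply(names(collection), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PPI edge list
#'
#' Tab-delimited with two symbol columns and a throughput column
#' (BioGRID-like). Self-loops are removed and duplicate edges in either
#' orientation collapse to one.
#'
#' @param path edge list file (columns `a`, `b`, `throughput`).
#' @param low_throughput_only keep only edges tagged `low`.
#' @return A [ppi_network()].
#' @export
read_ppi_edges <- function(path, low_throughput_only = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs >= 2 columns")
  names(df)[1:2] <- c("a", "b")
  if (ncol(df) >= 3L && !"throughput" %in% names(df))
    names(df)[3L] <- "throughput"
  if (!"throughput" %in% names(df)) df$throughput <- "unknown"
  if (low_throughput_only) df <- df[df$throughput == "low", , drop = FALSE]
  if (nrow(df) == 0L) stop("no edges remain after throughput filtering")
  ppi_network(df)
}

#' Write a PPI network as an edge list
#'
#' @param net a [ppi_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  df <- data.frame(a = el[, 1L], b = el[, 2L],
                   throughput = igraph::E(net$graph)$throughput)
  write_tsv_stable(df, path)
  invisible(path)
}

#' Read JASPAR-format position weight matrices
#'
#' Plain-text JASPAR blocks: a `>ID name` header followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional) for A, C, G, T.
#'
#' @param path JASPAR text file.
#' @return A [pwm_set()].
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no PWM blocks found")
  pwms <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop("PWM block must have exactly 4 base rows: ", lines[headers[i]])
    nm <- trimws(sub("^>\\s*", "", lines[headers[i]]))
    nm <- strsplit(nm, "\\s+")[[1L]]
    nm <- if (length(nm) >= 2L) nm[2L] else nm[1L]
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      toks <- strsplit(trimws(l), "\\s+")[[1L]]
      base <- toks[1L]
      vals <- suppressWarnings(as.numeric(toks[-1L]))
      if (any(is.na(vals))) stop("non-numeric PWM entry in block ", nm)
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("PWM block ", nm, " must have rows A, C, G, T")
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(mat) <- bases
    pwms[[nm]] <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  }
  pwm_set(pwms)
}

#' Write a PWM set in JASPAR text format
#'
#' @param pwms a [pwm_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  out <- character()
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    out <- c(out, paste0(">", nm, " ", nm),
             vapply(c("A", "C", "G", "T"), function(b)
               paste0(b, " [ ", paste(m[b, ], collapse = " "), " ]"),
               character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Sequences are uppercased and validated to contain only A, C, G, T, N.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  # BStringSet keeps bytes verbatim so invalid characters can be rejected
  # (DNAStringSet would silently drop non-alphabet letters)
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Read a two-column orthology table
#'
#' Tab-delimited, rodent symbol then human symbol; a header row is
#' detected by the literal column names `rodent`/`human`.
#'
#' @param path orthology file.
#' @return An [orthology_map()].
#' @export
read_orthology <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- identical(tolower(first[1:2]), c("rodent", "human"))
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE,
                   col.names = c("rodent", "human"))
  if (any(is.na(df)) || any(!nzchar(df$rodent)) || any(!nzchar(df$human)))
    stop("orthology row with missing field")
  orthology_map(df$rodent, df$human)
}

#' Write an orthology map to TSV
#'
#' @param om an [orthology_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orthology <- function(om, path) {
  write_tsv_stable(data.frame(rodent = names(om), human = as.vector(om)), path)
  invisible(path)
}

#' Write a gene signature as TSV plus a JSON provenance sidecar
#'
#' @param sig a [gene_signature()].
#' @param path two-column TSV output (symbol, direction).
#' @param provenance_path optional JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path, provenance_path = NULL) {
  df <- data.frame(symbol = c(sig$up, sig$down),
                   direction = rep(c("up", "down"),
                                   c(length(sig$up), length(sig$down))))
  write_tsv_stable(df, path)
  if (!is.null(provenance_path))
    jsonlite::write_json(sig$provenance %||% list(), provenance_path,
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a gene signature written by [write_signature()]
#'
#' @param path signature TSV.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gene_signature(df$symbol[df$direction == "up"],
                 df$symbol[df$direction == "down"])
}
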