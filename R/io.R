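# Readers/writers for every external representation the pipeline touches.
# All tabular files are TSV with '#'-prefixed comment lines; readers
# validate and reject malformed input with line/coordinate information
# rather than coercing. Genomic coordinates are 0-based half-open
# throughout; 1-based inputs are converted at the boundary.

read_tsv_quiet <- function(path, col_names = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, comment = "#", col_names = col_names,
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a miRNA-target interaction table
#'
#' Expects a TSV edge list whose first two columns are the miRNA
#' (source) and target ids. Duplicate (source, target) rows are dropped
#' with a message reporting the count; empty ids are rejected with the
#' offending line number.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @param target_kind What the targets are: `"lncRNA"`, `"TF"` or `"mRNA"`.
#' @param header Whether the file has a header line.
#' @return A tibble with columns `source_id`, `target_id`, `target_kind`.
#' @export
read_interaction_table <- function(path, target_kind = c("lncRNA", "TF", "mRNA"),
                                   header = TRUE) {
  target_kind <- match.arg(target_kind)
  tab <- read_tsv_quiet(path, col_names = header)
  if (nrow(tab) == 0L) abort(sprintf("empty interaction table: %s", path))
  if (ncol(tab) < 2L) abort(sprintf("need >= 2 columns in %s", path))
  out <- tibble(source_id = tab[[1]], target_id = tab[[2]])
  bad <- which(is.na(out$source_id) | is.na(out$target_id) |
                 out$source_id == "" | out$target_id == "")
  if (length(bad)) {
    abort(sprintf("empty source/target id at line %d of %s",
                  bad[1] + as.integer(header), path))
  }
  n0 <- nrow(out)
  out <- distinct(out)
  if (nrow(out) < n0) {
    inform(sprintf("dropped %d duplicate interaction row(s).", n0 - nrow(out)))
  }
  out$target_kind <- target_kind
  out
}

#' Read a gene x sample expression matrix
#'
#' TSV with gene ids in the first column and one column per sample.
#' Values are log-scale expression. `NA` (or empty) cells are stored as
#' missing, never as zero; non-numeric cells and duplicated gene ids are
#' rejected with coordinates.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix (genes x samples) with dimnames.
#' @export
read_expression_matrix <- function(path) {
  tab <- read_tsv_quiet(path)
  if (ncol(tab) < 2L) abort(sprintf("expression matrix %s needs >= 1 sample column", path))
  genes <- tab[[1]]
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicated gene id '%s' in %s", genes[duplicated(genes)][1], path))
  }
  samples <- names(tab)[-1]
  mat <- matrix(NA_real_, nrow = nrow(tab), ncol = length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    raw <- tab[[j + 1L]]
    missing <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!missing & is.na(num))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                    raw[bad[1]], genes[bad[1]], samples[j], path))
    }
    mat[, j] <- num
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- tibble(gene_id = rownames(mat))
  df <- bind_cols(df, as_tibble(mat))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a clinical / survival table
#'
#' Required columns: `sample_id`, `time` (days, non-negative), `event`
#' (0 = censored, 1 = death observed). Optional: `subtype`, `stage`,
#' `tissue` (`tumor`/`normal`). Sample ids must be unique.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per sample.
#' @export
read_clinical_table <- function(path) {
  tab <- read_tsv_quiet(path)
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(tab))
  if (length(miss)) abort(sprintf("clinical table missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  out <- tibble(
    sample_id = tab$sample_id,
    time = suppressWarnings(as.numeric(tab$time)),
    event = suppressWarnings(as.integer(tab$event))
  )
  if (anyDuplicated(out$sample_id)) abort("duplicate sample_id in clinical table.")
  bad_t <- which(is.na(out$time) | out$time < 0)
  if (length(bad_t)) abort(sprintf("invalid time at line %d", bad_t[1] + 1L))
  bad_e <- which(!out$event %in% c(0L, 1L))
  if (length(bad_e)) abort(sprintf("event must be 0/1; offending line %d", bad_e[1] + 1L))
  for (opt in c("subtype", "stage", "tissue")) {
    if (opt %in% names(tab)) out[[opt]] <- tab[[opt]]
  }
  if ("tissue" %in% names(out)) {
    bad <- setdiff(unique(out$tissue[!is.na(out$tissue)]), c("tumor", "normal"))
    if (length(bad)) abort(sprintf("unknown tissue value(s): %s", paste(bad, collapse = ", ")))
  }
  out
}

#' @rdname read_clinical_table
#' @param clinical Tibble as returned by [read_clinical_table()].
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Read gene annotation (BED-like)
#'
#' BED6: chrom, start, end, name (gene id), score, strand; 0-based
#' half-open coordinates. Set `one_based = TRUE` for GTF-style 1-based
#' closed input, converted at the boundary.
#'
#' @param path Path to the BED file.
#' @param one_based Input uses 1-based closed coordinates.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, one_based = FALSE) {
  tab <- read_tsv_quiet(path, col_names = FALSE)
  if (ncol(tab) < 6L) abort(sprintf("BED6 needs 6 columns: %s", path))
  out <- tibble(
    gene_id = tab[[4]],
    chrom = tab[[1]],
    start = suppressWarnings(as.integer(tab[[2]])),
    end = suppressWarnings(as.integer(tab[[3]])),
    strand = tab[[6]]
  )
  if (one_based) out$start <- out$start - 1L
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end)
  if (length(bad)) abort(sprintf("invalid interval at line %d of %s", bad[1], path))
  bad_s <- which(!out$strand %in% c("+", "-"))
  if (length(bad_s)) abort(sprintf("strand must be +/- (line %d)", bad_s[1]))
  out
}

#' Write genomic regions as BED6
#'
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  df <- tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions$region_id, score = 0L, strand = regions$strand
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is what the scanner and generators work with.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of DNA sequences.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a cerna_network as node + edge TSV tables
#'
#' `write_network()` writes `nodes.tsv` and `edges.tsv` under `dir`;
#' `read_network()` reconstructs the network. The round trip is the
#' identity (node-for-node, edge-for-edge with evidence attributes).
#' Unknown edge types on read are rejected.
#'
#' @param net A [cerna_network()].
#' @param dir Directory to write into (created if needed).
#' @return `write_network()` returns `dir` invisibly; `read_network()` a
#'   [cerna_network()].
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "cerna_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(net$nodes, file.path(dir, "nodes.tsv"))
  readr::write_tsv(net$edges, file.path(dir, "edges.tsv"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  nodes <- readr::read_tsv(file.path(dir, "nodes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(edges)) {
    bad <- setdiff(unique(edges$type), c("ceRNA", "PPI"))
    if (length(bad)) abort(sprintf("unknown edge type on read: %s",
                                   paste(bad, collapse = ", ")))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  nodes$id <- as.character(nodes$id)
  cerna_network(nodes, edges)
}
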