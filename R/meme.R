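# MEME minimal motif format: parse and emit position probability
# matrices over the ACGT alphabet.

#' Construct a position weight matrix object
#'
#' @param matrix Numeric width x 4 matrix of probabilities, columns
#'   A, C, G, T. Rows must each sum to 1 (within 1e-6 after the
#'   renormalisation applied by the MEME reader).
#' @param motif_id Motif identifier.
#' @param background Length-4 background base probabilities (must sum to 1).
#' @return An object of class `pwm`.
#' @export
make_pwm <- function(matrix, motif_id, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) abort("PWM matrix must have 4 columns (A, C, G, T).")
  if (any(matrix < 0)) abort("PWM probabilities must be non-negative.")
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-6)) {
    abort(sprintf("PWM row %d sums to %.6f, not 1.", which(abs(rs - 1) > 1e-6)[1],
                  rs[which(abs(rs - 1) > 1e-6)[1]]))
  }
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    abort("background must be 4 positive probabilities summing to 1.")
  }
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = setNames(background, c("A", "C", "G", "T"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d\n", x$motif_id, nrow(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per column)
#'
#' Ties resolve to the first base in A, C, G, T order.
#'
#' @param pwm A [make_pwm()] object.
#' @return Single character string of length `width`.
#' @export
consensus_sequence <- function(pwm) {
  paste(colnames(pwm$matrix)[apply(pwm$matrix, 1, which.max)], collapse = "")
}

#' Read motifs in MEME minimal format
#'
#' Parses every `MOTIF` block into a [make_pwm()] object. The alphabet
#' must be ACGT. Letter-probability rows off from 1 by less than 1e-3
#' are silently renormalised; larger deviations are an error.
#'
#' @param path Path to a MEME minimal format file.
#' @return Named list of `pwm` objects.
#' @export
read_motifs_meme <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_line)) {
    alpha <- gsub("\\s", "", sub("^ALPHABET=?", "", alpha_line[1]))
    if (toupper(alpha) != "ACGT") abort(sprintf("alphabet must be ACGT, got '%s'", alpha))
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- suppressWarnings(as.numeric(toks[c(2, 4, 6, 8)]))
      if (!anyNA(vals)) background <- vals / sum(vals)
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) abort(sprintf("no MOTIF blocks in %s", path))
  motifs <- list()
  for (i in seq_along(motif_at)) {
    start <- motif_at[i]
    stop_at <- if (i < length(motif_at)) motif_at[i + 1L] - 1L else length(lines)
    block <- lines[start:stop_at]
    id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    lp <- grep("^letter-probability matrix", block)
    if (!length(lp)) abort(sprintf("motif %s lacks a letter-probability matrix", id))
    width <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[lp[1]])))
    rows <- block[-seq_len(lp[1])]
    rows <- rows[trimws(rows) != ""]
    rows <- grep("^[0-9eE+.[:space:]-]+$", trimws(rows), value = TRUE)
    if (is.na(width)) width <- length(rows)
    if (length(rows) < width) abort(sprintf("motif %s: expected %d rows, found %d",
                                            id, width, length(rows)))
    mat <- t(vapply(rows[seq_len(width)], function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4)))
    rs <- rowSums(mat)
    off <- abs(rs - 1)
    if (any(off >= 1e-3)) {
      abort(sprintf("motif %s row %d sums to %.4f (tolerance 1e-3)",
                    id, which(off >= 1e-3)[1], rs[which(off >= 1e-3)[1]]))
    }
    mat <- mat / rs
    rownames(mat) <- NULL
    motifs[[id]] <- make_pwm(mat, id, background)
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of [make_pwm()] objects.
#' @param path Output path.
#' @export
write_motifs_meme <- function(motifs, path) {
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  bg <- motifs[[1]]$background
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), ""
  )
  for (m in motifs) {
    out <- c(out,
             sprintf("MOTIF %s", m$motif_id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(m$matrix)),
             apply(m$matrix, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                    r[1], r[2], r[3], r[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
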