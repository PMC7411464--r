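# FIMO-style PWM scanning with exact p-values, promoter region
# derivation, crosstalk network assembly and generic gene-set
# over-representation.

BASES <- c("A", "C", "G", "T")

encode_dna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, BASES)           # N and anything else -> NA
  code
}

# Integer log-odds score matrix (w x 4) on a 1/granularity grid.
# Zero probability entries get a 1e-3 pseudocount so scores stay finite.
pwm_int_scores <- function(pwm, background, granularity) {
  p <- pwm$matrix
  p[p == 0] <- 1e-3
  lo <- log2(sweep(p, 2, background, "/"))
  matrix(as.integer(round(granularity * lo)), nrow = nrow(p))
}

# Exact null distribution of the integer window score under the 0-order
# background model, by dynamic programming (convolution column by
# column). Returns list(min, tail) where tail[s - min + 1] = P(S >= s).
pwm_score_tail <- function(int_scores, background) {
  w <- nrow(int_scores)
  lo <- sum(apply(int_scores, 1, min))
  hi <- sum(apply(int_scores, 1, max))
  width <- hi - lo + 1L
  d <- numeric(width)
  # after 0 columns the score is 0; track running offset
  cur_lo <- 0L
  d[1] <- 1
  cur <- d[1:1]
  for (j in seq_len(w)) {
    col <- int_scores[j, ]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1L + max(col)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + background[b] * cur
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  stopifnot(cur_lo == lo, length(cur) == width)
  tail <- rev(cumsum(rev(cur)))
  list(min = lo, max = hi, tail = tail)
}

window_scores <- function(code, int_scores) {
  w <- nrow(int_scores)
  L <- length(code)
  n_win <- L - w + 1L
  if (n_win < 1L) return(numeric(0))
  s <- numeric(n_win)
  na <- logical(n_win)
  for (j in seq_len(w)) {
    b <- code[j:(j + n_win - 1L)]
    bad <- is.na(b)
    na <- na | bad
    bj <- b
    bj[bad] <- 1L
    s <- s + int_scores[j, bj]
  }
  s[na] <- NA_real_
  s
}

#' Scan a sequence with a PWM, reporting hits with exact p-values
#'
#' At every offset, on both strands, the window is scored as
#' `sum_j log2(pwm[j, base_j] / background[base_j])` (zero PWM entries
#' receive a 1e-3 pseudocount; scores are discretised on a
#' `1/granularity` grid). The p-value of a score is the exact
#' probability, computed by dynamic programming over the discretised
#' score distribution, that a background-model sequence of motif width
#' scores at least as high. Hits with `p < p_threshold` are returned
#' sorted by position. Windows containing non-ACGT letters are skipped;
#' a motif wider than the sequence yields an empty result.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param pwm A [make_pwm()] object.
#' @param p_threshold Strict p-value cutoff (default 1e-4).
#' @param background Length-4 background probabilities; defaults to the
#'   PWM's own background (uniform unless set otherwise).
#' @param granularity Score discretisation steps per log2 unit (default 1000).
#' @return Tibble: `motif_id`, `start` (0-based offset), `strand`,
#'   `score` (log2 odds), `p`.
#' @export
pwm_scan <- function(sequence, pwm, p_threshold = 1e-4, background = NULL,
                     granularity = 1000) {
  stopifnot(inherits(pwm, "pwm"))
  background <- background %||% unname(pwm$background)
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1.")
  int_fwd <- pwm_int_scores(pwm, background, granularity)
  w <- nrow(int_fwd)
  code <- encode_dna(sequence)
  if (length(code) < w) {
    return(tibble(motif_id = character(), start = integer(),
                  strand = character(), score = numeric(), p = numeric()))
  }
  # reverse-complement scan: score of revcomp(window) against the PWM
  # equals scanning forward with the row-reversed, base-complemented matrix
  int_rev <- int_fwd[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE]
  null <- pwm_score_tail(int_fwd, background)
  pval <- function(s) null$tail[pmin(pmax(s, null$min), null$max) - null$min + 1L]

  res <- list()
  for (strand in c("+", "-")) {
    sc <- window_scores(code, if (strand == "+") int_fwd else int_rev)
    ok <- which(!is.na(sc))
    if (!length(ok)) next
    p <- pval(sc[ok])
    hit <- p < p_threshold
    if (any(hit)) {
      res[[strand]] <- tibble(
        motif_id = pwm$motif_id,
        start = ok[hit] - 1L,
        strand = strand,
        score = sc[ok][hit] / granularity,
        p = p[hit]
      )
    }
  }
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(tibble(motif_id = character(), start = integer(),
                  strand = character(), score = numeric(), p = numeric()))
  }
  arrange(out, .data$start, .data$strand)
}

#' Scan many regions with many motifs
#'
#' @param sequences Named character vector of region sequences.
#' @param pwms List of [make_pwm()] objects (or a single one).
#' @param ... Passed to [pwm_scan()].
#' @return Tibble of hits with a leading `region_id` column.
#' @export
scan_regions <- function(sequences, pwms, ...) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  out <- list()
  for (rid in names(sequences)) {
    for (pwm in pwms) {
      h <- pwm_scan(sequences[[rid]], pwm, ...)
      if (nrow(h)) out[[length(out) + 1L]] <- mutate(h, region_id = rid, .before = 1)
    }
  }
  if (!length(out)) {
    return(tibble(region_id = character(), motif_id = character(),
                  start = integer(), strand = character(),
                  score = numeric(), p = numeric()))
  }
  bind_rows(out)
}

#' Promoter regions around strand-aware TSS
#'
#' The TSS of a `+` strand gene is its `start` coordinate; of a `-`
#' strand gene, `end - 1` (0-based half-open). The promoter is
#' `[TSS - flank, TSS + flank)`, clipped at 0 and, when `chrom_sizes`
#' is provided, at the contig end.
#'
#' @param annotation Tibble from [read_gene_annotation()] (`gene_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param flank Bases on each side of the TSS (default 2000).
#' @param chrom_sizes Optional named vector of contig lengths for clipping.
#' @return Region tibble: `region_id`, `chrom`, `start`, `end`, `strand`,
#'   `kind = "promoter"`, `gene_id`.
#' @export
promoter_regions <- function(annotation, flank = 2000, chrom_sizes = NULL) {
  ann <- as_tibble(annotation)
  if (any(!ann$strand %in% c("+", "-"))) abort("unknown strand in annotation.")
  tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  start <- pmax(0L, tss - as.integer(flank))
  end <- tss + as.integer(flank)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[ann$chrom]
    if (anyNA(lim)) abort("chrom_sizes missing a contig present in the annotation.")
    end <- pmin(end, as.integer(lim))
  }
  tibble(
    region_id = paste0(ann$gene_id, "_promoter"),
    chrom = ann$chrom, start = start, end = end, strand = ann$strand,
    kind = "promoter", gene_id = ann$gene_id
  )
}

#' Core lncRNA-TF crosstalk network
#'
#' Restricts the ceRNA network to its top `hub_fraction` hub lncRNAs (by
#' degree; ties broken as in [select_hubs()]) and keeps a ceRNA edge
#' (lncRNA, TF) only when the TF has at least one motif hit in a
#' promoter or enhancer region linked to that lncRNA. The resulting edge
#' set is always a subset of the input's ceRNA edges.
#'
#' @param net A [cerna_network()].
#' @param hits Motif hit tibble from [scan_regions()] (needs `region_id`,
#'   `motif_id`).
#' @param regions Region tibble linking `region_id` to `gene_id`.
#' @param motif_tf Two-column tibble mapping `motif_id` to `tf_id`.
#'   Motifs with no mapping are skipped with a warning.
#' @param hub_fraction Top fraction of lncRNAs by degree (default 0.20).
#' @return A [cerna_network()] containing the crosstalk edges and their
#'   incident nodes.
#' @export
build_crosstalk_network <- function(net, hits, regions, motif_tf,
                                    hub_fraction = 0.20) {
  stopifnot(inherits(net, "cerna_network"))
  metrics <- node_metrics(net)
  lnc <- filter(metrics, .data$kind == "lncRNA") |>
    arrange(desc(.data$degree), desc(.data$betweenness), .data$id)
  n_hub <- floor(hub_fraction * nrow(lnc))
  hub_lnc <- head(lnc$id, n_hub)

  hits <- as_tibble(hits)
  unmapped <- setdiff(unique(hits$motif_id), motif_tf$motif_id)
  if (length(unmapped)) {
    warn(sprintf("motif(s) with no TF mapping skipped: %s",
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  linked <- hits |>
    inner_join(as_tibble(motif_tf), by = "motif_id") |>
    inner_join(select(as_tibble(regions), "region_id", "gene_id"),
               by = "region_id") |>
    distinct(.data$gene_id, .data$tf_id)

  ce <- filter(net$edges, .data$type == "ceRNA", .data$from %in% hub_lnc)
  keep <- semi_join(ce, linked, by = c(from = "gene_id", to = "tf_id"))
  nodes <- filter(net$nodes, .data$id %in% unique(c(keep$from, keep$to)))
  cerna_network(nodes, keep)
}

#' Gene-set over-representation (hypergeometric)
#'
#' For each set, tests whether the query genes overlap it more than
#' expected by chance, using the same hypergeometric upper tail as the
#' ceRNA pair test. Optional Benjamini-Hochberg adjustment across sets.
#'
#' @param query_genes Character vector (subset of `universe`).
#' @param gene_sets Named list of character vectors (subsets of `universe`).
#' @param universe Character vector of all considered genes.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `set`, `k` (overlap), `K` (set size), `n` (query size),
#'   `N` (universe size), `p`, and `p_adj` when adjusted.
#' @export
gene_set_overrepresentation <- function(query_genes, gene_sets, universe,
                                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!length(universe)) abort("empty universe.")
  if (!all(query_genes %in% universe)) abort("query genes must lie in the universe.")
  query_genes <- unique(query_genes)
  N <- length(unique(universe))
  out <- imap(gene_sets, function(gset, name) {
    gset <- intersect(unique(gset), universe)
    k <- length(intersect(query_genes, gset))
    p <- hypergeom_upper_tail(k, length(gset), length(query_genes), N)
    tibble(set = name, k = k, K = length(gset), n = length(query_genes), N = N,
           p = p)
  }) |> list_rbind()
  if (adjust == "BH") out$p_adj <- p.adjust(out$p, method = "BH")
  arrange(out, .data$p)
}
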