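# Shared-miRNA ceRNA pair inference: hypergeometric overlap test on the
# miRNA target sets of each lncRNA-TF pair, followed by an expression
# correlation filter, then assembly of the mixed ceRNA/PPI network.

#' Hypergeometric upper-tail probability of shared-miRNA overlap
#'
#' For a lncRNA targeted by `m_l` miRNAs and a TF targeted by `m_t`
#' miRNAs out of a universe of `N`, returns `P(X >= k)` where
#' `X ~ Hypergeometric(N, m_l, m_t)` — the probability of observing at
#' least the seen number of shared miRNAs by chance. Evaluated through
#' [stats::phyper()], which works in log space internally. Vectorised.
#'
#' @param k Observed shared-miRNA count(s).
#' @param m_l,m_t miRNA target-set sizes of the two partners.
#' @param N miRNA universe size.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10) # 5/210
#' @export
hypergeom_upper_tail <- function(k, m_l, m_t, N) {
  n <- max(length(k), length(m_l), length(m_t), length(N))
  k <- rep_len(as.numeric(k), n); m_l <- rep_len(as.numeric(m_l), n)
  m_t <- rep_len(as.numeric(m_t), n); N <- rep_len(as.numeric(N), n)
  if (any(k < 0 | m_l < 0 | m_t < 0 | N < 1)) abort("counts must be non-negative, N >= 1.")
  if (any(m_l > N | m_t > N)) abort("target-set sizes cannot exceed the universe N.")
  if (any(k > pmin(m_l, m_t))) abort("k cannot exceed min(m_l, m_t).")
  phyper(k - 1, m_l, N - m_l, m_t, lower.tail = FALSE)
}

#' Score all lncRNA-TF pairs for shared-miRNA excess
#'
#' Counts shared miRNAs for every (lncRNA, TF) combination across the
#' two interaction tables and attaches the hypergeometric upper-tail
#' p-value. By default only pairs sharing at least one miRNA are
#' returned; set `include_empty = TRUE` to also emit k = 0 pairs (p = 1).
#'
#' @param mirna_lncrna,mirna_tf Interaction tibbles as returned by
#'   [read_interaction_table()] (columns `source_id`, `target_id`).
#' @param universe miRNA universe size `N`; defaults to the number of
#'   distinct source miRNAs across both tables. May also be a character
#'   vector of miRNA ids.
#' @param include_empty Emit rows for pairs with no shared miRNA.
#' @return Tibble with columns `lncrna_id`, `tf_id`, `m_l`, `m_t`, `k`,
#'   `N`, `p`.
#' @export
score_all_pairs <- function(mirna_lncrna, mirna_tf, universe = NULL,
                            include_empty = FALSE) {
  mirna_lncrna <- distinct(as_tibble(mirna_lncrna), .data$source_id, .data$target_id)
  mirna_tf <- distinct(as_tibble(mirna_tf), .data$source_id, .data$target_id)
  if (nrow(mirna_lncrna) == 0L || nrow(mirna_tf) == 0L) {
    abort("both interaction tables must be non-empty.")
  }
  observed <- union(mirna_lncrna$source_id, mirna_tf$source_id)
  if (is.character(universe)) {
    if (!all(observed %in% universe)) abort("universe must contain every observed miRNA.")
    N <- length(universe)
  } else if (is.numeric(universe)) {
    if (universe < length(observed)) abort("universe smaller than observed miRNA set.")
    N <- as.integer(universe)
  } else {
    N <- length(observed)
  }
  if (N < 1L) abort("empty miRNA universe.")

  mirs <- factor(mirna_lncrna$source_id, levels = observed)
  lncs <- factor(mirna_lncrna$target_id)
  A <- Matrix_incidence(as.integer(mirs), as.integer(lncs),
                        length(observed), nlevels(lncs))
  mirs2 <- factor(mirna_tf$source_id, levels = observed)
  tfs <- factor(mirna_tf$target_id)
  B <- Matrix_incidence(as.integer(mirs2), as.integer(tfs),
                        length(observed), nlevels(tfs))
  K <- crossprod(A, B)                      # shared-miRNA counts, lnc x tf
  m_l <- colSums(A); m_t <- colSums(B)
  out <- tibble(
    lncrna_id = rep(levels(lncs), times = nlevels(tfs)),
    tf_id = rep(levels(tfs), each = nlevels(lncs)),
    m_l = rep(m_l, times = nlevels(tfs)),
    m_t = rep(m_t, each = nlevels(lncs)),
    k = as.vector(K),
    N = N
  )
  if (!include_empty) out <- filter(out, .data$k >= 1)
  out$p <- hypergeom_upper_tail(out$k, out$m_l, out$m_t, out$N)
  arrange(out, .data$lncrna_id, .data$tf_id)
}

# dense 0/1 incidence matrix (rows = miRNAs, cols = targets)
Matrix_incidence <- function(i, j, nrow, ncol) {
  m <- matrix(0L, nrow, ncol)
  m[cbind(i, j)] <- 1L
  m
}

#' Pearson correlation on pairwise-complete observations
#'
#' Product-moment correlation using only positions where both vectors
#' are observed; requires at least 3 complete pairs and non-zero
#' variance in both.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  ok <- complete.cases(x, y)
  if (sum(ok) < 3L) abort("need >= 3 paired non-missing observations.")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance.")
  }
  cor(x, y)
}

#' Filter pair scores by significance and expression correlation
#'
#' Retains exactly the pairs with `p < p_threshold` AND
#' `pcc > pcc_threshold` (both strict). Pairs whose members lack
#' expression rows (or whose correlation is undefined) are dropped with
#' a message reporting the count. Order-independent: the retained set
#' does not depend on the input row order.
#'
#' @param results Pair table from [score_all_pairs()].
#' @param expr Expression matrix (genes x samples) holding both members
#'   of each surviving pair.
#' @param p_threshold,pcc_threshold Strict cutoffs (defaults 0.05, 0.6).
#' @param keep_all Return all scored pairs with a `retained` flag instead
#'   of only the retained subset.
#' @return Tibble like `results` plus a `pcc` column (and `retained` if
#'   `keep_all`).
#' @export
filter_significant_pairs <- function(results, expr, p_threshold = 0.05,
                                     pcc_threshold = 0.6, keep_all = FALSE) {
  results <- as_tibble(results)
  have <- results$lncrna_id %in% rownames(expr) & results$tf_id %in% rownames(expr)
  if (any(!have)) {
    inform(sprintf("dropped %d pair(s) lacking expression.", sum(!have)))
    results <- results[have, , drop = FALSE]
  }
  # correlate only pairs that already clear the p cutoff; others keep NA
  pcc <- rep(NA_real_, nrow(results))
  idx <- which(results$p < p_threshold)
  if (length(idx)) {
    ex <- expr[unique(c(results$lncrna_id[idx], results$tf_id[idx])), , drop = FALSE]
    pcc[idx] <- vapply(idx, function(i) {
      x <- ex[results$lncrna_id[i], ]; y <- ex[results$tf_id[i], ]
      ok <- complete.cases(x, y)
      if (sum(ok) < 3L) return(NA_real_)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
      cor(x[ok], y[ok])
    }, numeric(1))
  }
  results$pcc <- pcc
  retained <- !is.na(results$p) & results$p < p_threshold &
    !is.na(results$pcc) & results$pcc > pcc_threshold
  if (keep_all) {
    results$retained <- retained
    return(results)
  }
  results[retained, , drop = FALSE]
}

#' Assemble the mixed ceRNA / PPI network
#'
#' Builds an undirected typed graph from the retained lncRNA-TF ceRNA
#' pairs plus TF-TF protein-protein interaction pairs. By default PPI
#' edges are kept only between TFs that already appear in at least one
#' significant ceRNA pair; `include_all_ppi = TRUE` adds every PPI TF as
#' a node. Self-loops and duplicate edges are removed; an id appearing
#' as both a lncRNA and a TF is an error.
#'
#' @param significant_pairs Tibble with `lncrna_id`, `tf_id` and (optionally)
#'   evidence columns `m_l`, `m_t`, `k`, `N`, `p`, `pcc`.
#' @param ppi Optional TF-TF interaction tibble (`source_id`, `target_id`).
#' @param include_all_ppi Keep PPI edges (and nodes) among TFs not present
#'   in any ceRNA pair.
#' @return A [cerna_network()].
#' @export
assemble_network <- function(significant_pairs, ppi = NULL, include_all_ppi = FALSE) {
  pairs <- as_tibble(significant_pairs)
  lnc_ids <- unique(pairs$lncrna_id)
  tf_ids <- unique(pairs$tf_id)
  ppi_edges <- NULL
  if (!is.null(ppi) && nrow(as_tibble(ppi))) {
    ppi <- distinct(as_tibble(ppi), .data$source_id, .data$target_id)
    ppi <- filter(ppi, .data$source_id != .data$target_id)
    if (include_all_ppi) {
      tf_ids <- union(tf_ids, unique(c(ppi$source_id, ppi$target_id)))
    } else {
      ppi <- filter(ppi, .data$source_id %in% tf_ids & .data$target_id %in% tf_ids)
    }
    if (nrow(ppi)) {
      ppi_edges <- tibble(from = ppi$source_id, to = ppi$target_id, type = "PPI")
    }
  }
  clash <- intersect(lnc_ids, tf_ids)
  if (length(clash)) {
    abort(sprintf("id(s) appear as both lncRNA and TF: %s",
                  paste(head(clash, 5), collapse = ", ")))
  }
  nodes <- bind_rows(
    tibble(id = lnc_ids, kind = "lncRNA"),
    tibble(id = tf_ids, kind = "TF")
  )
  evidence <- intersect(c("m_l", "m_t", "k", "N", "p", "pcc"), names(pairs))
  ce_edges <- tibble(from = pairs$lncrna_id, to = pairs$tf_id, type = "ceRNA")
  for (col in evidence) ce_edges[[col]] <- pairs[[col]]
  cerna_network(nodes, bind_rows(ce_edges, ppi_edges))
}
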