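# Seeded synthetic-data generators with planted ground truth. Each
# generator is fully deterministic given its seed, and the planted
# structure matches the assumptions of the downstream tests exactly:
# planted ceRNA pairs are enriched in shared miRNAs and correlated in
# expression, survival times follow proportional hazards by
# construction, and planted motif sites carry the motif consensus.

default_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate miRNA-target interaction tables with planted overlap
#'
#' Every miRNA targets every lncRNA and every TF independently with
#' probability `baseline_rate`. For each planted (lncRNA, TF) pair a set
#' of `shared_boost` additional miRNAs is wired to BOTH members,
#' guaranteeing an excess of shared miRNAs over the background.
#'
#' @param n_mirna,n_lncrna,n_tf Universe sizes.
#' @param baseline_rate Independent targeting probability in (0, 1)
#'   (0 is allowed for fully-planted constructions).
#' @param true_pairs Tibble with `lncrna_id`, `tf_id` (ids like
#'   `"LNC001"`, `"TF001"`), or an integer count of pairs to plant
#'   (matched by index).
#' @param shared_boost Number of guaranteed shared miRNAs per true pair
#'   (must not exceed `n_mirna`).
#' @param seed Integer seed.
#' @return List: `mirna_lncrna`, `mirna_tf` (interaction tibbles) and
#'   `truth` (list with `true_pairs`, `shared_boost`, `baseline_rate`).
#' @export
generate_interactions <- function(n_mirna, n_lncrna, n_tf, baseline_rate,
                                  true_pairs, shared_boost, seed = 1L) {
  if (baseline_rate < 0 || baseline_rate >= 1) abort("baseline_rate must be in [0, 1).")
  if (shared_boost > n_mirna) abort("shared_boost cannot exceed n_mirna.")
  mirna_ids <- default_ids("miR", n_mirna)
  lnc_ids <- default_ids("LNC", n_lncrna)
  tf_ids <- default_ids("TF", n_tf)
  if (is.numeric(true_pairs) && length(true_pairs) == 1L) {
    if (true_pairs > min(n_lncrna, n_tf)) abort("too many true pairs to plant.")
    true_pairs <- tibble(lncrna_id = lnc_ids[seq_len(true_pairs)],
                         tf_id = tf_ids[seq_len(true_pairs)])
  }
  true_pairs <- as_tibble(true_pairs)
  stopifnot(all(true_pairs$lncrna_id %in% lnc_ids), all(true_pairs$tf_id %in% tf_ids))

  withr::with_seed(seed, {
    A <- matrix(rbinom(n_mirna * n_lncrna, 1, baseline_rate), n_mirna, n_lncrna,
                dimnames = list(mirna_ids, lnc_ids))
    B <- matrix(rbinom(n_mirna * n_tf, 1, baseline_rate), n_mirna, n_tf,
                dimnames = list(mirna_ids, tf_ids))
    if (nrow(true_pairs) && shared_boost > 0) {
      for (i in seq_len(nrow(true_pairs))) {
        shared <- sample.int(n_mirna, shared_boost)
        A[shared, true_pairs$lncrna_id[i]] <- 1L
        B[shared, true_pairs$tf_id[i]] <- 1L
      }
    }
  })
  to_table <- function(M, kind) {
    idx <- which(M == 1L, arr.ind = TRUE)
    tibble(source_id = rownames(M)[idx[, 1]], target_id = colnames(M)[idx[, 2]],
           target_kind = kind) |> arrange(.data$source_id, .data$target_id)
  }
  list(
    mirna_lncrna = to_table(A, "lncRNA"),
    mirna_tf = to_table(B, "TF"),
    truth = list(true_pairs = true_pairs, shared_boost = shared_boost,
                 baseline_rate = baseline_rate, n_mirna = n_mirna)
  )
}

#' Generate log-scale expression with planted pair correlation
#'
#' Members of each planted pair share a standard-normal latent factor:
#' `x = sqrt(rho) * z_shared + sqrt(1 - rho) * z_own`, which gives the
#' pair an expected Pearson correlation of exactly `rho`. All other
#' genes are independent standard normals. Genes listed in
#' `shift_genes` receive an additive `group_shift` in tumor samples
#' relative to normals. Values are on the log scale; `noise_sd` scales
#' the overall spread.
#'
#' @param genes Character vector of gene ids (must include all planted
#'   pair members and `shift_genes`).
#' @param n_tumor,n_normal Sample counts (total >= 3).
#' @param true_pairs Tibble with `lncrna_id`, `tf_id`; both members get the
#'   shared factor. May be `NULL`.
#' @param rho Target pairwise correlation, |rho| < 1.
#' @param group_shift Tumor-vs-normal mean shift for `shift_genes`.
#' @param shift_genes Genes receiving the shift (default none).
#' @param noise_sd Overall scale (default 1).
#' @param seed Integer seed.
#' @return Numeric matrix genes x samples with a `samples` attribute
#'   (tibble: `sample_id`, `tissue`).
#' @export
generate_expression <- function(genes, n_tumor, n_normal, true_pairs = NULL,
                                rho = 0, group_shift = 0, shift_genes = character(),
                                noise_sd = 1, seed = 1L) {
  if (abs(rho) >= 1) abort("|rho| must be < 1.")
  n <- n_tumor + n_normal
  if (n < 3L) abort("need n_tumor + n_normal >= 3 for downstream correlations.")
  stopifnot(all(shift_genes %in% genes))
  sample_ids <- c(default_ids("TUM", n_tumor), default_ids("NOR", n_normal))
  tissue <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  withr::with_seed(seed, {
    mat <- matrix(rnorm(length(genes) * n), length(genes), n,
                  dimnames = list(genes, sample_ids))
    if (!is.null(true_pairs) && nrow(as_tibble(true_pairs))) {
      tp <- as_tibble(true_pairs)
      stopifnot(all(tp$lncrna_id %in% genes), all(tp$tf_id %in% genes))
      for (i in seq_len(nrow(tp))) {
        z <- rnorm(n)
        for (g in c(tp$lncrna_id[i], tp$tf_id[i])) {
          mat[g, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
        }
      }
    }
  })
  mat <- mat * noise_sd
  if (length(shift_genes) && group_shift != 0) {
    mat[shift_genes, tissue == "tumor"] <-
      mat[shift_genes, tissue == "tumor"] + group_shift
  }
  attr(mat, "samples") <- tibble(sample_id = sample_ids, tissue = tissue)
  mat
}

#' Sample annotations attached to a generated expression matrix
#'
#' @param expr Matrix from [generate_expression()].
#' @return Tibble with `sample_id`, `tissue`.
#' @export
expression_samples <- function(expr) {
  s <- attr(expr, "samples")
  if (is.null(s)) abort("matrix carries no sample annotations.")
  s
}

#' Generate exponential survival under proportional hazards
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(sum_g coef_g * expr[g, sample])`; censoring
#' times are independent exponentials with rate `censor_rate`
#' (`censor_rate = 0` disables censoring). Proportional hazards holds by
#' construction.
#'
#' @param expr Expression matrix (genes x samples).
#' @param risk_genes Named numeric vector of true log-hazard coefficients
#'   (names must be rows of `expr`); may be empty for a null cohort.
#' @param baseline_hazard Positive baseline rate.
#' @param censor_rate Non-negative censoring rate.
#' @param seed Integer seed.
#' @return Clinical tibble: `sample_id`, `time`, `event`, `tissue` (when
#'   the matrix carries sample annotations).
#' @export
generate_survival <- function(expr, risk_genes = numeric(), baseline_hazard = 0.1,
                              censor_rate = 0.02, seed = 1L) {
  if (baseline_hazard <= 0) abort("baseline_hazard must be > 0.")
  if (censor_rate < 0) abort("censor_rate must be >= 0.")
  if (length(risk_genes)) {
    missing_g <- setdiff(names(risk_genes), rownames(expr))
    if (length(missing_g)) abort("risk_genes must be rows of expr.")
  }
  n <- ncol(expr)
  lp <- if (length(risk_genes)) {
    as.vector(crossprod(expr[names(risk_genes), , drop = FALSE], risk_genes))
  } else rep(0, n)
  withr::with_seed(seed, {
    t_event <- rexp(n, rate = baseline_hazard * exp(lp))
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
  })
  out <- tibble(
    sample_id = colnames(expr),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
  s <- attr(expr, "samples")
  if (!is.null(s)) out <- left_join(out, s, by = "sample_id")
  out
}

#' Generate background DNA regions with planted motif consensus sites
#'
#' Regions are i.i.d. background nucleotides at GC composition `gc`. At
#' each planted site the motif's consensus (per-column argmax) is
#' written, reverse-complemented when the site's strand is `-`. Sites
#' overlapping within a region, or extending past the region end, are
#' errors.
#'
#' @param n_regions Number of regions (ids `REG001`, ...).
#' @param region_len Length of each region in bp.
#' @param motifs List of [make_pwm()] objects (named by motif id or not).
#' @param planted_sites Tibble with `region_id`, `motif_id`, `position`
#'   (0-based offset), `strand`; may be empty.
#' @param gc GC fraction of the background (default 0.5).
#' @param seed Integer seed.
#' @return List: `sequences` (named character), `regions` (BED-style
#'   tibble with `gene_id = region_id`), `truth` (the planted site table).
#' @export
generate_regions_with_motifs <- function(n_regions, region_len, motifs,
                                         planted_sites = NULL, gc = 0.5,
                                         seed = 1L) {
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  names(motifs) <- vapply(motifs, function(m) m$motif_id, character(1))
  region_ids <- default_ids("REG", n_regions)
  planted_sites <- if (is.null(planted_sites)) {
    tibble(region_id = character(), motif_id = character(),
           position = integer(), strand = character())
  } else as_tibble(planted_sites)
  if (nrow(planted_sites)) {
    stopifnot(all(planted_sites$region_id %in% region_ids),
              all(planted_sites$motif_id %in% names(motifs)),
              all(planted_sites$strand %in% c("+", "-")))
    widths <- vapply(motifs[planted_sites$motif_id],
                     function(m) nrow(m$matrix), integer(1))
    if (any(planted_sites$position < 0 |
              planted_sites$position + widths > region_len)) {
      abort("planted site extends past the region end.")
    }
    for (rid in unique(planted_sites$region_id)) {
      s <- planted_sites[planted_sites$region_id == rid, ]
      wd <- vapply(motifs[s$motif_id], function(m) nrow(m$matrix), integer(1))
      o <- order(s$position)
      pos <- s$position[o]; wd <- wd[o]
      if (any(pos[-1] < (pos + wd)[-length(pos)])) {
        abort(sprintf("overlapping planted sites in region %s.", rid))
      }
    }
  }
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(n_regions), function(i) {
      paste(sample(BASES, region_len, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
  })
  names(seqs) <- region_ids
  if (nrow(planted_sites)) {
    for (i in seq_len(nrow(planted_sites))) {
      m <- motifs[[planted_sites$motif_id[i]]]
      word <- consensus_sequence(m)
      if (planted_sites$strand[i] == "-") word <- revcomp(word)
      rid <- planted_sites$region_id[i]
      pos <- planted_sites$position[i]
      substr(seqs[[rid]], pos + 1L, pos + nchar(word)) <- word
    }
  }
  regions <- tibble(region_id = region_ids, chrom = region_ids,
                    start = 0L, end = as.integer(region_len), strand = "+",
                    kind = "enhancer", gene_id = region_ids)
  list(sequences = seqs, regions = regions, truth = planted_sites)
}
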