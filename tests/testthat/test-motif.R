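sharp_pwm <- function(id = "SHARP", word = "ACGTAC") {
  bases <- strsplit(word, "")[[1]]
  mat <- t(vapply(bases, function(b) {
    p <- rep(0.01, 4)
    p[match(b, c("A", "C", "G", "T"))] <- 0.97
    p
  }, numeric(4)))
  rownames(mat) <- NULL
  make_pwm(mat, id)
}

test_that("promoters are strand-aware +/- flank windows around the TSS", {
  ann <- tibble::tibble(
    gene_id = c("Gp", "Gm", "Gc"), chrom = "chr1",
    start = c(10000L, 10000L, 500L), end = c(20000L, 20000L, 900L),
    strand = c("+", "-", "+")
  )
  pr <- promoter_regions(ann, flank = 2000)
  expect_equal(pr$start[1], 8000L)
  expect_equal(pr$end[1], 12000L)
  # minus strand: TSS = end - 1 = 19999
  expect_equal(pr$start[2], 17999L)
  expect_equal(pr$end[2], 21999L)
  # clipped at contig start
  expect_equal(pr$start[3], 0L)
  expect_equal(pr$end[3], 2500L)
  expect_true(all(pr$kind == "promoter"))

  ann$strand[1] <- "?"
  expect_error(promoter_regions(ann), "strand")
})

test_that("scanning the consensus yields the maximal-score hit at offset 0", {
  pwm <- sharp_pwm()
  hits <- pwm_scan(consensus_sequence(pwm), pwm, p_threshold = 1e-3)
  fwd <- dplyr::filter(hits, strand == "+")
  expect_equal(fwd$start, 0L)
  # p of the top score = background probability of the top-scoring word set
  oracle <- pwm_tail_oracle(pwm)
  expect_equal(fwd$p, oracle(round(1000 * fwd$score)), tolerance = 1e-12)
})

test_that("exact p-values equal the 4^w enumeration for small motifs", {
  pwms <- list(
    sharp_pwm("S4", "ACGT"),
    make_pwm(matrix(c(0.7, 0.1, 0.1, 0.1,
                      0.1, 0.5, 0.2, 0.2,
                      0.4, 0.3, 0.2, 0.1,
                      0.1, 0.1, 0.1, 0.7,
                      0.25, 0.25, 0.25, 0.25), ncol = 4, byrow = TRUE), "W5"),
    sharp_pwm("S6", "ACGTAC")
  )
  seqs <- withr::with_seed(21, vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  }, character(1)))
  for (pwm in pwms) {
    oracle <- pwm_tail_oracle(pwm)
    for (sq in seqs) {
      hits <- pwm_scan(sq, pwm, p_threshold = 1)  # every window reported
      expect_gt(nrow(hits), 0)
      expect_equal(hits$p,
                   vapply(round(1000 * hits$score), oracle, numeric(1)),
                   tolerance = 1e-12)
      # p monotone non-increasing in score across all offsets
      o <- order(hits$score)
      expect_true(all(diff(hits$p[o]) <= 1e-15))
    }
  }
})

test_that("reverse-complement scanning is strand-symmetric", {
  pwm <- sharp_pwm("S6", "ACGTTG")
  sq <- withr::with_seed(31, paste(sample(c("A", "C", "G", "T"), 400,
                                          replace = TRUE), collapse = ""))
  h_fwd <- pwm_scan(sq, pwm, p_threshold = 1)
  h_rc <- pwm_scan(revcomp_chr(sq), pwm, p_threshold = 1)
  L <- nchar(sq); w <- 6L
  # a + hit at offset i maps to a - hit at L - w - i on the reverse complement
  mirror <- function(h) {
    tibble::tibble(start = as.integer(L - w - h$start),
                   strand = ifelse(h$strand == "+", "-", "+"),
                   score = h$score, p = h$p) |>
      dplyr::arrange(start, strand)
  }
  expect_equal(mirror(h_fwd),
               dplyr::arrange(dplyr::select(h_rc, start, strand, score, p),
                              start, strand))
})

test_that("windows with N are skipped and short sequences yield empty results", {
  pwm <- sharp_pwm("S4", "ACGT")
  hits <- pwm_scan("NNACGTNN", pwm, p_threshold = 1)
  # only offsets 2..3 avoid N on the forward scan... both strands share windows
  expect_true(all(hits$start == 2L))
  expect_equal(nrow(pwm_scan("AC", pwm)), 0L)
})

test_that("planted consensus sites are recovered and false hits match calibration", {
  pwm <- sharp_pwm("S8", "ACGTTGCA")
  sites <- tibble::tibble(region_id = c("REG001", "REG002"), motif_id = "S8",
                          position = c(120L, 500L), strand = c("+", "-"))
  gen <- generate_regions_with_motifs(2, 1000, list(pwm), sites, seed = 51)
  hits <- scan_regions(gen$sequences, pwm)
  expect_true(any(hits$region_id == "REG001" & hits$start == 120 & hits$strand == "+"))
  expect_true(any(hits$region_id == "REG002" & hits$start == 500 & hits$strand == "-"))

  # false-hit calibration on pure background, against the achieved level
  # computed by independent enumeration (discrete scores make the nominal
  # threshold an upper bound)
  w <- 8; L <- 2000; n_seq <- 60
  bg <- generate_regions_with_motifs(n_seq, L, list(pwm), NULL, seed = 52)
  hits_bg <- scan_regions(bg$sequences, pwm, p_threshold = 1e-4)
  alpha_hat <- achieved_alpha(pwm, 1e-4)
  expect_lte(alpha_hat, 1e-4)
  expected <- 2 * (L - w + 1) * n_seq * alpha_hat
  expect_lt(abs(nrow(hits_bg) - expected), 3 * sqrt(expected) + 1)
})

test_that("crosstalk network keeps only hub-lncRNA ceRNA edges with motif support", {
  # 5 lncRNAs with descending degree; L1 is the single top-20% hub
  pairs <- tibble::tibble(
    lncrna_id = c("L1", "L1", "L1", "L2", "L2", "L3", "L4", "L5"),
    tf_id = c("T1", "T2", "T3", "T1", "T2", "T1", "T2", "T3")
  )
  net <- assemble_network(pairs)
  regions <- tibble::tibble(region_id = c("R1", "R2"), gene_id = c("L1", "L2"))
  hits <- tibble::tibble(region_id = c("R1", "R2"), motif_id = c("M_T1", "M_T2"))
  motif_tf <- tibble::tibble(motif_id = c("M_T1", "M_T2"), tf_id = c("T1", "T2"))
  xt <- build_crosstalk_network(net, hits, regions, motif_tf, hub_fraction = 0.20)
  # only (L1, T1): L2 is not a hub, and T2/T3 have no hit in L1's regions
  expect_equal(nrow(xt$edges), 1L)
  expect_equal(xt$edges$from, "L1")
  expect_equal(xt$edges$to, "T1")
  # always a subset of the input ceRNA edges
  expect_true(all(paste(xt$edges$from, xt$edges$to) %in%
                    paste(net$edges$from, net$edges$to)))

  # no hits -> empty network
  xt0 <- build_crosstalk_network(net, hits[0, ], regions, motif_tf)
  expect_equal(nrow(xt0$edges), 0L)

  # unmapped motifs warn and are skipped
  expect_warning(
    build_crosstalk_network(net, tibble::tibble(region_id = "R1", motif_id = "MX"),
                            regions, motif_tf),
    "no TF mapping")
})

test_that("planted TF motifs recover exactly the planted crosstalk pairs", {
  sim <- generate_interactions(386, 10, 8, 0.05, 4, 8, seed = 61)
  sc <- score_all_pairs(sim$mirna_lncrna, sim$mirna_tf, universe = 386)
  genes <- c(sprintf("LNC%03d", 1:10), sprintf("TF%03d", 1:8))
  expr <- generate_expression(genes, 150, 150, sim$truth$true_pairs, rho = 0.8,
                              seed = 62)
  sig <- filter_significant_pairs(sc, expr)
  net <- assemble_network(sig)
  tp <- sim$truth$true_pairs
  # one distinct sharp motif per planted TF, planted only in the partner's region
  pwms <- lapply(seq_len(nrow(tp)), function(i) {
    sharp_pwm(paste0("M_", tp$tf_id[i]),
              c("ACGTTGCA", "TTGACGCA", "GCATTACG", "CCGATAGT")[i])
  })
  lnc_hubs <- dplyr::filter(node_metrics(net), kind == "lncRNA")
  regions <- tibble::tibble(region_id = paste0(tp$lncrna_id, "_prom"),
                            gene_id = tp$lncrna_id)
  seqs <- generate_regions_with_motifs(
    nrow(tp), 800, pwms,
    tibble::tibble(region_id = sprintf("REG%03d", seq_len(nrow(tp))),
                   motif_id = vapply(pwms, function(m) m$motif_id, character(1)),
                   position = 100L, strand = "+"),
    seed = 63)
  names(seqs$sequences) <- regions$region_id
  hits <- scan_regions(seqs$sequences, pwms)
  motif_tf <- tibble::tibble(motif_id = vapply(pwms, function(m) m$motif_id, character(1)),
                             tf_id = tp$tf_id)
  xt <- build_crosstalk_network(net, hits, regions, motif_tf, hub_fraction = 1)
  got <- paste(xt$edges$from, xt$edges$to)
  planted <- paste(tp$lncrna_id, tp$tf_id)
  expect_setequal(got, intersect(planted, paste(net$edges$from, net$edges$to)))
})

test_that("gene-set over-representation shares the hypergeometric oracle", {
  universe <- sprintf("G%02d", 1:12)
  sets <- list(hitset = universe[1:4], other = universe[9:12],
               half = universe[3:8])
  res <- gene_set_overrepresentation(universe[1:4], sets, universe, adjust = "BH")
  expect_equal(res$p[res$set == "hitset"],
               hyper_tail_oracle(4, 4, 4, 12), tolerance = 1e-12)
  expect_equal(res$p[res$set == "other"], 1)
  # BH adjustment is monotone in raw p
  o <- order(res$p)
  expect_true(all(diff(res$p_adj[o]) >= -1e-15))
  expect_error(gene_set_overrepresentation("G01", sets, character()), "universe")
})
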