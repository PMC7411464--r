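# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is written from first principles so it can
# cross-check the package implementation.

# ---- fixture builders -------------------------------------------------

# cerna_network from a bare undirected edge list (all nodes TF, PPI edges)
graph_net <- function(from, to, extra_nodes = character()) {
  ids <- sort(unique(c(from, to, extra_nodes)))
  cerna_network(
    nodes = tibble::tibble(id = ids, kind = "TF"),
    edges = tibble::tibble(from = from, to = to, type = "PPI")
  )
}

clique_edges <- function(ids) {
  cmb <- t(combn(ids, 2))
  tibble::tibble(from = cmb[, 1], to = cmb[, 2])
}

complete_net <- function(n, prefix = "K") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  e <- clique_edges(ids)
  graph_net(e$from, e$to)
}

random_net <- function(n, p_edge, seed, prefix = "N") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  cmb <- t(combn(ids, 2))
  keep <- withr::with_seed(seed, stats::runif(nrow(cmb)) < p_edge)
  graph_net(cmb[keep, 1], cmb[keep, 2], extra_nodes = ids)
}

# small mixed ceRNA/PPI network with given class sizes
random_mixed_net <- function(n_lnc, n_tf, n_ce, n_ppi, seed) {
  lnc <- sprintf("L%03d", seq_len(n_lnc))
  tfs <- sprintf("T%03d", seq_len(n_tf))
  withr::with_seed(seed, {
    ce_all <- expand.grid(from = lnc, to = tfs, stringsAsFactors = FALSE)
    ce <- ce_all[sample.int(nrow(ce_all), n_ce), ]
    ppi_all <- as.data.frame(t(combn(tfs, 2)), stringsAsFactors = FALSE)
    names(ppi_all) <- c("from", "to")
    ppi <- ppi_all[sample.int(nrow(ppi_all), n_ppi), ]
  })
  cerna_network(
    nodes = tibble::tibble(id = c(lnc, tfs),
                           kind = rep(c("lncRNA", "TF"), c(n_lnc, n_tf))),
    edges = dplyr::bind_rows(
      tibble::tibble(from = ce$from, to = ce$to, type = "ceRNA"),
      tibble::tibble(from = ppi$from, to = ppi$to, type = "PPI")
    )
  )
}

# ---- combinatorial / statistical oracles ------------------------------

# hypergeometric upper tail by direct combinatorial sum
hyper_tail_oracle <- function(k, m_l, m_t, N) {
  j <- k:min(m_l, m_t)
  sum(choose(m_l, j) * choose(N - m_l, m_t - j)) / choose(N, m_t)
}

# betweenness by BFS distances + shortest-path counting (Brandes-free)
betweenness_oracle <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- igraph::distances(g)
  # sigma[s, v]: number of shortest s-v paths, by DP over distance layers
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(D[s, ]))
    for (d in sort(unique(D[s, reach][D[s, reach] > 0]))) {
      for (v in reach[D[s, reach] == d]) {
        pred <- which(A[, v] == 1 & D[s, ] == d - 1)
        sigma[s, v] <- sum(sigma[s, pred])
      }
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  stats::setNames(bc, igraph::V(g)$name)
}

# highest k-core of an adjacency matrix by iterative peeling, from scratch
highest_core_oracle <- function(A) {
  best <- NULL
  for (k in seq_len(nrow(A))) {
    B <- A
    repeat {
      deg <- rowSums(B)
      drop <- which(deg < k)
      if (!length(drop) || nrow(B) == 0) break
      B <- B[-drop, -drop, drop = FALSE]
    }
    if (nrow(B) > 0) best <- list(k = k, A = B) else break
  }
  best
}

# MCODE vertex weight from first principles
mcode_weight_oracle <- function(net, degree_cutoff = 2) {
  g <- as_igraph(net)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  ids <- igraph::V(g)$name
  deg <- rowSums(A)
  w <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    if (deg[i] < degree_cutoff) next
    nb <- which(A[i, ] == 1)
    nb <- nb[deg[nb] >= degree_cutoff]
    vs <- unique(c(i, nb))
    if (length(vs) < 2) next
    core <- highest_core_oracle(A[vs, vs, drop = FALSE])
    if (is.null(core)) next
    nv <- nrow(core$A)
    dens <- if (nv < 2) 0 else sum(core$A) / (nv * (nv - 1))
    w[i] <- core$k * dens
  }
  w
}

# Efron-tie Cox log partial likelihood for one covariate
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  eta <- beta * x
  r <- exp(eta)
  for (t in sort(unique(time[event == 1]))) {
    Dset <- which(time == t & event == 1)
    Rset <- which(time >= t)
    d <- length(Dset)
    sumD <- sum(r[Dset])
    sumR <- sum(r[Rset])
    ll <- ll + sum(eta[Dset])
    for (l in seq_len(d)) {
      ll <- ll - log(sumR - (l - 1) / d * sumD)
    }
  }
  ll
}

# exact two-sided rank-sum p by full enumeration of group assignments
wilcox_exact_oracle <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  rk <- rank(x)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(length(x), n1)
  w_all <- apply(idx, 2, function(s) sum(rk[s]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# exact PWM score tail by enumerating all 4^w words with the same
# integer discretisation the scanner states (round(gran * log2 odds))
pwm_tail_oracle <- function(pwm, background = rep(0.25, 4), granularity = 1000) {
  p <- pwm$matrix
  p[p == 0] <- 1e-3
  S <- round(granularity * log2(sweep(p, 2, background, "/")))
  w <- nrow(S)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    b <- words[i, ]
    sc[i] <- sum(S[cbind(seq_len(w), b)])
    pr[i] <- prod(background[b])
  }
  function(s_int) sum(pr[sc >= s_int])
}

# ---- PWM helpers ------------------------------------------------------

# integer score matrix identical in definition to the scanner's contract
pwm_int_scores_test <- function(pwm, background = rep(0.25, 4), gran = 1000) {
  p <- pwm$matrix
  p[p == 0] <- 1e-3
  round(gran * log2(sweep(p, 2, background, "/")))
}

# achieved level of the discrete test at nominal threshold t, by enumeration
achieved_alpha <- function(pwm, t, background = rep(0.25, 4)) {
  S <- pwm_int_scores_test(pwm, background)
  w <- nrow(S)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- apply(words, 1, function(b) sum(S[cbind(seq_len(w), b)]))
  pr <- apply(words, 1, function(b) prod(background[b]))
  ts <- sort(unique(sc), decreasing = TRUE)
  tails <- cumsum(vapply(ts, function(s) sum(pr[sc == s]), numeric(1)))
  hit_levels <- tails[tails < t]
  if (!length(hit_levels)) 0 else max(hit_levels)
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}
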