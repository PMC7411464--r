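# Network topology: degree diagnostics, power-law fit, average path
# length with a degree-preserving rewiring null, centralities, hubs.

#' Per-node topology metrics
#'
#' Degree, betweenness, closeness and mean shortest-path distance to the
#' reachable nodes (unweighted BFS distances throughout).
#'
#' @param net A [cerna_network()] or bare edge table.
#' @return Tibble with columns `id`, `kind`, `degree`, `betweenness`,
#'   `closeness`, `mean_distance`, sorted by decreasing degree.
#' @export
node_metrics <- function(net) {
  net <- as_cerna_graph(net)
  g <- as_igraph(net)
  d <- igraph::distances(g)
  diag(d) <- NA
  mean_dist <- apply(d, 1, function(r) mean(r[is.finite(r)], na.rm = TRUE))
  tibble(
    id = igraph::V(g)$name,
    kind = igraph::V(g)$kind,
    degree = as.integer(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE)),
    closeness = unname(suppressWarnings(igraph::closeness(g))),
    mean_distance = unname(mean_dist)
  ) |> arrange(desc(.data$degree), .data$id)
}

#' Least-squares power-law fit on a degree frequency table
#'
#' Fits `log10 f(k) = intercept + slope * log10 k` over degrees `k >= 1`
#' with frequency `f(k) > 0` (the regression convention of network
#' analyzer tools, which is what yields an R-squared; maximum-likelihood
#' exponent fitting is a different estimator and is not used here).
#'
#' @param degree Degrees (k).
#' @param frequency Node counts at each degree.
#' @return Object of class `powerlaw_fit` with `slope`, `intercept`,
#'   `r_squared`, `n_points` and the fitted table.
#' @export
fit_power_law <- function(degree, frequency) {
  keep <- degree >= 1 & frequency > 0
  degree <- degree[keep]; frequency <- frequency[keep]
  if (length(unique(degree)) < 3L) {
    abort("need >= 3 distinct degrees with non-zero frequency.")
  }
  lx <- log10(degree); ly <- log10(frequency)
  fit <- lm(ly ~ lx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = 1 - ss_res / ss_tot,
    n_points = length(degree),
    data = tibble(degree = degree, frequency = frequency)
  ), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> slope %.3f, R^2 %.3f over %d degree classes\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_points = x$n_points)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) x$data

#' Power-law fit of a network's degree distribution
#'
#' @param net A [cerna_network()] or bare edge table.
#' @return A [fit_power_law()] object.
#' @export
degree_distribution_fit <- function(net) {
  net <- as_cerna_graph(net)
  deg <- igraph::degree(as_igraph(net))
  tab <- table(deg[deg >= 1])
  fit_power_law(as.integer(names(tab)), as.integer(tab))
}

#' Average path length
#'
#' Mean BFS shortest-path distance over all unordered pairs of distinct
#' nodes lying in the same connected component (disconnected pairs are
#' excluded, the common tool convention).
#'
#' @param net A [cerna_network()] or bare edge table.
#' @return A single number >= 1.
#' @export
average_path_length <- function(net) {
  net <- as_cerna_graph(net)
  if (nrow(net$edges) == 0L) abort("average path length undefined: no edges.")
  igraph::mean_distance(as_igraph(net), directed = FALSE, unconnected = TRUE)
}

#' Degree-preserving rewiring of a typed network
#'
#' Randomises the network by repeated double-edge swaps performed
#' independently within each edge-type class: ceRNA swaps exchange TF
#' endpoints between two lncRNA-TF edges (preserving bipartiteness),
#' PPI swaps stay TF-TF. Every node keeps its exact degree, per-type
#' edge counts are unchanged, and no self-loops or duplicate edges are
#' introduced. `n_swaps_factor * |E|` swaps are attempted per class.
#'
#' @param net A [cerna_network()].
#' @param n_swaps_factor Attempted swaps per edge (default 10).
#' @param seed Optional integer seed (local to this call).
#' @return A rewired [cerna_network()] (edge evidence columns are not
#'   carried over; they describe the original pairs). If no swap could
#'   be performed the input is returned with a warning.
#' @export
rewire_degree_preserving <- function(net, n_swaps_factor = 10, seed = NULL) {
  stopifnot(inherits(net, "cerna_network"))
  run <- function() rewire_impl(net, n_swaps_factor)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

rewire_impl <- function(net, n_swaps_factor) {
  ids <- net$nodes$id
  idx <- setNames(seq_along(ids) - 1L, ids)
  pieces <- list()
  total_success <- 0L
  for (ty in unique(net$edges$type)) {
    e <- filter(net$edges, .data$type == ty)
    mat <- cbind(idx[e$from], idx[e$to])
    storage.mode(mat) <- "integer"
    res <- rewire_edges_cpp(mat, bipartite = identical(ty, "ceRNA"),
                            n_attempts = as.integer(ceiling(n_swaps_factor * nrow(mat))))
    total_success <- total_success + attr(res, "n_success")
    pieces[[ty]] <- tibble(from = ids[res[, 1] + 1L], to = ids[res[, 2] + 1L],
                           type = ty)
  }
  if (total_success == 0L && nrow(net$edges) > 0L) {
    warn("graph too constrained to swap; returning a copy of the input.")
  }
  cerna_network(net$nodes, bind_rows(pieces))
}

#' Average-path-length null test against degree-preserving rewirings
#'
#' Generates `n_random` degree-conserved random networks by
#' [rewire_degree_preserving()] and counts how many have an average path
#' length strictly shorter than the observed network. The empirical
#' p-value is that count divided by `n_random` (no continuity
#' correction).
#'
#' @param net A [cerna_network()].
#' @param n_random Number of random replicates (default 1000).
#' @param n_swaps_factor Attempted swaps per edge per replicate.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return Object of class `apl_null` with `apl_real`, `apl_random`,
#'   `count_shorter`, `empirical_p`, `n_random`.
#' @export
apl_null_test <- function(net, n_random = 1000, n_swaps_factor = 10, seed = 1L) {
  stopifnot(inherits(net, "cerna_network"))
  apl_real <- average_path_length(net)
  seeds <- derive_seeds(seed, n_random)
  apl_random <- vapply(seeds, function(s) {
    average_path_length(rewire_degree_preserving(net, n_swaps_factor, seed = s))
  }, numeric(1))
  count_shorter <- sum(apl_random < apl_real)
  structure(list(
    apl_real = apl_real, apl_random = apl_random,
    count_shorter = count_shorter,
    empirical_p = count_shorter / n_random,
    n_random = n_random
  ), class = "apl_null")
}

#' @export
print.apl_null <- function(x, ...) {
  cat(sprintf("<apl_null> real APL %.4f vs %d rewired replicates; %d shorter (p = %.4g)\n",
              x$apl_real, x$n_random, x$count_shorter, x$empirical_p))
  invisible(x)
}

#' @export
glance.apl_null <- function(x, ...) {
  tibble(apl_real = x$apl_real, apl_random_mean = mean(x$apl_random),
         count_shorter = x$count_shorter, n_random = x$n_random,
         empirical_p = x$empirical_p)
}

#' Select hub nodes by degree
#'
#' Hubs are the top `floor(fraction * |V|)` nodes by degree. Ties at the
#' cutoff are broken by higher betweenness, then lexicographic id, so
#' the selection is deterministic and independent of node order.
#'
#' @param net A [cerna_network()].
#' @param fraction Top fraction of nodes to keep (default 0.10).
#' @return Tibble of hubs (`id`, `kind`, `degree`, `betweenness`) with
#'   attribute `fraction`.
#' @export
select_hubs <- function(net, fraction = 0.10) {
  net <- as_cerna_graph(net)
  metrics <- node_metrics(net)
  n_hubs <- floor(fraction * nrow(metrics))
  ranked <- arrange(metrics, desc(.data$degree), desc(.data$betweenness), .data$id)
  out <- select(head(ranked, n_hubs), "id", "kind", "degree", "betweenness")
  attr(out, "fraction") <- fraction
  out
}

#' Hub-hub subnetwork
#'
#' Vertex-induced subgraph on the hub set, edge attributes preserved.
#'
#' @param net A [cerna_network()].
#' @param hubs Hub tibble from [select_hubs()] or a character vector of ids.
#' @return A [cerna_network()].
#' @export
hub_subnetwork <- function(net, hubs) {
  ids <- if (is.character(hubs)) hubs else hubs$id
  induce_subnetwork(net, ids)
}
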