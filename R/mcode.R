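# MCODE-style dense-module detection, written from scratch on igraph
# primitives. Vertex weighting uses the core-clustering coefficient
# (density of the highest k-core of a vertex's closed neighborhood,
# multiplied by that core's k); complexes grow greedily from the
# highest-weight unvisited seed and are post-processed by a k-core
# filter and an optional haircut.

#' MCODE vertex weighting
#'
#' For each node `v` with degree at least `degree_cutoff`: take the
#' closed neighborhood of `v` (v plus neighbors, excluding neighbors
#' whose degree in the full graph is below `degree_cutoff`), find its
#' highest k-core, and set `weight(v) = k_max * density(core)` where
#' density is `2|E|/(|V|(|V|-1))`. Nodes below the degree cutoff, or with
#' an empty core, score 0.
#'
#' @param net A [cerna_network()] or bare edge table (`from`, `to`).
#' @param degree_cutoff Minimum degree for a node to be scored (default 2).
#' @return Tibble with `id`, `weight`, `core_k`, `core_density`.
#' @export
mcode_vertex_weights <- function(net, degree_cutoff = 2) {
  net <- as_cerna_graph(net)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  ids <- igraph::V(g)$name
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  res <- lapply(seq_along(ids), function(i) {
    if (deg[i] < degree_cutoff) return(c(0, 0, 0))
    nb <- as.integer(adj[[i]])
    nb <- nb[deg[nb] >= degree_cutoff]
    vs <- unique(c(i, nb))
    if (length(vs) < 2L) return(c(0, 0, 0))
    sub <- igraph::induced_subgraph(g, vs)
    core <- igraph::coreness(sub)
    k_max <- max(core)
    if (k_max == 0) return(c(0, 0, 0))
    core_g <- igraph::induced_subgraph(sub, which(core >= k_max))
    nv <- igraph::vcount(core_g)
    dens <- if (nv < 2L) 0 else 2 * igraph::ecount(core_g) / (nv * (nv - 1))
    c(k_max * dens, k_max, dens)
  })
  res <- do.call(rbind, res)
  tibble(id = ids, weight = res[, 1], core_k = as.integer(res[, 2]),
         core_density = res[, 3])
}

#' MCODE-style dense-module detection
#'
#' Greedy complex prediction: seeds are taken in order of decreasing
#' vertex weight (ties: higher degree, then lexicographic id, so results
#' do not depend on node insertion order). From each unvisited seed the
#' complex grows breadth-first up to `max_depth`, admitting a neighbor
#' `w` when `weight(w) > seed_weight * (1 - node_score_cutoff)`; each
#' node belongs to at most one complex. Post-processing drops complexes
#' whose `k_core`-core is empty, optionally removes singly-connected
#' nodes (`haircut`), keeps the largest connected component if the
#' trimming disconnected the complex, and finally retains complexes with
#' score strictly greater than `score_min`, where
#' `score = density * |V|`.
#'
#' @param net A [cerna_network()] or bare edge table.
#' @param score_min Keep modules with score strictly above this (default 5).
#' @param degree_cutoff Vertex-weighting degree cutoff (default 2).
#' @param node_score_cutoff Expansion tolerance in (0, 1) (default 0.2).
#' @param max_depth Maximum BFS depth from the seed (default 100).
#' @param k_core Discard complexes without a non-empty k-core (default 2).
#' @param haircut Remove degree-1 nodes from each complex (default TRUE).
#' @param fluff Add boundary neighbors whose closed-neighborhood density
#'   exceeds `node_score_cutoff` (default FALSE; fluffed nodes may overlap
#'   between modules, as in the original formulation).
#' @return Object of class `mcode_result`: list with `summary` tibble
#'   (one row per module: nodes, kinds, edges, density, score, seed) and
#'   `modules`, a list of [cerna_network()] objects, ordered by
#'   decreasing score.
#' @export
mcode <- function(net, score_min = 5, degree_cutoff = 2, node_score_cutoff = 0.2,
                  max_depth = 100, k_core = 2, haircut = TRUE, fluff = FALSE) {
  net <- as_cerna_graph(net)
  g <- as_igraph(net)
  ids <- igraph::V(g)$name
  wt_tab <- mcode_vertex_weights(net, degree_cutoff)
  w <- setNames(wt_tab$weight, wt_tab$id)[ids]
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))

  seed_order <- order(-w, -deg, ids)
  visited <- rep(FALSE, length(ids))
  raw <- list()
  for (s in seed_order) {
    if (visited[s] || w[s] <= 0) next
    thr <- w[s] * (1 - node_score_cutoff)
    members <- s
    visited[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- integer()
      for (v in frontier) {
        nbs <- as.integer(adj[[v]])
        nbs <- nbs[order(ids[nbs])]           # canonical neighbor order
        for (u in nbs) {
          if (!visited[u] && w[u] > thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    raw[[length(raw) + 1L]] <- list(members = members, seed = ids[s])
  }

  modules <- list()
  rows <- list()
  for (cx in raw) {
    vs <- cx$members
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(g, vs)
    # k-core filter
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    if (haircut) {
      keep <- igraph::degree(sub) >= 2
      if (!any(keep)) next
      sub <- igraph::induced_subgraph(sub, which(keep))
    }
    if (fluff) {
      fl <- fluff_nodes(g, match(igraph::V(sub)$name, ids), adj, node_score_cutoff)
      if (length(fl)) {
        sub <- igraph::induced_subgraph(g, union(match(igraph::V(sub)$name, ids), fl))
      }
    }
    comps <- igraph::components(sub)
    if (comps$no > 1L) {
      big <- which.max(comps$csize)
      sub <- igraph::induced_subgraph(sub, which(comps$membership == big))
    }
    nv <- igraph::vcount(sub)
    if (nv < 2L) next
    dens <- 2 * igraph::ecount(sub) / (nv * (nv - 1))
    score <- dens * nv
    if (score <= score_min) next
    mod_net <- induce_subnetwork(net, igraph::V(sub)$name)
    modules[[length(modules) + 1L]] <- mod_net
    rows[[length(rows) + 1L]] <- tibble(
      n_nodes = nv,
      n_lncRNA = sum(mod_net$nodes$kind == "lncRNA"),
      n_TF = sum(mod_net$nodes$kind == "TF"),
      n_edges = nrow(mod_net$edges),
      density = dens, score = score, seed = cx$seed
    )
  }
  summary <- if (length(rows)) bind_rows(rows) else
    tibble(n_nodes = integer(), n_lncRNA = integer(), n_TF = integer(),
           n_edges = integer(), density = numeric(), score = numeric(),
           seed = character())
  ord <- order(-summary$score, summary$seed)
  summary <- summary[ord, , drop = FALSE]
  modules <- modules[ord]
  summary <- mutate(summary, module = dplyr::row_number(), .before = 1)
  structure(list(summary = summary, modules = modules,
                 params = list(score_min = score_min, degree_cutoff = degree_cutoff,
                               node_score_cutoff = node_score_cutoff,
                               max_depth = max_depth, k_core = k_core,
                               haircut = haircut, fluff = fluff)),
            class = "mcode_result")
}

# boundary nodes whose closed-neighborhood density exceeds the cutoff
fluff_nodes <- function(g, members, adj, cutoff) {
  boundary <- setdiff(unique(unlist(adj[members])), members)
  keep <- vapply(boundary, function(v) {
    vs <- unique(c(v, as.integer(adj[[v]])))
    if (length(vs) < 2L) return(FALSE)
    sub <- igraph::induced_subgraph(g, vs)
    nv <- igraph::vcount(sub)
    (2 * igraph::ecount(sub) / (nv * (nv - 1))) > cutoff
  }, logical(1))
  boundary[keep]
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("<mcode_result> %d module(s)\n", nrow(x$summary)))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' @export
tidy.mcode_result <- function(x, ...) x$summary

#' @export
glance.mcode_result <- function(x, ...) {
  tibble(n_modules = nrow(x$summary),
         best_score = if (nrow(x$summary)) max(x$summary$score) else NA_real_)
}

#' Composition of a detected module
#'
#' @param module A [cerna_network()] (e.g. one element of
#'   `mcode(...)$modules`).
#' @return Tibble with `n_lncRNA`, `n_TF`, `n_edges`.
#' @export
module_composition <- function(module) {
  stopifnot(inherits(module, "cerna_network"))
  tibble(
    n_lncRNA = sum(module$nodes$kind == "lncRNA"),
    n_TF = sum(module$nodes$kind == "TF"),
    n_edges = nrow(module$edges)
  )
}
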