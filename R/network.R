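#' Mixed ceRNA / PPI network container
#'
#' A `cerna_network` is an undirected, simple, typed graph: nodes are
#' lncRNAs or transcription factors (TFs); edges are either `ceRNA`
#' (lncRNA--TF, carrying shared-miRNA test evidence) or `PPI` (TF--TF).
#' Both components are plain tibbles so the object composes with dplyr.
#'
#' Edges are canonicalised on construction: a `ceRNA` edge always runs
#' lncRNA -> TF in (`from`, `to`); a `PPI` edge stores its endpoints in
#' lexicographic order. Self-loops are rejected and duplicate edges
#' (regardless of stored orientation) are collapsed, keeping the first
#' occurrence's evidence columns.
#'
#' @param nodes Tibble with columns `id` (character, unique) and `kind`
#'   (`"lncRNA"` or `"TF"`).
#' @param edges Tibble with columns `from`, `to`, `type` (`"ceRNA"` or
#'   `"PPI"`); any further columns are kept as edge evidence
#'   (e.g. `k`, `p`, `pcc`).
#' @return An object of class `cerna_network` with elements `nodes` and
#'   `edges`.
#' @examples
#' net <- cerna_network(
#'   nodes = tibble::tibble(id = c("L1", "T1"), kind = c("lncRNA", "TF")),
#'   edges = tibble::tibble(from = "L1", to = "T1", type = "ceRNA")
#' )
#' net
#' @export
cerna_network <- function(nodes, edges = NULL) {
  nodes <- as_tibble(nodes)
  if (!all(c("id", "kind") %in% names(nodes))) {
    abort("`nodes` needs columns `id` and `kind`.")
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) abort("node ids must be unique.")
  bad_kind <- setdiff(unique(nodes$kind), c("lncRNA", "TF"))
  if (length(bad_kind)) {
    abort(sprintf("unknown node kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  nodes <- arrange(nodes, .data$id)

  if (is.null(edges) || nrow(as_tibble(edges)) == 0L) {
    edges <- tibble(from = character(), to = character(), type = character())
  }
  edges <- as_tibble(edges)
  if (!all(c("from", "to", "type") %in% names(edges))) {
    abort("`edges` needs columns `from`, `to` and `type`.")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  bad_type <- setdiff(unique(edges$type), c("ceRNA", "PPI"))
  if (length(bad_type)) {
    abort(sprintf("unknown edge type(s): %s", paste(bad_type, collapse = ", ")))
  }
  missing_ref <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ref)) {
    abort(sprintf("edges reference unknown node(s): %s",
                  paste(head(missing_ref, 5), collapse = ", ")))
  }
  if (any(edges$from == edges$to)) abort("self-loops are not allowed.")

  kind <- setNames(nodes$kind, nodes$id)
  if (nrow(edges)) {
    ce <- edges$type == "ceRNA"
    ok_ce <- !ce | (kind[edges$from] != kind[edges$to] &
                      (kind[edges$from] == "lncRNA" | kind[edges$to] == "lncRNA"))
    if (!all(ok_ce)) abort("ceRNA edges must connect one lncRNA and one TF.")
    ok_ppi <- ce | (kind[edges$from] == "TF" & kind[edges$to] == "TF")
    if (!all(ok_ppi)) abort("PPI edges must connect two TFs.")
    # canonical orientation
    flip <- (ce & kind[edges$from] == "TF") | (!ce & edges$from > edges$to)
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    edges <- distinct(edges, .data$from, .data$to, .data$type, .keep_all = TRUE)
    edges <- arrange(edges, .data$type, .data$from, .data$to)
  }
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = c("lncRNA", "TF")))
  types <- table(factor(x$edges$type, levels = c("ceRNA", "PPI")))
  cat(sprintf(
    "<cerna_network> %d nodes (%d lncRNA, %d TF), %d edges (%d ceRNA, %d PPI)\n",
    nrow(x$nodes), kinds[["lncRNA"]], kinds[["TF"]],
    nrow(x$edges), types[["ceRNA"]], types[["PPI"]]))
  invisible(x)
}

#' @export
tidy.cerna_network <- function(x, ...) x$edges

#' @export
glance.cerna_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_lncRNA = sum(x$nodes$kind == "lncRNA"),
    n_TF = sum(x$nodes$kind == "TF"),
    n_edges = nrow(x$edges),
    n_ceRNA = sum(x$edges$type == "ceRNA"),
    n_PPI = sum(x$edges$type == "PPI")
  )
}

#' Convert a cerna_network to an igraph graph
#'
#' Node `kind` and edge `type` (plus evidence columns) become igraph
#' attributes.
#'
#' @param net A [cerna_network()].
#' @return An undirected [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(
    d = net$edges, directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

# Vertex-induced subgraph, preserving attributes and class.
induce_subnetwork <- function(net, ids) {
  stopifnot(inherits(net, "cerna_network"))
  missing_ids <- setdiff(ids, net$nodes$id)
  if (length(missing_ids)) {
    abort(sprintf("unknown node id(s): %s", paste(head(missing_ids, 5), collapse = ", ")))
  }
  nodes <- filter(net$nodes, .data$id %in% ids)
  edges <- filter(net$edges, .data$from %in% ids & .data$to %in% ids)
  cerna_network(nodes, edges)
}

# Accept a cerna_network or a bare edge table (from, to) for graph-only
# algorithms (MCODE, topology oracles). Bare tables get kind "TF"/"PPI".
as_cerna_graph <- function(x) {
  if (inherits(x, "cerna_network")) return(x)
  x <- as_tibble(x)
  if (!all(c("from", "to") %in% names(x))) {
    abort("expected a cerna_network or a table with `from` and `to` columns.")
  }
  ids <- sort(unique(c(x$from, x$to)))
  cerna_network(
    nodes = tibble(id = ids, kind = "TF"),
    edges = tibble(from = x$from, to = x$to, type = "PPI")
  )
}
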