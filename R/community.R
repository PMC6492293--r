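#' @title Discourse coalitions via Girvan-Newman clustering
#' @name community
#' @description Coalitions are detected on the *unweighted* thresholded
#'   graph (a tie is present or absent once the weight threshold has been
#'   applied; tie counts in embeddedness tables are integers). The
#'   Girvan-Newman procedure repeatedly removes the edge with maximum
#'   edge betweenness (shortest-path load), recording every component split;
#'   the partition maximizing Newman modularity over the dendrogram is
#'   selected. Betweenness is computed with Brandes' algorithm and verified
#'   in the test suite against exhaustive shortest-path enumeration.
NULL

# internal adjacency-list representation of the unweighted graph
dn_adjacency <- function(nodes, edges) {
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  if (nrow(edges) > 0) {
    ia <- match(edges$actor_a, nodes)
    ib <- match(edges$actor_b, nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  adj
}

# Brandes (2001) betweenness, edge variant, unweighted graph.
# Returns a numeric vector aligned with rows of `edges`; each unordered node
# pair (including edge endpoints) contributes 1 split equally across its
# shortest paths.
brandes_edge_betweenness <- function(nodes, edges) {
  m <- nrow(edges)
  if (m == 0) return(numeric(0))
  n <- length(nodes)
  ia <- match(edges$actor_a, nodes)
  ib <- match(edges$actor_b, nodes)
  # edge id lookup via n*min+max key
  key <- pmin(ia, ib) * (n + 1) + pmax(ia, ib)
  eid <- integer(0)
  eid[key] <- seq_len(m)
  adj <- dn_adjacency(nodes, edges)
  bc <- numeric(m)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); sigma <- numeric(n)
    dist[s] <- 0L; sigma[s] <- 1
    order_visited <- integer(0)
    queue <- s; qhead <- 1L
    preds <- vector("list", n)
    while (qhead <= length(queue)) {
      v <- queue[qhead]; qhead <- qhead + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        c_ <- sigma[v] / sigma[w] * (1 + delta[w])
        e <- eid[pmin(v, w) * (n + 1) + pmax(v, w)]
        bc[e] <- bc[e] + c_
        delta[v] <- delta[v] + c_
      }
    }
  }
  bc / 2   # each unordered pair was accumulated from both endpoints
}

#' Edge betweenness of a thresholded actor network
#'
#' For each edge, the number of shortest paths between unordered node pairs
#' passing through it, split equally across tied shortest paths. Computed on
#' the unweighted graph.
#'
#' @param network a `dn_network`.
#' @return data frame `actor_a`, `actor_b`, `betweenness` (zero rows for an
#'   edgeless network).
#' @export
edge_betweenness <- function(network) {
  stopifnot(inherits(network, "dn_network"))
  edges <- network$edges
  data.frame(actor_a = edges$actor_a, actor_b = edges$actor_b,
             betweenness = brandes_edge_betweenness(network$nodes$actor, edges),
             stringsAsFactors = FALSE)
}

# connected components; returns integer membership labelled 1..k in order of
# each component's lexicographically smallest member
dn_components <- function(nodes, edges) {
  n <- length(nodes)
  adj <- dn_adjacency(nodes, edges)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in order(nodes, method = "radix")) {  # ids follow smallest member
    if (comp[s] == 0L) {
      cur <- cur + 1L
      stack <- s
      comp[s] <- cur
      while (length(stack) > 0) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; stack <- c(stack, w) }
      }
    }
  }
  stats::setNames(comp, nodes)
}

#' Newman modularity of a coalition assignment
#'
#' `Q = sum_i (e_ii - a_i^2)` over coalitions, on the unweighted thresholded
#' graph: `e_ii` is the fraction of edges inside coalition `i`, `a_i` the
#' fraction of edge endpoints in `i`. Zero for the trivial one-coalition
#' partition; defined as 0 for an edgeless graph.
#'
#' @param network a `dn_network`.
#' @param assignment named vector (actor -> coalition id) covering every node.
#' @return modularity in `[-0.5, 1]`.
#' @export
modularity_q <- function(network, assignment) {
  stopifnot(inherits(network, "dn_network"))
  nodes <- network$nodes$actor
  if (!all(nodes %in% names(assignment))) {
    dn_abort("dn_coverage_error", "assignment must cover every node in the network")
  }
  edges <- network$edges
  m <- nrow(edges)
  if (m == 0) return(0)
  ca <- assignment[edges$actor_a]
  cb <- assignment[edges$actor_b]
  e_in <- sum(ca == cb) / m
  deg_ends <- c(ca, cb)                       # one entry per edge endpoint
  a_i <- table(deg_ends) / (2 * m)
  as.numeric(e_in - sum(a_i^2))
}

#' Girvan-Newman coalition detection
#'
#' Repeatedly removes a single maximum-betweenness edge (recomputing
#' betweenness after each removal; ties broken by the lexicographically
#' smallest `(actor_a, actor_b)` pair, so the procedure is deterministic),
#' records each component split, and returns the dendrogram level with
#' maximum modularity (earliest level on ties). Components are never merged,
#' so a disconnected input is only ever refined.
#'
#' @param network a `dn_network` with at least two nodes.
#' @return A `dn_partition`: list with `assignment` (named integer,
#'   actor -> coalition id; ids numbered by each coalition's smallest
#'   member), `modularity`, `n_coalitions`, and `dendrogram` (data frame of
#'   removals: `step`, `actor_a`, `actor_b`, `betweenness`,
#'   `n_components`).
#' @export
girvan_newman <- function(network) {
  stopifnot(inherits(network, "dn_network"))
  nodes <- network$nodes$actor
  if (length(nodes) < 2) dn_abort("dn_too_few_actors_error", "need at least two nodes to cluster")
  edges <- network$edges

  best_assignment <- dn_components(nodes, edges)
  best_q <- modularity_q(network, best_assignment)
  dendro <- list()
  n_comp_prev <- max(best_assignment)
  cur_edges <- edges
  step <- 0L
  while (nrow(cur_edges) > 0) {
    bc <- brandes_edge_betweenness(nodes, cur_edges)
    top <- which(bc == max(bc))
    if (length(top) > 1) top <- top[order(cur_edges$actor_a[top], cur_edges$actor_b[top],
                                          method = "radix")][1]
    step <- step + 1L
    removed <- cur_edges[top, , drop = FALSE]
    cur_edges <- cur_edges[-top, , drop = FALSE]
    comp <- dn_components(nodes, cur_edges)
    n_comp <- max(comp)
    dendro[[step]] <- data.frame(step = step,
                                 actor_a = removed$actor_a,
                                 actor_b = removed$actor_b,
                                 betweenness = bc[top],
                                 n_components = n_comp,
                                 stringsAsFactors = FALSE)
    if (n_comp > n_comp_prev) {
      q <- modularity_q(network, comp)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_assignment <- comp
      }
      n_comp_prev <- n_comp
    }
  }
  dendro <- if (length(dendro) > 0) do.call(rbind, dendro) else
    data.frame(step = integer(0), actor_a = character(0), actor_b = character(0),
               betweenness = numeric(0), n_components = integer(0))
  structure(list(assignment = best_assignment,
                 modularity = best_q,
                 n_coalitions = max(best_assignment),
                 dendrogram = dendro),
            class = "dn_partition")
}

#' Per-actor coalition embeddedness (external ratio)
#'
#' `external_ratio = (total_ties - within_ties) / total_ties` on the
#' unweighted thresholded graph: 0 means every tie stays inside the actor's
#' own coalition, values near 1 mark brokers straddling coalitions.
#'
#' @param network a `dn_network`.
#' @param assignment named vector (actor -> coalition id) covering all nodes,
#'   or a `dn_partition`.
#' @param actor actor key with at least one tie.
#' @return one-row data frame `actor`, `total_ties`, `within_ties`,
#'   `external_ratio` (full precision; round to 2 decimals for display).
#' @export
external_ratio <- function(network, assignment, actor) {
  stopifnot(inherits(network, "dn_network"))
  if (inherits(assignment, "dn_partition")) assignment <- assignment$assignment
  nodes <- network$nodes$actor
  if (!actor %in% nodes) dn_abort("dn_coverage_error", sprintf("unknown actor '%s'", actor))
  if (!all(nodes %in% names(assignment))) {
    dn_abort("dn_coverage_error", "assignment must cover every node in the network")
  }
  edges <- network$edges
  inc <- edges$actor_a == actor | edges$actor_b == actor
  total <- sum(inc)
  if (total == 0) {
    dn_abort("dn_undefined_ratio_error",
             sprintf("actor '%s' has no ties; external ratio undefined", actor))
  }
  other <- ifelse(edges$actor_a[inc] == actor, edges$actor_b[inc], edges$actor_a[inc])
  within <- sum(assignment[other] == assignment[actor])
  data.frame(actor = actor, total_ties = as.integer(total),
             within_ties = as.integer(within),
             external_ratio = (total - within) / total,
             stringsAsFactors = FALSE)
}

#' External-ratio table for every non-isolated actor
#'
#' @inheritParams external_ratio
#' @return data frame, one row per actor with >= 1 tie, actors sorted.
#'   Isolates (singleton coalitions by construction) are excluded.
#' @export
external_ratio_table <- function(network, assignment) {
  if (inherits(assignment, "dn_partition")) assignment <- assignment$assignment
  edges <- network$edges
  tied <- dn_sort(intersect(network$nodes$actor, unique(c(edges$actor_a, edges$actor_b))))
  out <- do.call(rbind, lapply(tied, function(a) external_ratio(network, assignment, a)))
  if (is.null(out)) {
    out <- data.frame(actor = character(0), total_ties = integer(0),
                      within_ties = integer(0), external_ratio = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.dn_partition <- function(x, ...) {
  cat(sprintf("<dn_partition> %d coalitions, modularity %.4f, %d removals recorded\n",
              x$n_coalitions, x$modularity, nrow(x$dendrogram)))
  invisible(x)
}
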