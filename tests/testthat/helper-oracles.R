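# Independent oracles. These deliberately share no code with the package
# internals: betweenness by exhaustive shortest-path enumeration, modularity
# by direct fraction counting over explicitly enumerated set partitions, and
# stance/frequency tallies by row-wise loops over the raw statement table.

# --- exhaustive shortest-path edge betweenness -------------------------------

oracle_edge_betweenness <- function(net) {
  nodes <- net$nodes$actor
  edges <- net$edges
  key <- function(a, b) paste(min(a, b), max(a, b), sep = "|")
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$actor_b[edges$actor_a == v], edges$actor_a[edges$actor_b == v])
  })
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0; q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.infinite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  bc <- stats::setNames(rep(0, nrow(edges)), mapply(key, edges$actor_a, edges$actor_b))
  pairs <- utils::combn(nodes, 2, simplify = FALSE)
  for (p in pairs) {
    s <- p[1]; t <- p[2]
    dt <- bfs_dist(t)
    if (is.infinite(dt[s])) next
    # enumerate every shortest s-t path (DFS pruned by distance-to-target)
    paths <- list()
    walk <- function(v, path) {
      if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
      for (w in adj[[v]]) {
        if (dt[w] == dt[v] - 1) walk(w, c(path, w))
      }
    }
    walk(s, s)
    npaths <- length(paths)
    for (pt in paths) {
      for (i in seq_len(length(pt) - 1)) {
        k <- key(pt[i], pt[i + 1])
        bc[k] <- bc[k] + 1 / npaths
      }
    }
  }
  unname(bc[mapply(key, edges$actor_a, edges$actor_b)])
}

# --- set partitions and direct modularity ------------------------------------

# all set partitions of n items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(0), 0L)
  out
}

oracle_modularity <- function(net, assignment) {
  edges <- net$edges
  m <- nrow(edges)
  if (m == 0) return(0)
  groups <- unique(assignment)
  q <- 0
  for (g in groups) {
    members <- names(assignment)[assignment == g]
    e_ii <- sum(edges$actor_a %in% members & edges$actor_b %in% members) / m
    ends <- sum(edges$actor_a %in% members) + sum(edges$actor_b %in% members)
    q <- q + e_ii - (ends / (2 * m))^2
  }
  q
}

# --- row-wise tally oracles --------------------------------------------------

oracle_stance_tally <- function(corpus, level) {
  df <- corpus$statements
  acc <- list()
  for (i in seq_len(nrow(df))) {
    k <- paste(df[[level]][i], df$concept[i], sep = "\r")
    if (is.null(acc[[k]])) acc[[k]] <- c(agree = 0L, disagree = 0L)
    acc[[k]][df$stance[i]] <- acc[[k]][df$stance[i]] + 1L
  }
  acc
}

oracle_concept_tally <- function(corpus) {
  df <- corpus$statements
  acc <- list()
  for (i in seq_len(nrow(df))) {
    k <- df$concept[i]
    if (is.null(acc[[k]])) acc[[k]] <- c(agree = 0L, disagree = 0L)
    acc[[k]][df$stance[i]] <- acc[[k]][df$stance[i]] + 1L
  }
  acc
}

# pairwise tie components recomputed concept-by-concept from raw counts
oracle_pair_components <- function(sm, a, b) {
  co_s <- 0L; co_r <- 0L; dv <- 0L
  for (concept in sm$concepts) {
    sa <- sign(sm$n_agree[a, concept] - sm$n_disagree[a, concept])
    sb <- sign(sm$n_agree[b, concept] - sm$n_disagree[b, concept])
    if (sm$n_agree[a, concept] + sm$n_disagree[a, concept] == 0) next
    if (sm$n_agree[b, concept] + sm$n_disagree[b, concept] == 0) next
    if (sa == 1 && sb == 1) co_s <- co_s + 1L
    if (sa == -1 && sb == -1) co_r <- co_r + 1L
    if (sa * sb == -1) dv <- dv + 1L
  }
  c(co_support = co_s, co_reject = co_r, diverge = dv)
}
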