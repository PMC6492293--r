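# Fixture builders: tiny corpora and hand-assembled networks.
# All built in code; nothing on disk.

mk_statements <- function(organization, concept, stance,
                          person = paste(organization, "spokesperson"),
                          date = "2011-06-15", source = "The Gazette",
                          actor_type = "charity", article_id = "a1", ...) {
  data.frame(article_id = article_id, source = source, date = date,
             person = person, organization = organization,
             actor_type = actor_type, concept = concept, stance = stance,
             stringsAsFactors = FALSE, ...)
}

mk_corpus <- function(...) as_corpus(mk_statements(...))

# stance shorthand: "A+X" = org A agrees with concept X, "A-X" disagrees
mk_corpus_compact <- function(codes, ...) {
  org <- sub("^(.*)[+-].*$", "\\1", codes)
  stance <- ifelse(grepl("\\+", codes), "agree", "disagree")
  concept <- sub("^.*[+-]", "", codes)
  mk_corpus(organization = org, concept = concept, stance = stance, ...)
}

# assemble a dn_network directly from an edge list (for community tests)
mk_net <- function(pairs, nodes = NULL, weight = 1) {
  if (length(pairs) == 0) {
    edges <- data.frame(actor_a = character(0), actor_b = character(0),
                        weight = numeric(0), co_support = integer(0),
                        co_reject = integer(0), diverge = integer(0))
  } else {
    a <- vapply(pairs, `[`, character(1), 1)
    b <- vapply(pairs, `[`, character(1), 2)
    edges <- data.frame(actor_a = pmin(a, b), actor_b = pmax(a, b),
                        weight = weight, co_support = 1L, co_reject = 0L,
                        diverge = 0L, stringsAsFactors = FALSE)
    edges <- edges[order(edges$actor_a, edges$actor_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$actor_a, edges$actor_b)))
  structure(list(nodes = data.frame(actor = nodes, actor_type = "org",
                                    statement_frequency = 1L,
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 config = tie_config(threshold = NULL), window = NULL),
            class = "dn_network")
}

two_triangles_bridge <- function() {
  mk_net(list(c("a", "b"), c("a", "c"), c("b", "c"),
              c("c", "d"),
              c("d", "e"), c("d", "f"), c("e", "f")))
}

# star network for embeddedness arithmetic: hub with `total` ties of which
# `within` go to its own coalition
mk_star <- function(total, within, hub = "HUB") {
  nb <- sprintf("N%02d", seq_len(total))
  net <- mk_net(lapply(nb, function(x) c(hub, x)))
  assignment <- stats::setNames(c(1L, rep(1L, within), rep(2L, total - within)),
                                c(hub, nb))
  list(net = net, assignment = assignment)
}

# random connected graph with <= n_max nodes (random spanning tree + extras)
random_connected_graph <- function(n_max = 8) {
  n <- sample(3:n_max, 1)
  nodes <- sprintf("v%d", seq_len(n))
  pairs <- list()
  perm <- sample(n)
  for (i in 2:n) {   # random tree: attach each node to an earlier one
    j <- perm[sample.int(i - 1, 1)]
    pairs[[length(pairs) + 1]] <- c(nodes[perm[i]], nodes[j])
  }
  all_pairs <- utils::combn(nodes, 2, simplify = FALSE)
  have <- vapply(pairs, function(p) paste(sort(p), collapse = "|"), character(1))
  for (p in all_pairs) {
    key <- paste(sort(p), collapse = "|")
    if (!key %in% have && stats::runif(1) < 0.3) {
      pairs[[length(pairs) + 1]] <- p
    }
  }
  mk_net(pairs, nodes = sort(nodes))
}
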