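test_that("pair components count co-support, co-rejection and divergence", {
  sm <- build_stance_matrix(mk_corpus_compact(c("A+X", "A+Y", "B+X", "B+Y")))
  expect_equal(pair_concept_components(sm, "A", "B"),
               c(co_support = 2L, co_reject = 0L, diverge = 0L))

  sm <- build_stance_matrix(mk_corpus_compact(c("A+X", "B-X")))
  expect_equal(pair_concept_components(sm, "A", "B"),
               c(co_support = 0L, co_reject = 0L, diverge = 1L))

  # A supports X, rejects Y; B rejects Y, supports Z -> only Y contributes
  sm <- build_stance_matrix(mk_corpus_compact(c("A+X", "A-Y", "B-Y", "B+Z")))
  expect_equal(pair_concept_components(sm, "A", "B"),
               c(co_support = 0L, co_reject = 1L, diverge = 0L))

  expect_error(pair_concept_components(sm, "A", "A"), class = "dn_self_pair_error")

  # contested and absent stances contribute nothing
  sm <- build_stance_matrix(mk_corpus_compact(c("A+X", "A-X", "B+X", "A+Z", "B+Q")))
  expect_equal(unname(pair_concept_components(sm, "A", "B")), c(0L, 0L, 0L))
})

test_that("tie_weight implements subtract/congruence/conflict with normalization", {
  expect_equal(tie_weight(c(2, 0, 0), 2, 2, tie_config()), 1.0)
  expect_equal(tie_weight(c(0, 0, 1), 1, 1, tie_config()), -1.0)
  expect_equal(tie_weight(c(0, 0, 0), 7, 3, tie_config()), 0.0)
  expect_equal(tie_weight(c(1, 1, 1), 2, 2, tie_config("congruence", "none", NULL)), 2)
  expect_equal(tie_weight(c(1, 1, 1), 2, 2, tie_config("conflict", "none", NULL)), 1)
  expect_equal(tie_weight(c(3, 1, 1), 4, 2, tie_config()), 3 / 3)
  expect_error(tie_weight(c(1, 0, 0), 0, 2, tie_config()),
               class = "dn_degenerate_actor_error")
  expect_error(tie_config(threshold = -0.1), class = "dn_config_error")
})

test_that("build_network produces the documented edge for a minimal pair", {
  # two actors, identical pairs of statements: weight (2-0)/((2+2)/2) = 1.0
  corpus <- mk_corpus_compact(c("A+X", "A+Y", "B+X", "B+Y"))
  net <- build_network(build_stance_matrix(corpus), tie_config())
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1.0)
  expect_equal(net$edges$co_support, 2L)
  expect_equal(net$nodes$statement_frequency, c(2L, 2L))

  expect_error(build_network(build_stance_matrix(mk_corpus_compact("A+X"))),
               class = "dn_too_few_actors_error")
})

test_that("threshold >= 0.4 keeps 0.40 and drops 0.39 exactly", {
  # A-C share 40 concepts, A-B and B-C share 39; every actor makes exactly
  # 100 statements on distinct concepts -> weights 0.40 and 0.39 exactly
  codes <- c(paste0("A+s", 1:40), paste0("A+ua", 1:60),
             paste0("B+s", 1:39), paste0("B+ub", 1:61),
             paste0("C+s", 1:40), paste0("C+uc", 1:60))
  sm <- build_stance_matrix(mk_corpus_compact(codes))
  unthresholded <- build_network(sm, tie_config(threshold = NULL))
  w <- unthresholded$edges
  expect_equal(w$weight[w$actor_a == "A" & w$actor_b == "C"], 0.40)
  expect_equal(w$weight[w$actor_a == "A" & w$actor_b == "B"], 0.39)

  net <- build_network(sm, tie_config(threshold = 0.4))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges[, c("actor_a", "actor_b")],
               data.frame(actor_a = "A", actor_b = "C"))
  # isolated-by-threshold actor B stays in the node table
  expect_true("B" %in% net$nodes$actor)
})

test_that("weights are symmetric and bounded by 1 under the default config", {
  for (seed in 1:10) {
    gen <- generate_corpus(sim_config(seed = seed, n_statements = 250,
                                      actors_per_coalition = c(6, 6), n_brokers = 2))
    sm <- build_stance_matrix(gen$corpus)
    net <- build_network(sm, tie_config(threshold = NULL))
    expect_true(all(abs(net$edges$weight) <= 1 + 1e-12))
    # symmetry: recompute a few pairs in both orders via the scalar route
    act <- activity <- sm$activity
    for (k in utils::head(seq_len(nrow(net$edges)), 5)) {
      a <- net$edges$actor_a[k]; b <- net$edges$actor_b[k]
      cab <- pair_concept_components(sm, a, b)
      cba <- pair_concept_components(sm, b, a)
      expect_equal(unname(cab), unname(cba))
      expect_equal(tie_weight(cab, act[[a]], act[[b]]),
                   tie_weight(cba, act[[b]], act[[a]]))
      expect_equal(tie_weight(cab, act[[a]], act[[b]]), net$edges$weight[k])
    }
  }
})

test_that("subtract = congruence - conflict pre-normalization, pair by pair", {
  sm <- build_stance_matrix(mk_corpus_compact(
    c("A+X", "B+X", "A-Y", "B-Y", "A+Z", "B-Z")))   # components (1,1,1)
  dec <- congruence_conflict_decomposition(sm)
  expect_equal(dec$congruence$edges$weight, 2)
  expect_equal(dec$conflict$edges$weight, 1)
  sub <- build_network(sm, tie_config("subtract", "none", NULL))
  expect_equal(sub$edges$weight, 1)

  # no opposing stances -> empty conflict network
  dec2 <- congruence_conflict_decomposition(
    build_stance_matrix(mk_corpus_compact(c("A+X", "B+X", "A+Y", "C+Y"))))
  expect_equal(nrow(dec2$conflict$edges), 0)
})

test_that("rate effects: duplication scales weights as 1/k; stance-neutral additions keep the numerator", {
  gen <- generate_corpus(sim_config(seed = 31, n_statements = 200,
                                    actors_per_coalition = c(5, 5)))
  sm1 <- build_stance_matrix(gen$corpus)
  doubled <- as_corpus(rbind(gen$corpus$statements, gen$corpus$statements))
  sm2 <- build_stance_matrix(doubled)

  raw1 <- build_network(sm1, tie_config("subtract", "none", NULL))$edges
  raw2 <- build_network(sm2, tie_config("subtract", "none", NULL))$edges
  # duplicating every row changes no net stance: numerators identical
  expect_equal(raw2[c("actor_a", "actor_b", "weight")],
               raw1[c("actor_a", "actor_b", "weight")])

  # ... so statement-based average-activity weights scale by exactly 1/2
  n1 <- build_network(sm1, tie_config(threshold = NULL))$edges
  n2 <- build_network(sm2, tie_config(threshold = NULL))$edges
  expect_equal(n2$weight, n1$weight / 2)

  # while distinct-concept activity is invariant to duplication
  cfg <- tie_config(threshold = NULL, activity = "distinct_concepts")
  expect_equal(build_network(sm2, cfg)$edges$weight,
               build_network(sm1, cfg)$edges$weight)
})

test_that("exports are written and loadable (edge list, GraphML, GEXF)", {
  gen <- generate_corpus(sim_config(seed = 41, n_statements = 150,
                                    actors_per_coalition = c(4, 4)))
  net <- build_network(build_stance_matrix(gen$corpus), tie_config(threshold = NULL))
  d <- withr::local_tempdir()

  f <- write_edge_list(net, file.path(d, "edges.csv"))
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$weight, net$edges$weight)

  g <- igraph::read_graph(write_network_graphml(net, file.path(d, "n.graphml")),
                          format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(sort(igraph::V(g)$name), sort(net$nodes$actor))

  gexf <- readLines(write_network_gexf(net, file.path(d, "n.gexf")))
  expect_equal(sum(grepl("<node ", gexf, fixed = TRUE)), nrow(net$nodes))
  expect_equal(sum(grepl("<edge ", gexf, fixed = TRUE)), nrow(net$edges))
})
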