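# the drift world: polarized benchmark spread over two windows, with one
# coalition-1 actor whose alignment drops by 0.45 in the second window
drift_cfg <- function(seed, drift = 0.45) sim_config(
  actors_per_coalition = c(10, 10), n_brokers = 0, n_concepts = 20,
  n_statements = 800, p_aligned = 0.9, activity_exponent = 0,
  min_activity = 40, concept_exponent = 0, repeat_penalty = 0.05,
  windows = data.frame(start = as.Date(c("2011-05-01", "2011-11-01")),
                       end = as.Date(c("2011-11-01", "2012-05-01"))),
  window_drift = c(0, drift), n_drift_actors = 1, seed = seed)

test_that("a fully aligned world is deterministic in the planted direction", {
  cfg <- sim_config(seed = 2, p_aligned = 1, broker_p_aligned = 1, n_brokers = 0,
                    actors_per_coalition = c(6, 6), n_concepts = 10,
                    n_statements = 240, window_drift = c(0, 0, 0))
  gen <- generate_corpus(cfg)
  sm <- build_stance_matrix(gen$corpus)
  ns <- net_stance_matrix(sm)
  own <- gen$truth$coalition_of[sm$actors]
  for (i in seq_along(sm$actors)) {
    addressed <- which(!is.na(ns[i, ]))
    planted <- ifelse(cfg$concept_ownership[addressed] == own[i], 1L, -1L)
    expect_equal(unname(ns[i, addressed]), planted)
  }
  # conflict ties occur across coalitions only
  conf <- congruence_conflict_decomposition(sm)$conflict
  expect_true(all(own[conf$edges$actor_a] != own[conf$edges$actor_b]))
  # no positive subtract weight crosses the divide
  sub <- build_network(sm, tie_config(threshold = NULL))
  cross <- own[sub$edges$actor_a] != own[sub$edges$actor_b]
  expect_true(all(sub$edges$weight[cross] < 0))
})

test_that("generation is reproducible: same seed, byte-identical corpus", {
  g1 <- generate_corpus(sim_config(seed = 7, n_statements = 200,
                                   actors_per_coalition = c(5, 5)))
  g2 <- generate_corpus(sim_config(seed = 7, n_statements = 200,
                                   actors_per_coalition = c(5, 5)))
  expect_identical(g1$corpus$statements, g2$corpus$statements)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_statements(g1$corpus, f1); write_statements(g2$corpus, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed changes the corpus
  g3 <- generate_corpus(sim_config(seed = 8, n_statements = 200,
                                   actors_per_coalition = c(5, 5)))
  expect_false(identical(g1$corpus$statements, g3$corpus$statements))
})

test_that("the emitted corpus passes statement-store validation end to end", {
  gen <- generate_corpus(sim_config(seed = 19, n_statements = 300))
  f <- withr::local_tempfile(fileext = ".csv")
  write_statements(gen$corpus, f)
  back <- read_statements(f)
  expect_equal(back$statements, gen$corpus$statements)
  expect_true(all(back$statements$stance %in% c("agree", "disagree")))
  expect_setequal(names(gen$truth$coalition_of),
                  unique(gen$corpus$statements$organization))
})

test_that("invalid configurations raise config errors", {
  expect_error(sim_config(p_aligned = 1.2), class = "dn_config_error")
  expect_error(sim_config(actors_per_coalition = c(4, 0)), class = "dn_config_error")
  expect_error(sim_config(window_drift = c(0, 0)), class = "dn_config_error")
  expect_error(sim_config(concept_ownership = rep(1, 3)), class = "dn_config_error")
  expect_error(generate_corpus(sim_config(n_statements = 5, min_activity = 2)),
               class = "dn_config_error")
})

test_that("adjusted Rand index behaves at its anchors", {
  x <- rep(1:4, each = 5)
  expect_equal(adjusted_rand_index(x, x), 1)
  relabelled <- c(3, 1, 4, 2)[x]             # ARI ignores label names
  expect_equal(adjusted_rand_index(x, relabelled), 1)
  expect_equal(adjusted_rand_index(x, rep(1, 20)), 0)

  set.seed(77)
  aris <- replicate(300, adjusted_rand_index(sample(1:3, 60, TRUE),
                                             sample(1:3, 60, TRUE)))
  expect_lt(abs(mean(aris)), 0.02)           # ~0 in expectation under independence

  part <- structure(list(assignment = c(a = 1L)), class = "dn_partition")
  truth <- structure(list(coalition_of = c(a = 1L, b = 2L), broker_set = character(0)),
                     class = "dn_ground_truth")
  expect_error(recovery_score(part, truth), class = "dn_coverage_error")
})

test_that("strong polarization yields exact recovery on benchmark seeds", {
  # the full 100-replicate experiment lives in the acceptance suite;
  # spot-check a handful of seeds here
  for (s in c(1, 2, 3)) {
    gen <- generate_corpus(polarized_config(seed = s))
    net <- build_network(build_stance_matrix(gen$corpus), tie_config())
    expect_equal(recovery_score(girvan_newman(net), gen$truth), 1)
  }
})

test_that("the drifting actor becomes less embedded in the window of drift", {
  res <- t(vapply(1:12, function(s) {
    gen <- generate_corpus(drift_cfg(s))
    w2 <- slice_window(gen$corpus, "2011-11-01", "2012-05-01")
    net <- build_network(build_stance_matrix(w2), tie_config(threshold = 0))
    part <- suppressWarnings(girvan_newman(net))
    tab <- external_ratio_table(net, part)
    da <- gen$truth$drift_actors
    peers <- setdiff(names(gen$truth$coalition_of)[gen$truth$coalition_of == 1], da)
    c(drifter = if (da %in% tab$actor) tab$external_ratio[tab$actor == da] else NA_real_,
      peer_mean = mean(tab$external_ratio[tab$actor %in% peers]))
  }, numeric(2)))
  expect_true(all(is.finite(res)))
  expect_gt(mean(res[, "drifter"]), mean(res[, "peer_mean"]))
  expect_gte(sum(res[, "drifter"] > res[, "peer_mean"]), 7)
})
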