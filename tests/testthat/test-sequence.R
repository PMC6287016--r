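test_that("the comparison kernel is 1 on self and ~0 on opposed angles", {
  cfg <- test_config()
  ev <- ev_table(c(0.3, 1.5, 4.0), c(0.4, 0.3, 0.5), c(0, 0.2, 0.3))
  hyp <- sequence_hypothesis("s1", ev)
  expect_equal(compare_sequences(ev, hyp, cfg), 1, tolerance = 1e-12)
  flipped <- ev
  flipped$angle <- (ev$angle + pi) %% (2 * pi)
  expect_lt(compare_sequences(flipped, hyp, cfg), 1e-6)
})

test_that("a one-sigma angle offset gives exactly exp(-1/2)", {
  cfg <- test_config()
  hyp <- sequence_hypothesis("s1", ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.2)))
  obs <- ev_table(1 + cfg$sigma_a, 0.5, 0)
  expect_equal(compare_sequences(obs, hyp, cfg), exp(-0.5),
               tolerance = 1e-9)
})

test_that("observations overrunning a shorter hypothesis are penalised", {
  cfg <- test_config()
  hyp <- sequence_hypothesis("s1", ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.2)))
  obs <- ev_table(c(1, 2, 3), c(0.5, 0.5, 0.5), c(0, 0.2, 0.2))
  expect_equal(compare_sequences(obs, hyp, cfg),
               exp(-cfg$overrun_penalty), tolerance = 1e-9)
  expect_error(compare_sequences(ev_table(numeric(), numeric(), numeric()),
                                 hyp, cfg), "empty")
})

test_that("the temporal factor follows the Gaussian binding form", {
  cfg <- test_config()
  hyp <- sequence_hypothesis("s1",
                             ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.4)))
  exact <- ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.4))
  expect_equal(sequence_likelihood(exact, hyp, config = cfg), 1,
               tolerance = 1e-9)
  # timing off by exactly pi_S: likelihood = exp(-1/2)
  off1 <- ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.4 + cfg$pi_s_temporal))
  expect_equal(sequence_likelihood(off1, hyp, config = cfg), exp(-0.5),
               tolerance = 1e-9)
  # iota = 0.8 with timing off by 2 pi_S: 0.8 * exp(-2)
  d <- cfg$sigma_a * sqrt(2 * log(1 / 0.8))
  off2 <- ev_table(c(1 + d, 2 + d), c(0.5, 0.5),
                   c(0, 0.4 + 2 * cfg$pi_s_temporal))
  expect_equal(sequence_likelihood(off2, hyp, config = cfg),
               0.8 * exp(-2), tolerance = 1e-9)
  expect_error(sequence_likelihood(exact, hyp, pi_s = 0), "positive")
})

test_that("temporal precision limits behave as binding theory predicts", {
  cfg <- test_config()
  hyp <- sequence_hypothesis("s1", ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.4)))
  obs <- ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.9))
  # infinite width: timing becomes irrelevant
  expect_equal(sequence_likelihood(obs, hyp, pi_s = 1e9, config = cfg), 1,
               tolerance = 1e-6)
  # vanishing width: any mismatch kills the likelihood
  expect_lt(sequence_likelihood(obs, hyp, pi_s = 1e-3, config = cfg), 1e-12)
  # monotone non-increasing in the timing mismatch
  liks <- vapply(seq(0, 1, by = 0.1), function(err) {
    o <- ev_table(c(1, 2), c(0.5, 0.5), c(0, 0.4 + err))
    sequence_likelihood(o, hyp, config = cfg)
  }, numeric(1))
  expect_true(all(diff(liks) <= 1e-12))
})

test_that("sequence posteriors aggregate consistently into the upward message", {
  rep <- test_repertoire()
  cfg <- test_config()
  st <- sequence_level_init(rep, cfg)
  schema_ids <- sort(names(rep$schemas))
  set.seed(11)
  sch_post <- rand_belief(length(schema_ids), schema_ids)
  ev <- rep$sequences[[1]]$events[1, c("angle", "length", "dt")]
  res <- update_sequence_level(st, sch_post, ev, rep)
  post <- res$state$level$posterior
  mem <- vapply(rep$sequences, function(s) s$schema_id, character(1))
  sums <- tapply(as.numeric(post), mem, sum)
  expect_equal(as.numeric(res$upward), as.numeric(sums / sum(sums)),
               tolerance = 1e-9)
})

test_that("without a vision event the bottom-up signal is the prior", {
  rep <- test_repertoire()
  cfg <- test_config()
  st <- sequence_level_init(rep, cfg)
  sch <- uniform_belief(sort(names(rep$schemas)))
  res <- update_sequence_level(st, sch, NULL, rep)
  # prior = posterior = uniform and P_td uniform -> posterior stays uniform
  expect_equal(as.numeric(res$state$level$posterior),
               rep(1 / length(rep$sequences), length(rep$sequences)),
               tolerance = 1e-9)
})

test_that("a schema point mass confines the top-down signal to its members", {
  rep <- test_repertoire()
  cfg <- test_config()
  st <- sequence_level_init(rep, cfg)
  target <- sort(names(rep$schemas))[1]
  sch <- point_belief(sort(names(rep$schemas)), target)
  res <- update_sequence_level(st, sch, NULL, rep)
  mem <- vapply(rep$sequences, function(s) s$schema_id, character(1))
  post <- as.numeric(res$state$level$posterior)
  # members of the boosted schema dominate all non-members
  expect_gt(min(post[mem == target]), max(post[mem != target]))
})

test_that("perceiving a training exemplar recovers its own sequence", {
  rep <- test_repertoire()
  cfg <- test_config()
  corp <- test_corpus(0, setdiff(0:9, 4))
  log <- run_perception(corp$trajectories[["d5_e01"]], rep, cfg, digit = 5)
  map_id <- log$steps$seq_map[nrow(log$steps)]
  expect_equal(rep$sequences[[map_id]]$source_digit, 5)
  # exhaustive oracle: the replayed exemplar's own events score the
  # highest full-sequence likelihood among all stored hypotheses
  obs <- segment_trajectory(corp$trajectories[["d5_e01"]], cfg)
  liks <- vapply(rep$sequences, function(s)
    sequence_likelihood(obs[, c("angle", "length", "dt")], s, config = cfg),
    numeric(1))
  expect_equal(rep$sequences[[names(which.max(liks))]]$source_digit, 5)
  expect_equal(map_id, names(which.max(liks)))
})

test_that("motor goals project events from the current anchor in order", {
  sq <- sequence_hypothesis("s1",
                            ev_table(c(0, pi / 2), c(1, 2), c(0, 0.3)))
  g1 <- emit_motor_goal(sq, 1, c(1, 1))
  expect_false(g1$end)
  expect_equal(g1$target, c(2, 1), tolerance = 1e-12)
  g2 <- emit_motor_goal(sq, 2, g1$target)
  expect_equal(g2$target, c(2, 3), tolerance = 1e-9)
  expect_equal(g2$dt, 0.3)
  expect_true(emit_motor_goal(sq, 3, g2$target)$end)
})
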