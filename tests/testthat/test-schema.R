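test_that("identical sequences collapse into a single schema", {
  ev <- ev_table(c(0.3, 1.5, 4.0), c(0.4, 0.3, 0.5), c(0, 0.2, 0.3))
  seqs <- list(sequence_hypothesis("s001", ev),
               sequence_hypothesis("s002", ev))
  built <- build_schemas(seqs, config = test_config())
  expect_length(built$schemas, 1)
  expect_setequal(built$schemas[[1]]$members, c("s001", "s002"))
})

test_that("schemas partition the repertoire at any threshold", {
  set.seed(21)
  seqs <- lapply(1:12, function(i) {
    n <- sample(2:6, 1)
    sequence_hypothesis(sprintf("s%03d", i),
                        ev_table(stats::runif(n, 0, 2 * pi),
                                 stats::runif(n, 0.1, 1),
                                 c(0, stats::runif(n - 1, 0.05, 0.5))))
  })
  for (thr in c(0.2, 0.6, 0.9)) {
    built <- build_schemas(seqs, thr, test_config())
    members <- unlist(lapply(built$schemas, `[[`, "members"))
    expect_setequal(members, sprintf("s%03d", 1:12))
    expect_equal(length(members), 12)   # each sequence in exactly one schema
    for (s in built$sequences)
      expect_true(s$id %in% built$schemas[[s$schema_id]]$members)
  }
})

test_that("low-noise exemplars cluster into one schema per digit", {
  cfg <- test_config()
  corp <- test_corpus(3, digits = 0:8, n = 4,
                      noise = list(angle = 0.05, scale = 0.03,
                                   timing = 0.03))
  repx <- train_repertoire(corp, cfg)
  mem <- vapply(repx$sequences, function(s) s$schema_id, character(1))
  src <- vapply(repx$sequences, function(s) s$source_digit, integer(1))
  expect_length(repx$schemas, 9)
  expect_true(all(rowSums(table(src, mem) > 0) == 1))
  # independent oracle: single-linkage clusters = connected components of
  # the thresholded similarity graph
  sim <- pairwise_iota(unname(repx$sequences), cfg)
  adj <- sim >= cfg$link_threshold
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  expect_equal(length(unique(comp)), length(repx$schemas))
  same_comp <- outer(comp, comp, "==")
  same_schema <- outer(mem, mem, "==")
  expect_true(all(same_comp == same_schema))
})

test_that("schema updates stay normalized and the boost is monotone", {
  rep <- test_repertoire()
  cfg <- test_config()
  ids <- sort(names(rep$schemas))
  set.seed(8)
  for (i in 1:10) {
    up <- rand_belief(length(ids), ids)
    st0 <- schema_level_init(rep$schemas, cfg)
    plain <- update_schema_level(st0, up, NULL)
    intent <- set_intention(ids[2], rep, boost = cfg$boost, config = cfg)
    boosted <- update_schema_level(st0, up, intent)
    expect_equal(sum(as.numeric(boosted$level$posterior)), 1,
                 tolerance = 1e-9)
    expect_gt(boosted$level$posterior[[ids[2]]],
              plain$level$posterior[[ids[2]]])
  }
})

test_that("an upward point mass drives the schema posterior mode", {
  rep <- test_repertoire()
  ids <- sort(names(rep$schemas))
  st <- schema_level_init(rep$schemas, test_config())
  st <- update_schema_level(st, point_belief(ids, ids[4]), NULL)
  expect_equal(names(which.max(st$level$posterior)), ids[4])
})

test_that("intentions validate their schema and select the intended sequence", {
  rep <- test_repertoire()
  cfg <- test_config()
  expect_error(set_intention("nope", rep, config = cfg), "unknown schema")
  sid <- digit_schema(rep, 9)
  it <- set_intention(sid, rep, config = cfg)
  expect_true(it$active)
  expect_equal(it$s_i, sort(rep$schemas[[sid]]$members)[1])  # uniform tie
  # a neutral boost of 1 is accepted (mode gating without probability change)
  it1 <- set_intention(sid, rep, boost = 1, config = cfg)
  expect_equal(it1$boost, 1)
  st <- schema_level_init(rep$schemas, cfg, "production")
  plain <- update_schema_level(st, NULL, NULL)
  gated <- update_schema_level(st, NULL, it1)
  expect_equal(as.numeric(plain$level$posterior),
               as.numeric(gated$level$posterior), tolerance = 1e-12)
})

test_that("the intended sequence only hands over within its schema", {
  rep <- test_repertoire()
  cfg <- test_config()
  sid <- digit_schema(rep, 9)
  it <- set_intention(sid, rep, config = cfg)
  ids <- names(rep$sequences)
  members <- sort(rep$schemas[[sid]]$members)
  # rival inside the schema above the switch factor: handover happens
  p <- stats::setNames(rep(1e-4, length(ids)), ids)
  p[it$s_i] <- 0.1
  p[members[2]] <- 0.25
  it2 <- maybe_switch_intention(it, belief(p, ids), rep, cfg)
  expect_equal(it2$s_i, members[2])
  # a dominant non-member never captures the intention
  p2 <- stats::setNames(rep(1e-4, length(ids)), ids)
  p2[it$s_i] <- 0.1
  outsider <- setdiff(ids, members)[1]
  p2[outsider] <- 0.9
  it3 <- maybe_switch_intention(it, belief(p2, ids), rep, cfg)
  expect_equal(it3$s_i, it$s_i)
})
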