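# Shared fixtures, built in code and memoised across test files.

.hpbu_test_cache <- new.env(parent = emptyenv())

test_config <- function(...) hpbu_config(...)

# trained repertoire on the standard corpus; memoised per (seed, digits)
test_repertoire <- function(seed = 0, digits = setdiff(0:9, 4)) {
  key <- paste0("rep_", seed, "_", paste(digits, collapse = ""))
  if (is.null(.hpbu_test_cache[[key]])) {
    corp <- generate_corpus(corpus_spec(digits = digits, master_seed = seed))
    .hpbu_test_cache[[key]] <- train_repertoire(corp, test_config())
  }
  .hpbu_test_cache[[key]]
}

test_corpus <- function(seed = 0, digits = 0:9, n = 10,
                        noise = list(angle = 0.1, scale = 0.05,
                                     timing = 0.05)) {
  key <- paste0("corp_", seed, "_", paste(digits, collapse = ""), "_", n,
                "_", noise$angle)
  if (is.null(.hpbu_test_cache[[key]])) {
    .hpbu_test_cache[[key]] <- generate_corpus(
      corpus_spec(digits = digits, n_per_digit = n, noise = noise,
                  master_seed = seed))
  }
  .hpbu_test_cache[[key]]
}

# event table constructor for hand-built sequences
ev_table <- function(angle, length, dt) {
  data.frame(angle = angle, length = length, dt = dt)
}

# simple straight-line trajectory
line_traj <- function(n = 40, from = c(0, 0), to = c(1, 0), dt = 0.01) {
  f <- seq(0, 1, length.out = n)
  data.frame(t = (seq_len(n) - 1) * dt,
             x = from[1] + f * (to[1] - from[1]),
             y = from[2] + f * (to[2] - from[2]))
}

# random belief over n labels
rand_belief <- function(n, labels = paste0("h", seq_len(n))) {
  belief(stats::runif(n, 0.01, 1), labels)
}
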