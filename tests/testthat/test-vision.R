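test_that("angle beliefs peak at the bin of the motion heading", {
  w_east <- data.frame(x = c(0, 1), y = c(0, 0))
  b <- angle_belief(w_east)
  expect_equal(which.max(as.numeric(b)), 1L)   # 0-rad bin
  w_north <- data.frame(x = c(0, 0), y = c(0, 1))
  b <- angle_belief(w_north)
  expect_equal(which.max(as.numeric(b)), 5L)   # pi/2 bin of 16
})

test_that("a 45-degree heading splits kernel mass symmetrically around pi/4", {
  w <- data.frame(x = c(0, 1), y = c(0, 1))
  b <- angle_belief(w, n_angle = 16, kappa = 8)
  # brute-force oracle: evaluate the von Mises kernel at the bin centres
  centers <- angle_bins(16)
  kern <- exp(8 * cos(centers - pi / 4))
  expect_equal(as.numeric(b), kern / sum(kern), tolerance = 1e-9)
  # pi/4 is the centre of bin a2; its neighbours share mass symmetrically
  expect_equal(which.max(as.numeric(b)), 3L)
  expect_equal(b[["a1"]], b[["a3"]], tolerance = 1e-9)
})

test_that("zero displacement yields a uniform no-motion belief", {
  w <- data.frame(x = c(0.3, 0.3), y = c(0.2, 0.2))
  expect_equal(as.numeric(angle_belief(w)), rep(1 / 16, 16),
               tolerance = 1e-12)
})

test_that("oculocentric transform matches the polar oracle and round-trips", {
  e <- to_oculocentric(c(0, 0), c(1, 0), 0.1)
  expect_equal(c(e$angle, e$length), c(0, 1))
  e <- to_oculocentric(c(0, 0), c(1, 1), 0.1)
  expect_equal(c(e$angle, e$length), c(pi / 4, sqrt(2)), tolerance = 1e-12)
  # degenerate case: angle 0 by convention
  e <- to_oculocentric(c(2, 3), c(2, 3), 0)
  expect_equal(c(e$angle, e$length), c(0, 0))
  set.seed(5)
  for (i in 1:25) {
    origin <- stats::runif(2, -5, 5); target <- stats::runif(2, -5, 5)
    ev <- to_oculocentric(origin, target, 0.1)
    expect_equal(from_oculocentric(origin, ev), target, tolerance = 1e-9)
  }
})

test_that("straight motion produces no surprise events before the pen lifts", {
  tr <- line_traj(60)
  st <- vision_init(test_config())
  for (i in seq_len(nrow(tr)))
    st <- vision_step(st, tr$t[i], c(tr$x[i], tr$y[i]))
  expect_equal(nrow(st$events), 0L)
  # the terminal flush closes the single stroke
  st <- vision_finish(st)
  expect_equal(nrow(st$events), 1L)
  expect_equal(st$events$angle[1], 0, tolerance = 1e-9)
  expect_equal(st$events$length[1], 1, tolerance = 1e-9)
})

test_that("an L-shaped corner fires exactly one in-stroke event at the corner", {
  n <- 40
  leg1 <- data.frame(t = (0:(n - 1)) * 0.01,
                     x = seq(0, 1, length.out = n), y = 0)
  leg2 <- data.frame(t = (n:(2 * n - 1)) * 0.01,
                     x = 1, y = seq(0, 1, length.out = n)[-1][1:n])
  tr <- rbind(leg1, leg2)
  tr <- tr[!is.na(tr$y), ]
  st <- vision_init(test_config())
  for (i in seq_len(nrow(tr)))
    st <- vision_step(st, tr$t[i], c(tr$x[i], tr$y[i]))
  expect_equal(nrow(st$events), 1L)
  # the event anchors at the corner (1, 0) within one sample
  expect_lt(abs(st$events$x[1] - 1), 0.05)
  expect_lt(abs(st$events$y[1] - 0), 0.05)
  # full segmentation adds the flush event for the second leg
  ev <- segment_trajectory(tr, test_config())
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$angle[2], pi / 2, tolerance = 0.1)
})

test_that("no event can fire during the burn-in window", {
  tr <- line_traj(3)
  st <- vision_init(test_config())
  for (i in seq_len(nrow(tr)))
    st <- vision_step(st, tr$t[i], c(tr$x[i], tr$y[i]))
  expect_equal(nrow(st$events), 0L)
})

test_that("event counts are invariant under translation and uniform rescaling", {
  tmpl <- digit_templates()[["3"]]
  tr <- generate_digit(tmpl, seed = 4)
  cfg <- test_config()
  n0 <- nrow(segment_trajectory(tr, cfg))
  shifted <- transform(tr, x = x + 7, y = y - 3)
  scaled <- transform(tr, x = x * 5, y = y * 5)
  expect_equal(nrow(segment_trajectory(shifted, cfg)), n0)
  expect_equal(nrow(segment_trajectory(scaled, cfg)), n0)
})

test_that("replaying a training trajectory reproduces its stored events", {
  rep <- test_repertoire()
  corp <- test_corpus(0, setdiff(0:9, 4))
  ev <- segment_trajectory(corp$trajectories[["d5_e01"]], test_config())
  stored <- NULL
  for (s in rep$sequences)
    if (s$source_digit == 5 && is.null(stored)) stored <- s
  expect_equal(nrow(ev), nrow(stored$events))
  expect_equal(ev$angle, stored$events$angle, tolerance = 2 * pi / 16)
  expect_equal(ev$dt, stored$events$dt, tolerance = 0.011)
})

test_that("trajectory files round-trip exactly through CSV and JSON", {
  tr <- generate_digit(digit_templates()[["2"]], seed = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trajectory(tr, csv)
  write_trajectory(tr, js)
  expect_equal(read_trajectory(csv), tr, tolerance = 0)
  expect_equal(read_trajectory(js), tr, tolerance = 0)
  expect_error(write_trajectory(data.frame(t = c(1, 1), x = 0:1, y = 0:1),
                                csv),
               "increasing")
})

test_that("motor done confirmation demands spatial and temporal agreement", {
  cfg <- test_config()
  vis <- vision_init(cfg)
  done <- list(subgoal = c(1, 0), time = 0.50, length = 1)
  # veridical: visual pen sits on the subgoal at the done time
  ev <- confirm_motor_done(done, vis, c(0.50, 1.0, 0.0), c(0, 0), NA, cfg)
  expect_false(is.null(ev))
  expect_equal(ev$length, 1, tolerance = 1e-9)
  expect_equal(ev$dt, 0)
  # substituted feedback far from the subgoal: no confirmation
  expect_null(confirm_motor_done(done, vis, c(0.50, 0.2, 0.9), c(0, 0), NA,
                                 cfg))
  # no visual sample inside the confirmation window: no confirmation
  expect_null(confirm_motor_done(done, vis, c(0.10, 1.0, 0.0), c(0, 0), NA,
                                 cfg))
  expect_null(confirm_motor_done(done, vis, NULL, c(0, 0), NA, cfg))
})
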