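test_that("the minimum of a V-shaped fitted curve is located at its bottom bin", {
  n <- 100
  y <- pmin(abs(0:(n - 1) - 37), n - abs(0:(n - 1) - 37)) + 5
  s <- structure(list(fitted = y, retained = rep(TRUE, n),
                      mask = rep(FALSE, n), bin_width = 1000,
                      genome_length = n * 1000),
                 class = "smoothed_profile")
  cfg <- chrom_config(n * 1000, c(ori = 87000))
  mn <- find_termination_minima(s, cfg)
  expect_equal(mn$position_bp, 37000)
  expect_equal(mn$position_mbp, 0.037)
  expect_false(mn$suspect)
})

test_that("ties break toward the smaller coordinate and origins are excluded", {
  n <- 50
  y <- rep(1, n); y[c(10, 30)] <- 0.5
  s <- structure(list(fitted = y, retained = rep(TRUE, n),
                      mask = rep(FALSE, n), bin_width = 1000,
                      genome_length = n * 1000),
                 class = "smoothed_profile")
  cfg <- chrom_config(n * 1000, c(ori = 0))
  expect_equal(find_termination_minima(s, cfg)$position_bp, 9000)
  # the origin bin can never be the terminus even if it is the lowest value
  y2 <- rep(1, n); y2[1] <- 0.1; y2[25] <- 0.6
  s2 <- s; s2$fitted <- y2
  expect_equal(find_termination_minima(s2, cfg)$position_bp, 24000)
})

test_that("noise-free symmetric simulations put minima at the fusion points", {
  # near-symmetric wild-type-like strain: single origin, traps untriggered
  cfg <- ecoli_model("oriC")
  nf <- noise_free_profile(cfg, 19.9)
  s <- remove_outliers_and_refit(nf$profile, smoothing_params())
  mn <- find_termination_minima(s, cfg)
  expect_lte(circular_distance(mn$position_bp, nf$timing$fusions$position_bp,
                               cfg$length_bp), 1000)
  # dual-origin strain: one minimum per inter-origin arc
  cfg2 <- ecoli_model()
  nf2 <- noise_free_profile(cfg2, 20.6)
  s2 <- remove_outliers_and_refit(nf2$profile, smoothing_params())
  mn2 <- find_termination_minima(s2, cfg2)
  expect_equal(nrow(mn2), 2)
  # the origin-proximal fusion is recovered to a bin; the trap-step minimum
  # is displaced by the smoothing window, bounded by half the window
  fus <- sort(nf2$timing$fusions$position_bp)
  got <- sort(mn2$position_bp)
  errs <- circular_distance(got, fus, cfg2$length_bp)
  expect_lte(min(errs), 1000)
  expect_true(all(errs <= s2$window_bp / 2))
})

test_that("inactivating the trap moves both dual-origin minima toward the midpoints", {
  cfg <- ecoli_model()
  tm_t <- simulate_replication_timing(cfg, simulation_params(doubling_time_min = 20.6))
  tm_n <- simulate_replication_timing(cfg, simulation_params(doubling_time_min = 20.6,
                                                             tus_active = FALSE))
  for (tm in list(tm_t, tm_n)) {
    cn <- timing_to_copy_number(tm, 20.6)
    s <- remove_outliers_and_refit(mfa_profile(cn / mean(cn)), smoothing_params())
    mn <- find_termination_minima(s, cfg)
    rep <- replichore_report(mn, cfg)
    if (identical(tm, tm_t)) shifts_tus <- abs(rep$midpoints$shift_kb)
    else shifts_free <- abs(rep$midpoints$shift_kb)
  }
  expect_true(all(shifts_free <= shifts_tus + 1))
})

test_that("replichore arms and shifts follow the printed geometry", {
  cfg <- chrom_config(4640000, c(oriZ = 344000))
  mn <- data.frame(arc_from = "oriZ", arc_to = "oriZ", position_bp = 1709000)
  rep <- replichore_report(mn, cfg)
  expect_equal(rep$replichore_lengths$clockwise_mbp, 1.365)
  expect_equal(rep$replichore_lengths$counterclockwise_mbp, 3.275)
  expect_equal(round(rep$replichore_lengths$counterclockwise_mbp, 1), 3.3)
  # a minimum at the midpoint has zero shift
  mn0 <- data.frame(arc_from = "oriZ", arc_to = "oriZ", position_bp = 2664000)
  expect_equal(replichore_report(mn0, cfg)$midpoints$shift_kb, 0)
  # dual-origin shifts, signed clockwise, from the printed minima
  cfg2 <- chrom_config(4640000, c(oriC = 3923000, oriZ = 344000))
  mn2 <- data.frame(arc_from = c("oriZ", "oriC"), arc_to = c("oriC", "oriZ"),
                    position_bp = c(1699000, 4459000))
  rep2 <- replichore_report(mn2, cfg2)
  sh <- rep2$midpoints$shift_kb[order(rep2$midpoints$midpoint_bp)]
  expect_equal(sh, c(-434.5, 5.5))
})

test_that("gradient scores are one on a pure exponential gradient", {
  L <- 200000
  cfg <- chrom_config(L, c(ori = 0),
                      slow_zones = data.frame(
                        name = "z", start_bp = 40000, end_bp = 60000,
                        transcription_direction = "counterclockwise",
                        head_on_factor = 0.5, codirectional_factor = 1))
  # hand-built exponential profile: log2 gradient constant on each arm
  tm <- simulate_replication_timing(
    chrom_config(L, c(ori = 0)), simulation_params())
  cn <- timing_to_copy_number(tm, 2)
  s <- structure(list(fitted = cn, retained = rep(TRUE, 200),
                      mask = rep(FALSE, 200), bin_width = 1000,
                      genome_length = L),
                 class = "smoothed_profile")
  sc <- gradient_deviation_scores(s, cfg)
  expect_equal(sc$score, 1, tolerance = 0.05)
})

test_that("a head-on zone that halves fork speed scores about two", {
  L <- 200000
  cfg <- chrom_config(L, c(ori = 0),
                      slow_zones = data.frame(
                        name = "z", start_bp = 40000, end_bp = 60000,
                        transcription_direction = "counterclockwise",
                        head_on_factor = 0.5, codirectional_factor = 1))
  tm <- simulate_replication_timing(cfg, simulation_params())
  cn <- timing_to_copy_number(tm, 2)
  s <- structure(list(fitted = cn, retained = rep(TRUE, 200),
                      mask = rep(FALSE, 200), bin_width = 1000,
                      genome_length = L),
                 class = "smoothed_profile")
  sc <- gradient_deviation_scores(s, cfg)
  expect_equal(sc$score, 2, tolerance = 0.1)
  # invariant to rescaling the profile
  s2 <- s; s2$fitted <- s$fitted * 37
  expect_equal(gradient_deviation_scores(s2, cfg)$score, sc$score)
})

test_that("a flat arm makes the score undefined with a signal", {
  n <- 100
  cfg <- chrom_config(n * 1000, c(ori = 0),
                      slow_zones = data.frame(
                        name = "z", start_bp = 20000, end_bp = 30000,
                        transcription_direction = "clockwise",
                        head_on_factor = 0.5, codirectional_factor = 1))
  s <- structure(list(fitted = rep(1, n), retained = rep(TRUE, n),
                      mask = rep(FALSE, n), bin_width = 1000,
                      genome_length = n * 1000),
                 class = "smoothed_profile")
  expect_warning(sc <- gradient_deviation_scores(s, cfg), "epsilon")
  expect_true(is.na(sc$score))
})
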