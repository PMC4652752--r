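test_that("single-origin timing without traps is symmetric and matches distance/speed", {
  cfg <- toy_config()
  tm <- simulate_replication_timing(cfg, simulation_params())
  expect_equal(tm$t_rep, c(0:5, 4:1))
  expect_equal(tm$fusions$position_bp, 5000)
  expect_equal(max(tm$fusions$time_s), 5)
  # oracle equivalence: circular_distance / fork_speed at every bin start
  starts <- (0:9) * 1000
  expect_equal(tm$t_rep, circular_distance(starts, rep(0, 10), 10000) / 1000)
})

test_that("a polar trap produces the hand-traced event sequence", {
  cfg <- toy_config(ter_sites = data.frame(name = "t", position_bp = 3000,
                                           block = "blocks_clockwise",
                                           efficiency = 1))
  tm <- simulate_replication_timing(cfg, simulation_params())
  expect_equal(tm$t_rep, c(0, 1, 2, 7, 6, 5, 4, 3, 2, 1))
  expect_equal(tm$fusions$position_bp, 3000)
  expect_equal(tm$fusions$time_s, 7)
  # closed form: beyond the trap every bin carries the far fork's arrival time
  expect_equal(tm$t_rep[5:10], (10000 - (4:9) * 1000) / 1000)
  expect_true(any(grepl("^block:", tm$events$type)))
})

test_that("transparent traps (tus off) restore the symmetric profile", {
  cfg <- toy_config(ter_sites = data.frame(name = "t", position_bp = 3000,
                                           block = "blocks_clockwise",
                                           efficiency = 1))
  tm <- simulate_replication_timing(cfg, simulation_params(tus_active = FALSE))
  expect_equal(tm$t_rep, c(0:5, 4:1))
})

test_that("two simultaneous origins fuse midway between them", {
  cfg <- toy_config(origins = c(a = 0, b = 5000))
  tm <- simulate_replication_timing(cfg, simulation_params())
  expect_setequal(tm$fusions$position_bp, c(2500, 7500))
  expect_equal(max(tm$fusions$time_s), 2.5)
  expect_equal(tm$t_rep[c(1, 6)], c(0, 0))  # origin bins
})

test_that("opposed traps leaving an unreachable region are an explicit error", {
  cfg <- toy_config(ter_sites = data.frame(
    name = c("t1", "t2"), position_bp = c(3000, 7000),
    block = c("blocks_clockwise", "blocks_counterclockwise"),
    efficiency = c(1, 1)))
  expect_error(simulate_replication_timing(cfg, simulation_params()),
               "unreachable")
})

test_that("head-on slow zones scale the local timing gradient by 1/factor", {
  cfg <- chrom_config(100000, c(ori = 0),
                      slow_zones = data.frame(
                        name = "z", start_bp = 20000, end_bp = 30000,
                        transcription_direction = "counterclockwise",
                        head_on_factor = 0.5, codirectional_factor = 1))
  tm <- simulate_replication_timing(cfg, simulation_params())
  g <- diff(tm$t_rep[1:45])
  expect_equal(unique(g[1:20]), 1)        # full speed outside
  expect_equal(unique(g[21:30]), 2)       # 1/0.5 inside the head-on zone
  # the rpo* flag relieves half of the deficit: factor 0.75 -> dt 4/3
  tmr <- simulate_replication_timing(cfg, simulation_params(rpo_star = TRUE))
  expect_equal(unique(diff(tmr$t_rep[1:45])[21:30]), 1 / 0.75)
})

test_that("barrier elements impose their pause on crossing forks", {
  cfg <- toy_config(barriers = data.frame(name = "tetO", position_bp = 2000,
                                          pause_s = 3))
  tm <- simulate_replication_timing(cfg, simulation_params())
  expect_equal(tm$t_rep[1:3], c(0, 1, 2))
  expect_equal(tm$t_rep[4], 6)            # 3 s pause at the array
})

test_that("partial trap efficiency is a reproducible coin flip", {
  cfg <- toy_config(ter_sites = data.frame(name = "t", position_bp = 3000,
                                           block = "blocks_clockwise",
                                           efficiency = 0.5))
  t1 <- simulate_replication_timing(cfg, simulation_params(seed = 5))
  t2 <- simulate_replication_timing(cfg, simulation_params(seed = 5))
  expect_identical(t1$t_rep, t2$t_rep)
})

test_that("copy number follows the exponential-population law", {
  expect_equal(timing_to_copy_number(rep(0, 4), 10), rep(1, 4))
  expect_equal(timing_to_copy_number(600, 10), 0.5)   # one doubling time
  cfg <- toy_config(ter_sites = data.frame(name = "t", position_bp = 3000,
                                           block = "blocks_clockwise",
                                           efficiency = 1))
  tm <- simulate_replication_timing(cfg, simulation_params())
  cn <- timing_to_copy_number(tm, 10 / 60)            # tau_d = 10 s
  expect_equal(cn[4], 2^(-0.7), tolerance = 1e-12)    # terminus bin, t = 7
  # origin/terminus ratio equals 2^(t_max / tau_d)
  expect_equal(max(cn) / min(cn), 2^(max(tm$t_rep) / 10), tolerance = 1e-12)
  expect_true(all(diff(cn[order(tm$t_rep)]) <= 1e-12))
  expect_error(timing_to_copy_number(tm, -1), "positive")
})

test_that("count pairs are reproducible and unbiased without mappability bias", {
  cn <- 2^(-seq(0, 1, length.out = 400))
  pars <- simulation_params(mean_depth_per_bin = 2000, bias_sd_log = 0, seed = 3)
  p1 <- sample_count_pair(cn, pars)
  p2 <- sample_count_pair(cn, pars)
  expect_identical(p1$exponential$counts, p2$exponential$counts)
  expect_identical(p1$stationary$counts, p2$stationary$counts)
  expect_equal(p1$bias, rep(1, 400))
  # Poisson means proportional to copy number
  expect_equal(cor(p1$exponential$counts, cn), 1, tolerance = 0.01)
  expect_equal(mean(p1$stationary$counts), 2000, tolerance = 0.05)
})

test_that("shared bias cancels in the marker frequency", {
  cn <- 2^(-seq(0, 1.5, length.out = 800))
  pars <- simulation_params(mean_depth_per_bin = 200, bias_sd_log = 0.3, seed = 9)
  pair <- sample_count_pair(cn, pars)
  mf <- marker_frequency(pair$exponential, pair$stationary)
  expect_gt(cor(mf$enrichment, cn, use = "complete.obs"),
            cor(pair$exponential$counts, cn))
})

test_that("inverting a segment is an involution and matches the hand example", {
  x <- 0:9
  expect_equal(apply_inversion(x, 2, 6), c(0, 1, 5, 4, 3, 2, 6:9))
  expect_equal(apply_inversion(apply_inversion(x, 2, 6), 2, 6), x)
  expect_equal(apply_inversion(x, 3, 4), x)            # single-bin segment
  # wrap-through-zero segment
  xw <- apply_inversion(x, 8, 2)
  expect_equal(xw, c(9, 8, 2:7, 1, 0))
  expect_equal(apply_inversion(xw, 8, 2), x)
  # snapping and strict mode on off-boundary breakpoints
  bc <- binned_coverage(1:10, 1000, 10000)
  expect_warning(apply_inversion(bc, 2500, 6000), "snapped")
  expect_error(apply_inversion(bc, 2500, 6000, strict = TRUE), "boundary")
  expect_error(apply_inversion(x, 3, 3), "differ")
})

test_that("growth curves follow the multi-subpopulation closed form", {
  g <- simulate_growth_curve(data.frame(fraction = 1, doubling_time_min = 20),
                             n0_cfu_per_ml = 1e6)
  expect_equal(g$times_min, seq(0, 480, by = 30))
  expect_equal(g$cfu_per_ml[g$times_min == 60] /
                 g$cfu_per_ml[g$times_min == 0], 8)  # 3 doublings in 60 min
  # a 1% fast subpopulation makes the log-count curve convex (biphasic)
  gb <- simulate_growth_curve(data.frame(fraction = c(0.99, 0.01),
                                         doubling_time_min = c(40, 20)))
  lc <- log2(gb$cfu_per_ml)
  expect_true(all(diff(diff(lc)) > 0))
  # deterministic without noise; reproducible with seed
  g2 <- simulate_growth_curve(data.frame(fraction = 1, doubling_time_min = 20),
                              n0_cfu_per_ml = 1e6)
  expect_identical(g$cfu_per_ml, g2$cfu_per_ml)
  n1 <- simulate_growth_curve(noise_sd_log = 0.1, seed = 4)
  n2 <- simulate_growth_curve(noise_sd_log = 0.1, seed = 4)
  expect_identical(n1$cfu_per_ml, n2$cfu_per_ml)
})

test_that("the simulated ectopic-origin strain shows the terminus step", {
  cfg <- ecoli_model("oriZ")
  tm <- simulate_replication_timing(cfg, simulation_params(doubling_time_min = 39.8))
  cn <- timing_to_copy_number(tm, 39.8)
  # fusion is confined at the innermost clockwise-blocking ter site
  terC <- cfg$ter_sites$position_bp[cfg$ter_sites$name == "terC"]
  expect_equal(tm$fusions$position_bp, terC)
  # discontinuity at the trap: the jump there dwarfs neighbouring gradients
  j <- terC / 1000
  step <- abs(cn[j + 1] - cn[j])
  expect_gt(step, 50 * median(abs(diff(cn[1:200]))))
})
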