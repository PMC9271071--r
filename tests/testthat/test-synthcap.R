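test_that("the default configuration matches the published task design", {
  cfg <- sim_config()
  expect_identical(cfg$n_cs_plus, 48L)
  expect_identical(cfg$n_cs_minus, 48L)
  expect_equal(cfg$iti_set, c(20, 28, 36, 44, 56, 68, 96, 120))
  expect_equal(cfg$cs_duration, 4)
  expect_equal(cfg$access_duration, 8)
  expect_equal(cfg$cs_minus_exclusion, 3)
  expect_equal(cfg$alternation_p, 0.6)
  expect_equal(cfg$p_drink_given_correct, 0.95)
})

test_that("configuration validation rejects out-of-range values", {
  expect_error(sim_config(alternation_p = 1.4), "probabilities")
  expect_error(sim_config(n_cs_plus = 0L), "n_cs_plus")
  expect_error(sim_config(change_point_trial = 99L), "change_point_trial")
  expect_error(sim_config(signal_gains = list(g = c(seek = 1))),
               "signal_gains")
})

test_that("schedules are legal, complete, and reproducible", {
  cfg <- sim_config(seed = 21L)
  sch <- generate_schedule(cfg)
  expect_identical(nrow(sch), 96L)
  expect_identical(sum(sch$cs_type == "plus"), 48L)
  expect_identical(sum(sch$cs_type == "minus"), 48L)
  expect_true(all(diff(sch$cs_onset) > 0))
  expect_true(assert_schedule_legal(sch, cfg))
  # CS+ end-to-onset gaps come from the published ITI set
  plus <- sch[sch$cs_type == "plus", ]
  gaps <- diff(plus$cs_onset) - (cfg$cs_duration + cfg$access_duration)
  expect_true(all(vapply(gaps, function(g) {
    any(abs(g - cfg$iti_set) < 1e-9)
  }, logical(1))))
  expect_identical(generate_schedule(cfg), sch)
  expect_false(identical(generate_schedule(cfg, seed = 22L)$cs_onset,
                         sch$cs_onset))
})

test_that("the type sequence alternates with the task's bias", {
  set.seed(77)
  flips <- 0L; total <- 0L
  for (r in 1:40) {
    s <- draw_type_sequence(48L, 48L, 0.6)
    flips <- flips + sum(diff(s) != 0)
    total <- total + length(s) - 1L
  }
  expect_gt(flips / total, 0.57)
  expect_lt(flips / total, 0.63)
})

test_that("behavior switches from high to low approach at the planted trial", {
  cfg <- sim_config(p_approach_high = 1, p_approach_low = 0,
                    change_point_trial = 25L, seed = 3L)
  sch <- generate_schedule(cfg)
  beh <- simulate_behavior(sch, cfg)
  plus <- beh$trials[beh$trials$cs_type == "plus", ]
  plus <- plus[order(plus$cs_index), ]
  expect_identical(as.integer(plus$approach),
                   c(rep(1L, 24), rep(0L, 24)))
  expect_identical(beh$truth$change_point_trial, 25L)
  # drinking only on correct approach trials
  expect_true(all(!plus$drink[!plus$approach]))
  expect_true(all(plus$correct[plus$drink] %in% TRUE))
})

test_that("approach rates match the planted state probabilities", {
  set.seed(9)
  pre <- c(); post <- c()
  for (r in 1:20) {
    cfg <- sim_config(seed = 400L + r)
    sch <- generate_schedule(cfg)
    beh <- simulate_behavior(sch, cfg, seed = 500L + r)
    plus <- beh$trials[beh$trials$cs_type == "plus", ]
    plus <- plus[order(plus$cs_index), ]
    pre <- c(pre, plus$approach[plus$cs_index < 25])
    post <- c(post, plus$approach[plus$cs_index >= 25])
  }
  expect_gt(mean(pre), 0.85)
  expect_lt(mean(post), 0.25)
})

test_that("tracking ground truth is kinematically consistent", {
  cfg <- sim_config(seed = 31L, n_neurons = 5L)
  sch <- generate_schedule(cfg)
  beh <- simulate_behavior(sch, cfg)
  trk <- simulate_tracking(beh$trials, cfg)
  tt <- trk$truth
  ap <- which(beh$trials$approach & beh$trials$cs_type == "plus")
  expect_true(all(!is.na(tt$approach_init[ap])))
  expect_true(all(tt$arrival[ap] > tt$approach_init[ap], na.rm = TRUE))
  # drink times only on correct approach trials, inside the access window
  dk <- which(!is.na(tt$drink_time))
  expect_true(all(beh$trials$correct[dk] %in% TRUE))
  expect_true(all(tt$drink_time[dk] >= cfg$cs_duration))
  expect_true(all(tt$drink_time[dk] <=
                    cfg$cs_duration + cfg$access_duration))
  expect_true(all(trk$tracking$x >= 0 & trk$tracking$x <= cfg$arena_width))
})

test_that("no-approach trials never reach a sipper", {
  cfg <- sim_config(seed = 57L, tracking_noise_sd = 0)
  sch <- generate_schedule(cfg)
  beh <- simulate_behavior(sch, cfg)
  trk <- simulate_tracking(beh$trials, cfg)
  plus <- beh$trials[beh$trials$cs_type == "plus", ]
  noap <- which(!plus$approach)
  d <- detect_drink_initiation(plus, trk$tracking, trk$sippers, cfg)
  expect_true(all(is.na(d[noap])))
})

test_that("zero gains give a homogeneous Poisson population at baseline", {
  cfg <- sim_config(n_cs_plus = 8L, n_cs_minus = 8L, n_neurons = 30L,
                    iti_set = c(20, 28), baseline_rate = 5,
                    change_point_trial = 5L,
                    signal_gains = list(g = c(seek = 0, cue = 0,
                                              approach = 0, drink = 0)),
                    seed = 61L)
  s <- simulate_session(cfg, group = "g", seed = 61L)
  dur <- max(s$spikes$spike_time)
  rate <- nrow(s$spikes) / cfg$n_neurons / dur
  se <- sqrt(cfg$baseline_rate / (cfg$n_neurons * dur))
  expect_lt(abs(rate - cfg$baseline_rate), 3 * se)
})

test_that("rates above the cap raise a configuration error", {
  cfg <- sim_config(n_cs_plus = 8L, n_cs_minus = 8L, n_neurons = 30L,
                    iti_set = c(20, 28), change_point_trial = 5L,
                    signal_gains = list(g = c(seek = 20, cue = 20,
                                              approach = 20, drink = 20)),
                    seed = 62L)
  expect_error(simulate_session(cfg, group = "g", seed = 62L), "rate_cap")
})

test_that("session simulation is deterministic in the root seed", {
  cfg <- sim_config(n_cs_plus = 8L, n_cs_minus = 8L, n_neurons = 10L,
                    iti_set = c(20, 28), change_point_trial = 5L,
                    signal_gains = list(g = c(seek = 1, cue = 1,
                                              approach = 1, drink = 1)),
                    seed = 63L)
  s1 <- simulate_session(cfg, group = "g", seed = 63L)
  s2 <- simulate_session(cfg, group = "g", seed = 63L)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$tracking, s2$tracking)
  s3 <- simulate_session(cfg, group = "g", seed = 64L)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("derived seeds and config hashes are stable and distinct", {
  expect_identical(derive_seed(1L, 1L), derive_seed(1L, 1L))
  expect_false(derive_seed(1L, 1L) == derive_seed(1L, 2L))
  expect_true(derive_seed(2147483000L, 999L) >= 1)
  expect_true(derive_seed(2147483000L, 999L) < 2^31)
  c1 <- sim_config(seed = 1L)
  c2 <- sim_config(seed = 2L)
  expect_identical(config_hash(c1), config_hash(c1))
  expect_false(identical(config_hash(c1), config_hash(c2)))
})
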