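make_tracking <- function(times, xy) {
  data.frame(time = times, x = xy[, 1], y = xy[, 2])
}

test_that("approach likelihood is exact in the degenerate label cases", {
  set.seed(41)
  n <- 6
  trials <- data.frame(cs_onset = seq(0, by = 20, length.out = n),
                       approach = rep(TRUE, n))
  tk <- data.frame(time = seq(0, 130, by = 0.05),
                   x = runif(2601, 0, 600), y = runif(2601, 0, 200))
  q <- approach_likelihood(trials, tk, window = c(0, 2))
  expect_true(all(abs(q$q - 1) < 1e-9))
  trials$approach <- rep(FALSE, n)
  q0 <- approach_likelihood(trials, tk, window = c(0, 2))
  expect_true(all(abs(q0$q) < 1e-9))
})

test_that("weights are normalized inverse distances (hand computation)", {
  # three trials; identical motion except a constant x offset, so distances
  # are constant across bins: d(1,2) = 1, d(1,3) = 2 in raw x units
  base <- seq(0, 0.9, by = 0.1)
  trials <- data.frame(cs_onset = c(0, 100, 200),
                       approach = c(FALSE, TRUE, FALSE))
  mk_seg <- function(x0) cbind(x0 + base * 10, 50 + base * 10)
  tk <- rbind(
    make_tracking(seq(0, 0.9, 0.1), mk_seg(0)),
    make_tracking(100 + seq(0, 0.9, 0.1), mk_seg(30)),
    make_tracking(200 + seq(0, 0.9, 0.1), mk_seg(60)))
  q <- approach_likelihood(trials, tk, window = c(0, 1),
                           return_weights = TRUE)
  # z-scoring rescales x but preserves the 1:2 distance ratio, so
  # q_1 = (1/1) / (1/1 + 1/2) = 2/3 up to the epsilon regularizer
  expect_equal(q$q[1, ], rep(2 / 3, ncol(q$q)), tolerance = 1e-4)
  W <- q$weights
  sums <- apply(W, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a step in approach likelihood is detected at the step bin", {
  qs <- matrix(c(rep(0.1, 20), rep(0.9, 100)), 1, 120, byrow = TRUE)
  q <- list(q = qs, t_rel = seq(0, 11.9, by = 0.1), trials = 1L, p = 1,
            bin_width = 0.1)
  ai <- detect_approach_initiation(q)
  expect_equal(ai$approach_init, 2.0) # first post-change bin is bin 21
  expect_equal(ai$magnitude, 0.8, tolerance = 1e-12)
})

test_that("flat approach likelihood is flagged as undefined", {
  q <- list(q = matrix(0.5, 1, 120), t_rel = seq(0, 11.9, by = 0.1),
            trials = 1L, p = 1, bin_width = 0.1)
  ai <- detect_approach_initiation(q)
  expect_true(is.na(ai$approach_init))
})

test_that("surrogate times are drawn from the session's real event pool", {
  tr <- data.frame(approach_init = c(1.5, NA, 2.5, NA, NA),
                   drink_time = c(5, NA, 6, NA, NA))
  out <- assign_surrogate_times(tr, "approach", seed = 8L)
  expect_true(all(!is.na(out$approach_init)))
  expect_true(all(out$approach_init[out$approach_surrogate] %in% c(1.5, 2.5)))
  expect_identical(out$approach_init[c(1, 3)], c(1.5, 2.5))
  expect_identical(out$approach_surrogate, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  # reproducible in the seed
  expect_identical(assign_surrogate_times(tr, "approach", seed = 8L),
                   out)
  tr$approach_init <- NA_real_
  expect_error(assign_surrogate_times(tr, "approach"), "no real")
})

test_that("drink initiation is the first sample within the sipper radius", {
  trials <- data.frame(cs_type = "plus", side = "left", cs_onset = 0)
  cfg <- list(cs_duration = 4, access_duration = 8)
  sip <- list(left = c(40, 120), right = c(600, 120))
  tm <- seq(0, 12, by = 0.1)
  x <- rep(300, length(tm)); y <- rep(120, length(tm))
  x[tm >= 6.0] <- 45 # within 9 px of the left sipper from 6.0 s
  d <- detect_drink_initiation(trials, data.frame(time = tm, x = x, y = y),
                               sip, cfg)
  expect_equal(d, 6.0)
  # never entering the radius yields NA
  d2 <- detect_drink_initiation(trials,
                                data.frame(time = tm, x = rep(300, length(tm)),
                                           y = y), sip, cfg)
  expect_true(is.na(d2))
  expect_error(detect_drink_initiation(trials, NULL, list(), cfg), "sipper")
})

test_that("cs sensitivity is the CS+ share of all approaches", {
  tr <- data.frame(cs_type = c("plus", "plus", "minus", "minus"),
                   approach = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(cs_sensitivity(tr), 2 / 3)
  tr$approach <- FALSE
  expect_error(cs_sensitivity(tr), "zero approaches")
})

test_that("phenotype classification follows the strain and both thresholds", {
  ses <- data.frame(
    strain = c(rep("P", 4), rep("Wistar", 4)),
    consumption_alcohol = c(10, 10, 10, 10, 8, 8, 8, 8),
    consumption_quinine = c(9, 9.5, 9.2, 2.0, 1.0, 1.2, 1.1, 7.5))
  out <- classify_session_phenotype(ses)
  # P sessions default compulsive; the low-quinine outlier with > 50%
  # decrease is reclassified non-compulsive
  expect_identical(out$label[1:3], rep("compulsive", 3))
  expect_identical(out$label[4], "non-compulsive")
  # Wistar sessions default non-compulsive; the high-quinine outlier with
  # < 50% decrease is reclassified compulsive
  expect_identical(out$label[5:7], rep("non-compulsive", 3))
  expect_identical(out$label[8], "compulsive")
  expect_identical(out$reclassified, c(rep(FALSE, 3), TRUE,
                                       rep(FALSE, 3), TRUE))
  expect_error(classify_session_phenotype(
    data.frame(strain = c("P", "Wistar", "Wistar"),
               consumption_alcohol = c(1, 1, 1),
               consumption_quinine = c(1, 1, 1))), "< 2 sessions")
  expect_error(classify_session_phenotype(
    data.frame(strain = "rat", consumption_alcohol = 1,
               consumption_quinine = 1)))
})

test_that("session metrics summarize sipper occupancy sensibly", {
  cfg <- sim_config(seed = 83L)
  sch <- generate_schedule(cfg)
  beh <- simulate_behavior(sch, cfg)
  trk <- simulate_tracking(beh$trials, cfg)
  m <- session_metrics(beh$trials, trk$tracking, trk$sippers, cfg)
  expect_equal(m$prop_approached, mean(beh$trials$approach))
  plus <- beh$trials[beh$trials$cs_type == "plus", ]
  drank <- which(plus$drink)
  expect_true(all(m$time_at_sipper[drank] > 1))
  expect_true(all(!is.na(m$latency[drank])))
  expect_true(all(m$occupancy$likelihood >= 0 & m$occupancy$likelihood <= 1))
})
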