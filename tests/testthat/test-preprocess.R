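test_that("binning uses half-open 100-ms bins at 10 Hz", {
  sp <- list(u1 = c(0, 0.05, 0.1, 0.199999, 0.2), u2 = numeric(0))
  m <- bin_spikes(sp, bin_width = 0.1, duration = 1)
  expect_identical(dim(m), c(2L, 10L))
  expect_identical(as.integer(m["u1", 1:3]), c(2L, 2L, 1L))
  expect_identical(sum(m["u2", ]), 0L)
  expect_equal(attr(m, "bin_width"), 0.1)
  expect_error(bin_spikes(list(u = c(-0.1)), duration = 1), "negative")
  expect_error(bin_spikes(list(u = c(0.2, 0.1)), duration = 1), "ascending")
  expect_error(bin_spikes(list(u = 2), duration = 1), "duration")
})

test_that("adaptive smoothing conserves each unit's total count exactly", {
  set.seed(11)
  sp <- list()
  for (i in 1:50) {
    n <- sample(5:200, 1)
    sp[[sprintf("u%02d", i)]] <- sort(runif(n, 0, 60))
  }
  counts <- bin_spikes(sp, 0.1, 60)
  sm <- smooth_adaptive(counts, sp)
  expect_equal(rowSums(sm), rowSums(counts), tolerance = 1e-12)
  expect_true(all(sm >= 0))
})

test_that("the smoothing kernel is the truncated renormalized Gaussian", {
  # single spike far from the edges: the smoothed train is the kernel itself
  st <- c(10, 14) # mean ISI 4 s -> SD = 1 s = 10 bins
  counts <- bin_spikes(list(u = st), 0.1, 30)
  sm <- smooth_adaptive(counts, list(u = st))
  h <- ceiling(4 * 10)
  K <- dnorm(-h:h, sd = 10); K <- K / sum(K)
  # spikes at 10 s and 14 s sit in bins 101 and 141 (1-based); the smoothed
  # train is the sum of the two per-source renormalized kernels
  contrib2 <- numeric(300)
  idx2 <- (141 - h):(141 + h); ok2 <- idx2 >= 1 & idx2 <= 300
  contrib2[idx2[ok2]] <- K[ok2] / sum(K[ok2])
  contrib1 <- numeric(300)
  idx1 <- (101 - h):(101 + h); ok1 <- idx1 >= 1 & idx1 <= 300
  contrib1[idx1[ok1]] <- K[ok1] / sum(K[ok1])
  expect_equal(as.numeric(sm[1, ]), contrib1 + contrib2, tolerance = 1e-12)
})

test_that("smoothing a constant train is identity away from the boundaries", {
  x <- rep(2, 400)
  sm <- gauss_smooth_conserve(x, sd_bins = 5)
  h <- ceiling(4 * 5)
  interior <- (2 * h + 1):(400 - 2 * h)
  expect_equal(sm[interior], x[interior], tolerance = 1e-9)
  expect_equal(sum(sm), sum(x), tolerance = 1e-9)
})

test_that("units with fewer than two spikes pass through unsmoothed", {
  sp <- list(u1 = 5, u2 = c(1, 2, 3))
  counts <- bin_spikes(sp, 0.1, 10)
  expect_warning(sm <- smooth_adaptive(counts, sp), "unsmoothed")
  expect_identical(attr(sm, "unsmoothed_units"), "u1")
  expect_equal(as.numeric(sm["u1", ]), as.numeric(counts["u1", ]))
})

test_that("event alignment windows match the published design", {
  w <- default_windows()
  expect_identical(w$cs_plus, c(-100L, 200L))
  expect_identical(w$cs, c(-100L, 200L))
  expect_identical(w$approach_init, c(-50L, 20L))
  expect_identical(w$drink, c(-100L, 100L))
  # bin counts: 301, 301, 71, 201
  expect_identical(vapply(w, function(x) x[2] - x[1] + 1L, integer(1)),
                   c(cs_plus = 301L, cs = 301L, approach_init = 71L,
                     drink = 201L))
})

test_that("aligned extraction slices the correct bins and drops edge events", {
  rates <- matrix(rep(1:100, each = 2), 2, 100,
                  dimnames = list(c("u1", "u2"), NULL))
  attr(rates, "bin_width") <- 0.1
  ev <- c(0.05, 5.0, 9.99) # bins 1, 51, 100 (1-based)
  al <- extract_aligned(rates, ev, "drink", window = c(-3L, 2L))
  expect_identical(attr(al, "kept"), 2L)
  expect_identical(attr(al, "dropped"), c(1L, 3L))
  expect_equal(as.numeric(al["u1", 1, ]), 48:53)
  expect_error(extract_aligned(rates, c(0.01), "drink", window = c(-3L, 2L)),
               "no event survives")
})

test_that("z-scoring standardizes per unit and flags constant units", {
  set.seed(5)
  x <- array(rnorm(4 * 6 * 10, mean = 3, sd = 2), c(4, 6, 10),
             dimnames = list(paste0("u", 1:4), NULL, NULL))
  x[3, , ] <- 7 # constant unit
  z <- zscore_aligned(x)
  for (i in c(1, 2, 4)) {
    v <- as.numeric(z[i, , ])
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  expect_true(all(z[3, , ] == 0))
  expect_identical(attr(z, "constant_units"), "u3")
})

test_that("trial-type averaging requires both cells and averages exactly", {
  x <- array(0, c(1, 4, 2))
  x[1, , 1] <- c(1, 2, 3, 4)
  x[1, , 2] <- c(10, 20, 30, 40)
  avg <- average_trial_types(x, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(avg$plus), c(2, 20))
  expect_equal(as.numeric(avg$minus), c(3, 30))
  expect_identical(avg$n_plus, 2L)
  expect_error(average_trial_types(x, rep(TRUE, 4)), "empty cell")
  expect_error(average_trial_types(x, rep(FALSE, 4)), "empty cell")
})

test_that("concatenated profiles have the published segment layout", {
  units <- c("u1", "u2")
  mk <- function(nb) matrix(rnorm(2 * nb), 2, nb,
                            dimnames = list(units, NULL))
  means <- list(a_plus = mk(301), a_minus = mk(301), b_plus = mk(301),
                b_minus = mk(301), c_plus = mk(71), c_minus = mk(71),
                d_plus = mk(201), d_minus = mk(201))
  p <- concatenate_profiles(means)
  expect_identical(ncol(p), 1748L)
  sm <- attr(p, "segment_map")
  expect_identical(sm$a_plus, 1:301)
  expect_identical(sm$a_minus, 302:602)
  expect_identical(sm$b_plus, 603:903)
  expect_identical(sm$b_minus, 904:1204)
  expect_identical(sm$c_plus, 1205:1275)
  expect_identical(sm$c_minus, 1276:1346)
  expect_identical(sm$d_plus, 1347:1547)
  expect_identical(sm$d_minus, 1548:1748)
  expect_equal(p[, sm$c_minus], means$c_minus, ignore_attr = TRUE)
  expect_identical(segment_bins(p, "c_minus"), 1276:1346)
  expect_error(concatenate_profiles(means[-1]), "missing segment")
  expect_error(segment_bins(p, "nope"), "unknown segment")
})
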