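test_that("each subsampled PCA is orthonormal and reconstructs its data", {
  X <- planted_profiles(n_units = 60L, n_bins = 80L, seed = 7L)
  des <- subsample_design(rep("g", 60), n_iterations = 5L,
                          n_per_group = 40L, seed = 7L)
  res <- run_subsampled_pca(X, des, n_pcs = 40L)
  for (k in 1:5) {
    V <- res$coef[[k]]
    expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    sel <- des$selections[[k]]
    Xc <- sweep(t(X[sel, ]), 2, res$centers[[k]])
    # with full rank retained, scores %*% t(V) reconstructs the centered data
    expect_equal(res$scores[, , k] %*% t(V), Xc, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # and scores are exactly the centered projection
    expect_equal(res$scores[, , k], Xc %*% V, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("sign alignment flips coefficients and scores together", {
  X <- planted_profiles(n_units = 80L, n_bins = 60L, seed = 9L)
  des <- subsample_design(rep("g", 80), n_iterations = 12L,
                          n_per_group = 50L, seed = 9L)
  res <- align_pc_signs(run_subsampled_pca(X, des, n_pcs = 6L))
  for (k in c(1L, 7L, 12L)) {
    sel <- des$selections[[k]]
    Xc <- sweep(t(X[sel, ]), 2, res$centers[[k]])
    expect_equal(res$scores[, , k], Xc %*% res$coef[[k]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # after alignment, every live iteration correlates positively with the mean
  for (j in 1:6) {
    tr <- res$scores[, j, ]
    m <- rowMeans(tr)
    live <- apply(tr, 2, sd) > 1e-12
    if (sd(m) > 1e-12 && any(live)) {
      expect_true(all(cor(tr[, live, drop = FALSE], m) >= 0))
    }
  }
})

test_that("stability separates shared signal from independent noise", {
  X <- planted_profiles(n_units = 100L, n_bins = 200L, n_sig = 2L,
                        snr = 4, seed = 13L)
  des <- subsample_design(rep("g", 100), n_iterations = 30L,
                          n_per_group = 60L, seed = 13L)
  res <- align_pc_signs(run_subsampled_pca(X, des, n_pcs = 6L))
  st <- pc_stability(res)
  expect_true(all(st$stable[1:2]))
  expect_true(all(!st$stable[4:6]))
  expect_true(min(st$variance_ratio[1:2]) > max(st$variance_ratio[4:6]))
})

test_that("degenerate identical iterations hit the stability sentinel", {
  # all units identical: centered subsample data are exactly zero, so
  # deviations about the mean trace vanish and the ratio is capped
  X <- matrix(rep(sin(seq_len(50) / 5), each = 30), 30, 50,
              dimnames = list(paste0("u", 1:30), NULL))
  des <- subsample_design(rep("g", 30), n_iterations = 4L,
                          n_per_group = 20L, seed = 2L)
  st <- pc_stability(run_subsampled_pca(X, des, n_pcs = 3L))
  expect_true(all(st$variance_ratio == 1e12))
  expect_true(all(st$stable))
})

test_that("group projection reduces to the scores for a single full group", {
  X <- planted_profiles(n_units = 40L, n_bins = 50L, seed = 3L)
  des <- subsample_design(rep("g", 40), n_iterations = 1L,
                          n_per_group = 40L, seed = 3L)
  res <- align_pc_signs(run_subsampled_pca(X, des, n_pcs = 4L))
  pr <- project_group(X, res, "g")
  expect_equal(pr, res$scores[, , 1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(colnames(pr), paste0("PC", 1:4))
  expect_error(project_group(X, res, "nope"), "unknown group")
})

test_that("trajectory separation is the per-bin Euclidean distance", {
  t1 <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  t2 <- matrix(0, 2, 2)
  expect_equal(pc_separation(t1, t2), c(0, 5))
  expect_error(pc_separation(t1, matrix(0, 3, 2)), "do not match")
})

test_that("default epochs index the published task periods", {
  ep <- default_epochs()
  expect_identical(names(ep),
                   c("seeking", "cs_onset", "cs_discrim", "approach", "drink"))
  expect_identical(ep$seeking$segments, c("a_plus", "a_minus"))
  expect_identical(ep$seeking$rel_bins, -25:-6)
  expect_identical(ep$cs_onset$segments, c("b_plus", "b_plus"))
  expect_identical(ep$cs_onset$rel_bins, 0:19)
  expect_identical(ep$cs_onset$rel_bins2, -24:-5)
  expect_identical(ep$cs_discrim$rel_bins, 20:39)
  expect_identical(ep$approach$segments, c("c_plus", "c_minus"))
  expect_identical(ep$approach$rel_bins, -30:-11)
  expect_identical(ep$drink$rel_bins, 0:19)
})

test_that("epoch separation picks the intended bins of the trajectory", {
  units <- c("u1", "u2")
  mk <- function(nb) matrix(0, 2, nb, dimnames = list(units, NULL))
  means <- list(a_plus = mk(20), a_minus = mk(20), b_plus = mk(20),
                b_minus = mk(20), c_plus = mk(10), c_minus = mk(10),
                d_plus = mk(10), d_minus = mk(10))
  p <- concatenate_profiles(means)
  sm <- attr(p, "segment_map")
  w <- tiny_windows()
  traj <- matrix(0, ncol(p), 2)
  # seeking epoch rel_bins -6:-1 in a 20-bin [-10, 9] window -> bins 5:10
  traj[sm$a_plus[5:10], 1] <- 3
  traj[sm$a_minus[5:10], 2] <- 4
  ep <- epoch_mean_separation(traj, sm, tiny_epochs()$seeking, windows = w)
  expect_equal(ep$values, rep(5, 6))
  expect_equal(ep$mean, 5)
  expect_identical(ep$n_bins, 6L)
  bad <- list(segments = c("a_plus", "a_minus"), rel_bins = -12:-1)
  expect_error(epoch_mean_separation(traj, sm, bad, windows = w),
               "outside")
})

test_that("subsample designs are reproducible and guard group sizes", {
  g <- rep(c("x", "y"), c(30, 25))
  d1 <- subsample_design(g, n_iterations = 6L, n_per_group = 20L, seed = 5L)
  d2 <- subsample_design(g, n_iterations = 6L, n_per_group = 20L, seed = 5L)
  expect_identical(d1$selections, d2$selections)
  expect_identical(length(d1$selections), 6L)
  expect_true(all(vapply(d1$selections, length, integer(1)) == 40L))
  for (sel in d1$selections) {
    expect_identical(sum(g[sel] == "x"), 20L)
    expect_identical(sum(g[sel] == "y"), 20L)
    expect_false(anyDuplicated(sel) > 0)
  }
  expect_error(subsample_design(g, n_per_group = 26L), "smaller than")
})
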