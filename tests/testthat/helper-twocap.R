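# Shared test helpers: an independently coded change-point oracle, planted
# profile builders, lean synthetic sessions, and fake session_data objects.

# Independent exhaustive single-split RSS minimizer (deliberately written
# with plain per-split sums, unlike the cumsum formulation in the package).
# Returns the first post-change index; earliest split wins ties.
oracle_change_point <- function(x, min_seg = 2L) {
  x <- as.numeric(x)
  n <- length(x)
  if (max(x) == min(x)) return(NA_integer_)
  ks <- (min_seg + 1L):(n - min_seg + 1L)
  rss <- vapply(ks, function(k) {
    pre <- x[seq_len(k - 1L)]
    post <- x[k:n]
    sum((pre - mean(pre))^2) + sum((post - mean(post))^2)
  }, numeric(1))
  tol <- 1e-9 * (1 + sum((x - mean(x))^2))
  ks[which(rss - min(rss) <= tol)[1]]
}

# Profiles with n_sig planted latent signals shared across units plus
# independent per-unit noise; SNR is the amplitude ratio signal sd / noise sd.
# Signal strengths are mildly graded (factors around 1) so the planted
# principal-component ranks are identifiable: exactly equal strengths make the
# planted eigenvalues degenerate, and degenerate PCs rotate freely between
# subsamples, leaving no well-defined "rank" to recover.
planted_profiles <- function(n_units = 120L, n_bins = 300L, n_sig = 3L,
                             snr = 4, seed = 1L) {
  with_seed(seed, {
    S <- matrix(rnorm(n_sig * n_bins), n_sig, n_bins)
    S <- S / apply(S, 1, sd)
    amp <- snr * seq(1.25, 0.8, length.out = n_sig)
    L <- matrix(rnorm(n_units * n_sig), n_units, n_sig)
    L <- L / sqrt(rowSums(L^2)) # unit loading norm: per-unit signal sd ~ 1
    X <- (L %*% (amp * S)) + matrix(rnorm(n_units * n_bins), n_units, n_bins)
    rownames(X) <- sprintf("u%03d", seq_len(n_units))
    X
  })
}

# A small complete synthetic session for end-to-end tests.
lean_session <- function(seed, gains = c(seek = 1, cue = 1, approach = 1,
                                         drink = 1),
                         n_neurons = 50L, group = "g", session_id = "s01",
                         animal = session_id, ...) {
  cfg <- sim_config(n_cs_plus = 32L, n_cs_minus = 32L,
                    iti_set = c(20, 28, 36), n_neurons = n_neurons,
                    baseline_rate = 3, loading_spread = 0.1,
                    signal_gains = setNames(list(gains), group),
                    seed = seed, ...)
  simulate_session(cfg, group = group, session_id = session_id,
                   animal = animal, seed = seed)
}

lean_pipeline_config <- function(seed, ...) {
  pipeline_config(n_iterations = 20L, n_per_group = 40L, n_pcs = 8L,
                  seed = seed, ...)
}

# Miniature alignment windows/epochs for fake-session tests (bins, 10 Hz).
tiny_windows <- function() {
  list(cs_plus = c(-10L, 9L), cs = c(-10L, 9L),
       approach_init = c(-5L, 4L), drink = c(-5L, 4L))
}

# covers every default epoch name (pipeline_config merges epochs recursively)
tiny_epochs <- function() {
  list(
    seeking = list(segments = c("a_plus", "a_minus"), rel_bins = -6:-1),
    cs_onset = list(segments = c("b_plus", "b_plus"),
                    rel_bins = 0:4, rel_bins2 = -5:-1),
    cs_discrim = list(segments = c("b_plus", "b_minus"), rel_bins = 5:9),
    approach = list(segments = c("c_plus", "c_minus"), rel_bins = -5:-1),
    drink = list(segments = c("d_plus", "d_minus"), rel_bins = 0:4)
  )
}

# Fake session_data objects: z-scored-looking tensors with an optional
# split-locked mean shift planted in the "a" alignment.
fake_session <- function(session_id, n_units = 60L, n_trials = 24L,
                         effect = 0, seed = 1L, group = "g",
                         animal = session_id) {
  with_seed(seed, {
    ids <- paste0(session_id, "_u", sprintf("%03d", seq_len(n_units)))
    mk <- function(nb) {
      array(rnorm(n_units * n_trials * nb), c(n_units, n_trials, nb),
            dimnames = list(ids, NULL, NULL))
    }
    splits <- list(a = rep(c(TRUE, FALSE), length.out = n_trials),
                   b = rep(c(TRUE, FALSE), length.out = n_trials),
                   c = rep(c(TRUE, FALSE), length.out = n_trials),
                   d = rep(c(TRUE, FALSE), length.out = n_trials))
    tensors <- list(a = mk(20L), b = mk(20L), c = mk(10L), d = mk(10L))
    if (effect != 0) {
      shift <- effect * matrix(rnorm(n_units), n_units, 20L) # unit pattern
      for (j in which(splits$a)) {
        tensors$a[, j, ] <- tensors$a[, j, ] + shift
      }
    }
    list(tensors = tensors, splits = splits,
         units = data.frame(unit_id = ids, group = group, animal = animal,
                            stringsAsFactors = FALSE),
         group = group, animal = animal, session_id = session_id)
  })
}
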