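# Subsampled PCA with stability selection, sign alignment, group
# projections, and PC-separation representation strength.

#' Subsampling design for group-matched PCA
#'
#' Each iteration draws `n_per_group` units without replacement from every
#' group, so no group dominates the decomposition while components remain
#' comparable across groups.
#'
#' @param groups character/factor vector, one group label per unit (in
#'   profile row order).
#' @param n_iterations number of subsample iterations (default 500).
#' @param n_per_group units drawn per group per iteration (default 200).
#' @param seed integer seed.
#' @return list of class `subsample_design` with `selections` (per iteration,
#'   integer unit indices, grouped), `groups`, `n_iterations`, `n_per_group`.
#' @export
subsample_design <- function(groups, n_iterations = 500L,
                             n_per_group = 200L, seed = 1L) {
  groups <- as.character(groups)
  tab <- table(groups)
  too_small <- tab < n_per_group
  if (any(too_small)) {
    stop("subsample_design: group(s) smaller than n_per_group = ",
         n_per_group, ": ",
         paste(sprintf("%s (%d)", names(tab)[too_small], tab[too_small]),
               collapse = ", "))
  }
  idx_by_group <- split(seq_along(groups), groups)
  selections <- with_seed(seed, {
    lapply(seq_len(n_iterations), function(k) {
      unlist(lapply(idx_by_group, sample, size = n_per_group), use.names = FALSE)
    })
  })
  structure(list(selections = selections, groups = groups,
                 n_iterations = as.integer(n_iterations),
                 n_per_group = as.integer(n_per_group), seed = seed),
            class = "subsample_design")
}

#' Subsampled principal component analysis of concatenated profiles
#'
#' Runs one PCA per subsample iteration on the bins x units matrix (time bins
#' are observations, neurons are variables; each unit centered over bins).
#' Components are ordered by explained variance within each iteration and
#' matched across iterations by rank.
#'
#' @param profiles units x bins matrix from [concatenate_profiles()].
#' @param design a [subsample_design()] over the profile rows.
#' @param n_pcs number of leading components to keep (default 10).
#' @return list of class `subsampled_pca` with `scores` (bins x n_pcs x
#'   iterations), `coef` (per iteration: selected-units x n_pcs rotation with
#'   rownames = unit indices), `centers` (per iteration), `evar`
#'   (iterations x n_pcs explained-variance fractions), and the design.
#' @export
run_subsampled_pca <- function(profiles, design, n_pcs = 10L) {
  stopifnot(inherits(design, "subsample_design"))
  nt <- ncol(profiles)
  K <- design$n_iterations
  n_pcs <- min(n_pcs, length(design$selections[[1]]), nt)
  scores <- array(NA_real_, c(nt, n_pcs, K))
  coef <- vector("list", K)
  centers <- vector("list", K)
  evar <- matrix(NA_real_, K, n_pcs)
  for (k in seq_len(K)) {
    sel <- design$selections[[k]]
    X <- t(profiles[sel, , drop = FALSE])
    pr <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
    scores[, , k] <- pr$x
    rot <- pr$rotation
    rownames(rot) <- as.character(sel)
    coef[[k]] <- rot
    centers[[k]] <- setNames(pr$center, as.character(sel))
    evar[k, ] <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(n_pcs)]
  }
  structure(list(scores = scores, coef = coef, centers = centers,
                 evar = evar, n_pcs = n_pcs, design = design),
            class = "subsampled_pca")
}

#' Align component signs across iterations
#'
#' PCA component signs are arbitrary; iterations whose score trace correlates
#' negatively with the cross-iteration mean trace are inverted (coefficients
#' and scores multiplied by -1), iterating until no flips occur (at most
#' `max_pass` passes). Zero-variance traces are excluded from the correlation
#' and left unflipped.
#'
#' @param result a [run_subsampled_pca()] result.
#' @param max_pass maximum alignment passes (default 10).
#' @return the result with aligned `scores`/`coef` and a `flips` attribute
#'   (total sign flips applied per PC).
#' @export
align_pc_signs <- function(result, max_pass = 10L) {
  K <- dim(result$scores)[3]
  if (K < 2L) return(result)
  n_flips <- integer(result$n_pcs)
  parity <- matrix(1, result$n_pcs, K) # net sign applied per (PC, iteration)
  for (j in seq_len(result$n_pcs)) {
    tr <- result$scores[, j, ] # bins x iterations
    live <- apply(tr, 2, sd) > 1e-12
    if (!any(live)) next
    for (pass in seq_len(max_pass)) {
      m <- rowMeans(tr)
      if (sd(m) < 1e-15) break
      cc <- rep(1, K)
      cc[live] <- as.numeric(cor(tr[, live, drop = FALSE], m))
      flip <- which(live & cc < 0)
      if (length(flip) == 0L) break
      tr[, flip] <- -tr[, flip]
      parity[j, flip] <- -parity[j, flip]
      n_flips[j] <- n_flips[j] + length(flip)
    }
    result$scores[, j, ] <- tr
  }
  for (k in seq_len(K)) { # keep coefficients consistent with scores
    result$coef[[k]] <- sweep(result$coef[[k]], 2, parity[, k], `*`)
  }
  attr(result, "flips") <- n_flips
  result
}

#' Stability of components across subsample iterations
#'
#' For each component rank, the variance over time of the iteration-mean
#' score trace is divided by the variance (over bins and iterations) of the
#' deviations from that mean. Components with ratio > 1 are flagged stable. A
#' zero deviation variance (identical traces) is reported as the capped
#' sentinel `1e12` and flagged stable.
#'
#' @param result an aligned [run_subsampled_pca()] result.
#' @return data.frame `pc`, `variance_ratio`, `stable`, `mean_evar`.
#' @export
pc_stability <- function(result) {
  ratios <- numeric(result$n_pcs)
  for (j in seq_len(result$n_pcs)) {
    tr <- result$scores[, j, ]
    m <- rowMeans(tr)
    num <- var(m)
    dev <- tr - m
    den <- var(as.vector(dev))
    ratios[j] <- if (den < 1e-300) 1e12 else min(num / den, 1e12)
  }
  data.frame(pc = seq_len(result$n_pcs), variance_ratio = ratios,
             stable = ratios > 1, mean_evar = colMeans(result$evar))
}

#' Project an experimental group onto the subsampled components
#'
#' For each iteration, the group trajectory is the projection of only that
#' group's selected units: `E_jk(t) = sum_{i in G} f_ijk * A_i(t)` with each
#' unit's profile centered by its over-bins mean (the center used by the
#' iteration's PCA). The returned trajectory is the mean over iterations.
#'
#' @param profiles units x bins matrix.
#' @param result aligned [run_subsampled_pca()] result.
#' @param group group label to project (must appear in the design).
#' @param pcs integer vector of component ranks to emit (default: all kept).
#' @return bins x length(pcs) matrix of iteration-mean projections, with the
#'   component ranks as column names.
#' @export
project_group <- function(profiles, result, group, pcs = NULL) {
  design <- result$design
  if (!group %in% design$groups) stop("project_group: unknown group '",
                                      group, "'")
  pcs <- pcs %||% seq_len(result$n_pcs)
  in_group <- which(design$groups == group)
  nt <- ncol(profiles)
  acc <- matrix(0, nt, length(pcs))
  K <- design$n_iterations
  for (k in seq_len(K)) {
    sel <- design$selections[[k]]
    sel_g <- sel[sel %in% in_group]
    rot <- result$coef[[k]][as.character(sel_g), pcs, drop = FALSE]
    ctr <- result$centers[[k]][as.character(sel_g)]
    Xg <- t(profiles[sel_g, , drop = FALSE]) # bins x units
    Xg <- sweep(Xg, 2, ctr)
    acc <- acc + Xg %*% rot
  }
  out <- acc / K
  colnames(out) <- paste0("PC", pcs)
  out
}

#' Euclidean separation between two trajectories across components
#'
#' Per matched time bin, the Euclidean distance across all supplied component
#' dimensions between the two trajectories: the operational measure of
#' representation strength.
#'
#' @param traj1,traj2 bins x PCs matrices over the same bins and components.
#' @return numeric vector of per-bin separations.
#' @export
pc_separation <- function(traj1, traj2) {
  if (!all(dim(traj1) == dim(traj2))) {
    stop("pc_separation: trajectory windows/PC sets do not match")
  }
  sqrt(rowSums((traj1 - traj2)^2))
}

#' Default analysis epochs
#'
#' Each epoch names the two trajectory slices it compares and the relative
#' 100-ms bins (bin 0 starts at the alignment event) it spans; every default
#' epoch is 20 bins (2 s) long. `seeking` compares pre/post change-point CS+
#' segments at -2.5..-0.6 s before CS+ onset (before the CS but clear of the
#' preceding trial); `cs_onset` compares, within the CS+ segment, the pre-CS
#' window (-2.4..-0.5 s) to the post-onset window (0..1.9 s), bin by bin;
#' `cs_discrim` compares CS+ and CS- at 2.0..3.9 s of the cue (after the
#' shared onset transient); `approach` compares approach/no-approach at
#' -3.0..-1.1 s before initiation; `drink` compares drink/no-drink at
#' 0..1.9 s after the drink time.
#' @return named list of epoch definitions.
#' @export
default_epochs <- function() {
  list(
    seeking = list(segments = c("a_plus", "a_minus"), rel_bins = -25:-6),
    cs_onset = list(segments = c("b_plus", "b_plus"),
                    rel_bins = 0:19, rel_bins2 = -24:-5),
    cs_discrim = list(segments = c("b_plus", "b_minus"), rel_bins = 20:39),
    approach = list(segments = c("c_plus", "c_minus"), rel_bins = -30:-11),
    drink = list(segments = c("d_plus", "d_minus"), rel_bins = 0:19)
  )
}

# map relative bins of a segment to concatenated-profile column indices
segment_rel_index <- function(seg_map, segment, rel_bins, windows) {
  align <- switch(substr(segment, 1, 1), a = "cs_plus", b = "cs",
                  c = "approach_init", d = "drink")
  win <- windows[[align]]
  if (any(rel_bins < win[1] | rel_bins > win[2])) {
    stop("epoch bins outside the ", segment, " window [",
         win[1], ", ", win[2], "]")
  }
  seg_map[[segment]][rel_bins - win[1] + 1L]
}

#' Per-bin epoch separation and its summary
#'
#' Slices a group trajectory at an epoch's two windows and returns the
#' per-bin Euclidean separations across the supplied components together with
#' their mean.
#'
#' @param trajectory bins x PCs matrix over the concatenated profile domain.
#' @param seg_map segment map of the profiles ([segment_bins()] source).
#' @param epoch one epoch definition from [default_epochs()].
#' @param windows alignment windows (default [default_windows()]).
#' @return list with `values` (per-bin separations), `mean`, `n_bins`.
#' @export
epoch_mean_separation <- function(trajectory, seg_map, epoch,
                                  windows = default_windows()) {
  idx1 <- segment_rel_index(seg_map, epoch$segments[1], epoch$rel_bins,
                            windows)
  rel2 <- epoch$rel_bins2 %||% epoch$rel_bins
  idx2 <- segment_rel_index(seg_map, epoch$segments[2], rel2, windows)
  vals <- pc_separation(trajectory[idx1, , drop = FALSE],
                        trajectory[idx2, , drop = FALSE])
  list(values = vals, mean = mean(vals), n_bins = length(vals))
}

#' Firing-rate change at the session change point against a jittered null
#'
#' The observed statistic is the absolute change in the per-trial rate
#' between the two trials adjacent to the session change point; the null
#' re-centers the change point at a uniform jitter of up to `jitter_max`
#' trials in either direction (excluding zero).
#'
#' @param trial_rates numeric vector of per-trial mean rates (CS+ trials in
#'   time order).
#' @param j_scp session change-point trial (first post-change trial).
#' @param jitter_max maximum jitter in trials (default 2).
#' @param n_random number of null draws (default 1000).
#' @param seed integer seed.
#' @return list with `observed` and `null` (numeric vector).
#' @export
rate_change_at_changepoint <- function(trial_rates, j_scp, jitter_max = 2L,
                                       n_random = 1000L, seed = 1L) {
  n <- length(trial_rates)
  if (j_scp - jitter_max < 2L || j_scp + jitter_max > n) {
    stop("rate_change_at_changepoint: j_scp = ", j_scp, " is within ",
         jitter_max, " trials of the session edge")
  }
  observed <- abs(trial_rates[j_scp] - trial_rates[j_scp - 1L])
  u_set <- setdiff(seq.int(-jitter_max, jitter_max), 0L)
  null <- with_seed(seed, {
    u <- sample(u_set, n_random, replace = TRUE)
    abs(trial_rates[j_scp + u] - trial_rates[j_scp + u - 1L])
  })
  list(observed = observed, null = null)
}
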