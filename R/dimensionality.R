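#' Participation ratio of a variance spectrum
#'
#' `d = 1 / sum(lambda^2)` over principal-component variances normalized
#' to sum to one.  One dominant component gives `d = 1`; `k` equal
#' components give `d = k`.
#'
#' @param lambda non-negative variances.  Must sum to 1 up to `1e-8`
#'   (renormalized internally) unless `normalize = TRUE`, in which case any
#'   positive spectrum is accepted and normalized.
#' @param normalize accept an unnormalized spectrum.
#' @return The participation ratio.
#' @export
#' @examples
#' participation_ratio(c(1, 0))            # 1
#' participation_ratio(rep(1 / 4, 4))      # 4
#' participation_ratio(c(2 / 3, 1 / 3))    # 1.8
participation_ratio <- function(lambda, normalize = FALSE) {
  if (any(lambda < 0)) stop("variances must be non-negative")
  s <- sum(lambda)
  if (s == 0) stop("all-zero variance spectrum")
  if (!normalize && abs(s - 1) > 1e-8)
    stop("`lambda` must be normalized to sum to 1 (or use normalize = TRUE)")
  lambda <- lambda / s
  1 / sum(lambda^2)
}

#' Per-neuron spike-error vectors of a set of rasters
#'
#' For each raster, `DeltaS_i = sum_t |ref[i, t] - s[i, t]|`: the
#' coordinates of that network history in the error space used by the
#' dimensionality analyses.
#'
#' @param rasters list of rasters (matrices or [spike_raster()]).
#' @param reference reference raster (the internal target, or the final
#'   dynamics of a training run).
#' @return An n-by-N matrix, one row per raster.
#' @export
delta_s_matrix <- function(rasters, reference) {
  ref <- raster_matrix(reference)
  t(vapply(rasters, function(r) rowSums(abs(raster_matrix(r) - ref)),
           numeric(nrow(ref))))
}

#' Effective dimensionality of a point cloud
#'
#' Centers the rows, extracts principal-component variances (via singular
#' values), discards numerically zero components (normalized variance
#' below `tol`), and returns the participation ratio.  A cloud with total
#' variance below `var_floor` is reported as 0-dimensional.
#'
#' @param X n-by-p matrix (rows = points).
#' @param tol normalized-variance cutoff for retaining a component.
#' @param var_floor total-variance floor below which the cloud is
#'   degenerate.
#' @return The participation ratio (0 for a degenerate cloud).
#' @export
cloud_dimensionality <- function(X, tol = 1e-12, var_floor = 1e-9) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  if (n < 2) stop("need at least two points")
  sv <- svd(Xc, nu = 0, nv = 0)$d
  vars <- sv^2 / (n - 1)
  total <- sum(vars)
  if (total < var_floor) return(0)
  lambda <- vars / total
  lambda <- lambda[lambda > tol]
  participation_ratio(lambda, normalize = TRUE)
}

#' Dimensionality of the convergence cloud across training replicas
#'
#' Trains `n_replicas` networks per feedback rank from independent weight
#' initializations on the same store-and-recall episode, collects the
#' final per-neuron spike-error vectors against the internal target, and
#' returns the participation ratio of each rank's replica cloud.  At full
#' rank every replica is pulled to the same internal solution and the
#' cloud collapses; lowering the rank frees a kernel of dimension `N - R`
#' along which replicas spread.
#'
#' Replicas that fail to converge are flagged and excluded (with a
#' message); the per-rank counts are returned.  Convergence means halving
#' the *attainable* part of the initial output error of the experiment:
#' the readout-limit residual is an unbeatable floor and the cohort median
#' of the replicas' untrained MSE is the common starting level, so a
#' replica converges when its final MSE falls below
#' `floor + (median initial - floor) / 2`.  (Judging each replica against
#' its own initial error would tie exclusion to the luck of the weight
#' draw rather than to the quality of the solution reached.)
#'
#' @param spec a [store_recall_spec()].
#' @param params a [network_params()].
#' @param ranks integer vector of feedback ranks to probe.
#' @param n_replicas replicas per rank (>= 3).
#' @param config a [learning_config()] (the training budget).
#' @param seed master seed; replica `r` of rank `R` trains from weights
#'   seeded by [derive_seed()].
#' @param feedback_mode feedback construction (diagonal by default, as in
#'   the rank sweep analyses).
#' @param sigma_w scale of the initial recurrent weights, the quantity the
#'   replicas differ in.
#' @return A data frame with columns `rank`, `dimensionality`,
#'   `n_converged`, `n_excluded`.
#' @export
replica_dimensionality <- function(spec, params, ranks, n_replicas = 5,
                                   config = learning_config(),
                                   seed = 1,
                                   feedback_mode = "diagonal",
                                   sigma_w = 30) {
  stopifnot(n_replicas >= 3)
  out <- data.frame(rank = integer(0), dimensionality = numeric(0),
                    n_converged = integer(0), n_excluded = integer(0))
  for (R in ranks) {
    runs <- lapply(seq_len(n_replicas), function(r) {
      run_store_recall(spec, params, R, config,
                       feedback_mode = feedback_mode,
                       seed = seed,
                       replica_seed = derive_seed(seed, 100 * R + r),
                       sigma_w = sigma_w)
    })
    s_star <- runs[[1]]$s_star
    E <- length(runs[[1]]$log$mse)
    mse0 <- stats::median(vapply(runs, function(x) x$log$mse[1], numeric(1)))
    floor_mse <- min(runs[[1]]$readout$residual, mse0)
    gate <- floor_mse + (mse0 - floor_mse) / 2
    conv <- vapply(runs, function(x) x$log$mse[E] <= gate, logical(1))
    clouds <- lapply(runs[conv], function(x) x$log$raster$spikes)
    excluded <- sum(!conv)
    if (excluded > 0)
      message(sprintf("rank %d: excluded %d non-converged replica(s)",
                      R, excluded))
    d <- if (length(clouds) >= 2)
      cloud_dimensionality(delta_s_matrix(clouds, s_star))
    else NA_real_
    out <- rbind(out, data.frame(rank = R, dimensionality = d,
                                 n_converged = length(clouds),
                                 n_excluded = excluded))
  }
  out
}

#' Single-trial dimensionality across a rank grid
#'
#' For each feedback rank, trains *one* store-and-recall network with
#' white synaptic noise on the weight updates, records the per-epoch
#' rasters, and estimates the dimensionality of the post-burn-in
#' fluctuation cloud with [single_trial_dimensionality()].
#'
#' @inheritParams replica_dimensionality
#' @param epsilon synaptic noise amplitude.
#' @param burn_in fraction of initial epochs discarded as
#'   learning-dominated.
#' @return A data frame with columns `rank`, `dimensionality`.
#' @export
single_trial_rank_sweep <- function(spec, params, ranks,
                                    config = learning_config(),
                                    epsilon = 0.1, burn_in = 0.5,
                                    seed = 1,
                                    feedback_mode = "diagonal",
                                    sigma_w = 30) {
  config$epsilon <- epsilon
  d <- vapply(ranks, function(R) {
    run <- run_store_recall(spec, params, R, config,
                            feedback_mode = feedback_mode,
                            seed = seed,
                            replica_seed = derive_seed(seed, 17 * R + 5),
                            sigma_w = sigma_w,
                            record_rasters = TRUE)
    single_trial_dimensionality(run$log, burn_in = burn_in)
  }, numeric(1))
  data.frame(rank = ranks, dimensionality = d)
}

#' Single-trial dimensionality from synaptic-noise fluctuations
#'
#' Estimates the dimensionality of the solution space from one training
#' run with white synaptic noise (see [noisy_train_step()]): after the
#' learning-dominated burn-in, the noise makes the network wander among
#' solutions, and the per-neuron spike-error vectors relative to the
#' *final* dynamics trace out the accessible subspace.  This is the probe
#' applicable when the internal target is unknown, as in experimental
#' recordings.
#'
#' @param log a [train_network()] `"training_log"` recorded with
#'   `record_rasters = TRUE` (and `config$epsilon > 0`).
#' @param burn_in fraction of initial epochs discarded as
#'   learning-dominated.
#' @return The participation ratio of the post-burn-in cloud.
#' @export
single_trial_dimensionality <- function(log, burn_in = 0.5) {
  if (is.null(log$rasters))
    stop("the training log has no raster snapshots; train with ",
         "`record_rasters = TRUE`")
  E <- length(log$rasters)
  keep <- seq.int(floor(burn_in * E) + 1, E)
  if (length(keep) < 10)
    stop("fewer than 10 post-burn-in snapshots; lower `burn_in` or train ",
         "for more epochs")
  reference <- log$rasters[[E]]
  cloud_dimensionality(delta_s_matrix(log$rasters[keep], reference))
}
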