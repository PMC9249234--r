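#' Generate an internal spike target from a desired output
#'
#' The internal target raster `s_star` is the activity expressed by the
#' *untrained* network (recurrent weights all zero) when the desired output
#' trajectory is randomly projected into it alongside the task input: the
#' total external current is `task_input + G y_star`, with `G` an N-by-O
#' Gaussian projection with zero mean and scale `sigma_proj`.
#'
#' By default `sigma_proj` is scaled so that the projected output drive has
#' a standard deviation across neurons of about the rest-to-threshold gap
#' `|v_rest|`, which yields a non-degenerate target firing pattern.
#'
#' @param y_star O-by-T desired output trajectory.
#' @param task_input N-by-T matrix of task currents (e.g. the clock input),
#'   or `NULL` for none.
#' @param params a [network_params()] object.
#' The projected drive is faded in over the first `ramp` steps (a linear
#' ramp from 0 to 1).  At the very start of an episode the network's
#' synaptic traces are empty, so recurrent connections cannot reproduce
#' any drive there: without the fade-in the first target spikes would be
#' unreachable for the trained network by construction.
#'
#' @param sigma_proj scale of the Gaussian projection entries; `NULL` for
#'   the automatic scaling described above.
#' @param seed integer seed for the projection.
#' @param ramp number of initial steps over which the projected drive is
#'   faded in (0 disables).
#' @return A list with the target [spike_raster()] `raster`, the projection
#'   matrix `G` and the `sigma_proj` used.
#' @export
generate_target_spikes <- function(y_star, task_input, params,
                                   sigma_proj = NULL, seed = 1,
                                   ramp = 3 * params$tau_m) {
  y_star <- as.matrix(y_star)
  if (any(!is.finite(y_star))) stop("`y_star` must be finite")
  N <- params$N
  O <- nrow(y_star)
  T_steps <- ncol(y_star)
  if (is.null(task_input)) task_input <- matrix(0, N, T_steps)
  if (nrow(task_input) != N || ncol(task_input) != T_steps)
    stop("`task_input` must be N-by-T, matching `y_star` columns")
  if (is.null(sigma_proj)) {
    # per-neuron drive (G y)_i has sd sigma_proj * ||y_t||; match |v_rest|
    # on the rms column norm of the target
    rms <- sqrt(mean(colSums(y_star^2)))
    sigma_proj <- if (rms > 0) abs(params$v_rest) / rms else 1
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  G <- matrix(stats::rnorm(N * O, sd = sigma_proj), N, O)
  proj <- G %*% y_star
  if (ramp > 0) {
    n_ramp <- min(ceiling(ramp / params$dt), T_steps)
    fade <- c(seq_len(n_ramp) / n_ramp, rep(1, T_steps - n_ramp))
    proj <- sweep(proj, 2, fade, "*")
  }
  sim <- simulate_network(matrix(0, N, N), task_input + proj,
                          params, record = "v")
  if (sum(sim$raster$spikes) == 0)
    warning("target raster is silent; consider a larger `sigma_proj`")
  list(raster = sim$raster, G = G, sigma_proj = sigma_proj)
}

#' Pre-train the linear readout on the internal target
#'
#' Fits the O-by-N readout matrix `B` that decodes the filtered internal
#' target into the desired output, `y = B s_bar_star`, by adaptive
#' (Adam) gradient descent on the summed squared error.  The achieved
#' residual is the *readout limit*: the lowest output error attainable by
#' the trained network given this frozen readout.
#'
#' @param s_bar_star N-by-T filtered internal target (e.g.
#'   `filter_spikes(s_star, tau)`).
#' @param y_star O-by-T desired output.
#' @param lr Adam learning rate.
#' @param epochs number of gradient steps.
#' @param B0 optional initial matrix (defaults to zero).
#' @return An object of class `"readout_matrix"`: list with `B` (O-by-N),
#'   `residual` (mean squared error of the fit), `residual_path` (per-step
#'   best-so-far MSE) and `tau` (set by the caller downstream; `NA` here).
#' @export
train_readout <- function(s_bar_star, y_star, lr = 1e-2, epochs = 2000,
                          B0 = NULL) {
  X <- as.matrix(s_bar_star)
  Y <- as.matrix(y_star)
  if (ncol(X) != ncol(Y)) stop("`s_bar_star` and `y_star` must share T")
  if (sum(X != 0) == 0 && sum(Y != 0) != 0)
    stop("empty internal target: cannot fit a readout")
  N <- nrow(X); O <- nrow(Y); Tn <- ncol(X)
  B <- if (is.null(B0)) matrix(0, O, N) else as.matrix(B0)
  opt <- adam_init(dim(B), lr = lr)
  mse <- function(B) mean((Y - B %*% X)^2)
  best <- B; best_mse <- mse(B)
  path <- numeric(epochs)
  for (it in seq_len(epochs)) {
    G <- -2 * ((Y - B %*% X) %*% t(X)) / Tn
    upd <- adam_step(opt, G)
    opt <- upd$opt
    B <- B - upd$delta
    m <- mse(B)
    if (m < best_mse) { best_mse <- m; best <- B }
    path[it] <- best_mse
  }
  tail_n <- max(1L, floor(epochs * 0.1))
  if (epochs > 20 && path[epochs - tail_n] - path[epochs] <= 0) {
    # stalling is only a problem when the fit sits meaningfully above the
    # least-squares optimum (a stall at the floor is convergence)
    ridge <- 1e-8 * max(diag(X %*% t(X)), 1)
    B_ls <- Y %*% t(X) %*% solve(X %*% t(X) + ridge * diag(N))
    floor_mse <- mean((Y - B_ls %*% X)^2)
    if (best_mse > 1.05 * floor_mse + 1e-12)
      warning("readout fit may not have converged: no improvement over ",
              "the last 10% of epochs")
  }
  structure(list(B = best, residual = best_mse, residual_path = path,
                 tau = NA_real_),
            class = "readout_matrix")
}

#' @export
print.readout_matrix <- function(x, ...) {
  cat(sprintf("readout_matrix: %d outputs x %d neurons, residual MSE %.4g\n",
              nrow(x$B), ncol(x$B), x$residual))
  invisible(x)
}

#' Expand a readout matrix with random hint rows
#'
#' Appends `R - O` extra rows to the O-by-N readout, drawn i.i.d. Gaussian
#' with zero mean and scale equal to twice the standard deviation of the
#' entries of `B`.  The extra rows define the hint constraints: random
#' linear combinations of the internal target that are imposed on the
#' network in addition to its behavioral output.
#'
#' @param B a [train_readout()] result or a plain O-by-N matrix.
#' @param R total number of rows after expansion, `O <= R <= N`.
#' @param seed integer seed for the extra rows.
#' @param scale scale (standard deviation) of the extra-row entries;
#'   defaults to `2 * sd(B)`.
#' @return An object of class `"expanded_readout"`: list with `B_plus`
#'   (R-by-N), `O`, `R`.
#' @export
expand_readout <- function(B, R, seed = 1, scale = NULL) {
  Bm <- if (inherits(B, "readout_matrix")) B$B else as.matrix(B)
  O <- nrow(Bm); N <- ncol(Bm)
  if (R < O) stop("`R` must be >= O (the number of behavior rows)")
  if (R > N) stop("`R` must be <= N")
  if (is.null(scale)) scale <- 2 * stats::sd(as.numeric(Bm))
  extra <- NULL
  if (R > O) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    extra <- matrix(stats::rnorm((R - O) * N, sd = scale), R - O, N)
  }
  structure(list(B_plus = rbind(Bm, extra), O = O, R = as.integer(R)),
            class = "expanded_readout")
}

#' Build the feedback matrix D
#'
#' Constructs the N-by-N matrix that propagates errors (or targets) back
#' into the network.  Its rank `R` is the number of independent constraints
#' imposed on the internal dynamics; the solutions compatible with a
#' converged network span the kernel of `D`, of dimension `N - R`.
#'
#' Modes:
#' \describe{
#'   \item{`"diagonal"`}{ones at the first `R` diagonal entries, zeros
#'     elsewhere (the Kronecker-delta construction; with `R = N` this is
#'     the identity and the rule reduces to learning through target
#'     spikes).}
#'   \item{`"random_gaussian"`}{`D = M^T M` with `M` an R-by-N standard
#'     Gaussian matrix.}
#'   \item{`"from_readout"`}{`D = B_plus^T B_plus` from an
#'     [expand_readout()] object.}
#' }
#'
#' @param mode one of `"diagonal"`, `"random_gaussian"`, `"from_readout"`.
#' @param R target rank, `1 <= R <= N`.
#' @param N number of neurons.
#' @param B_plus an [expand_readout()] object (required for
#'   `"from_readout"`).
#' @param seed seed for `"random_gaussian"`.
#' @param diag_scale optional scaling of the diagonal construction
#'   (e.g. `1/R`); default 1.
#' @return An object of class `"feedback_spec"`: list with `D` (N-by-N),
#'   `R`, `mode`, and `B_plus` (possibly `NULL`).
#' @export
build_feedback <- function(mode = c("diagonal", "random_gaussian",
                                    "from_readout"),
                           R, N, B_plus = NULL, seed = 1, diag_scale = 1) {
  mode <- match.arg(mode)
  if (mode != "from_readout") {
    stopifnot(R >= 1, R <= N)
  }
  D <- switch(mode,
    diagonal = {
      D <- matrix(0, N, N)
      diag(D)[seq_len(R)] <- diag_scale
      D
    },
    random_gaussian = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      M <- matrix(stats::rnorm(R * N), R, N)
      crossprod(M)
    },
    from_readout = {
      if (is.null(B_plus))
        stop("`from_readout` mode requires a `B_plus` expanded readout")
      R <- B_plus$R
      N <- ncol(B_plus$B_plus)
      crossprod(B_plus$B_plus)
    }
  )
  structure(list(D = D, R = as.integer(R), mode = mode, B_plus = B_plus),
            class = "feedback_spec")
}

#' @export
print.feedback_spec <- function(x, ...) {
  cat(sprintf("feedback_spec: %s, N = %d, rank R = %d (kernel dim %d)\n",
              x$mode, nrow(x$D), x$R, nrow(x$D) - x$R))
  invisible(x)
}

#' Assemble the generalized target bundle
#'
#' Collects the behavioral target `y_star`, the internal spike target and
#' its filtered version, and the generalized target `Y_star` whose first
#' `O` rows are `y_star` and whose remaining rows are the hint constraints
#' `B_plus[extra, ] %*% s_bar_star`.
#'
#' @param B_plus an [expand_readout()] object.
#' @param s_star internal target raster ([spike_raster()] or N-by-T matrix).
#' @param y_star O-by-T behavioral target.
#' @param tau_star spike-timing tolerance used to filter `s_star` (ms).
#' @param dt integration step (ms).
#' @return An object of class `"target_bundle"`: list with `y_star`,
#'   `s_star` (matrix), `s_bar_star`, `Y_star`, `tau_star`.
#' @export
make_generalized_target <- function(B_plus, s_star, y_star, tau_star,
                                    dt = 1) {
  S <- raster_matrix(s_star)
  y_star <- as.matrix(y_star)
  O <- B_plus$O; R <- B_plus$R
  if (nrow(y_star) != O) stop("`y_star` rows must equal B_plus$O")
  if (ncol(S) != ncol(y_star)) stop("targets must share T")
  s_bar_star <- filter_spikes(S, tau_star, dt)
  Y <- matrix(0, R, ncol(S))
  Y[seq_len(O), ] <- y_star
  if (R > O)
    Y[(O + 1):R, ] <- B_plus$B_plus[(O + 1):R, , drop = FALSE] %*% s_bar_star
  structure(list(y_star = y_star, s_star = S, s_bar_star = s_bar_star,
                 Y_star = Y, tau_star = tau_star, dt = dt),
            class = "target_bundle")
}
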