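#' Button-and-food environment state
#'
#' The agent starts at the center of a planar arena.  A button sits at
#' polar position `(r = 0.2, theta = -90)` degrees; the food at
#' `(r = 0.7, theta_food)` with `theta_food` in `[30, 150]` degrees.  The
#' food is locked until the agent has come within `contact_radius` of the
#' button; the button indicator latches on and never resets within an
#' episode.  The indicator is *not* part of the network's input.
#'
#' @param theta_food food angle in degrees.
#' @param r_food,r_btn,theta_btn arena geometry (degrees for angles).
#' @param contact_radius button contact radius.
#' @return An object of class `"button_food_state"`.
#' @export
button_food_state <- function(theta_food, r_food = 0.7,
                              r_btn = 0.2, theta_btn = -90,
                              contact_radius = 0.05) {
  stopifnot(theta_food >= 30, theta_food <= 150)
  polar <- function(r, th) r * c(cos(th * pi / 180), sin(th * pi / 180))
  structure(list(agent = c(0, 0),
                 button = polar(r_btn, theta_btn),
                 food = polar(r_food, theta_food),
                 theta_food = theta_food,
                 pressed = 0, t = 0L,
                 contact_radius = contact_radius),
            class = "button_food_state")
}

#' Encode an environment state as tuning-curve activations
#'
#' The four scalars fed to the network are the horizontal and vertical
#' offsets of the button and of the food relative to the agent
#' (`dxb, dyb, dxf, dyf`).  Each scalar drives a bank of
#' `n_units` Gaussian tuning curves with centers evenly spaced on
#' `[-1, 1]` and width equal to the center spacing (peak activation 1); the
#' four banks are concatenated.
#'
#' @param state a [button_food_state()].
#' @param n_units units per scalar.
#' @param extent half-width of the covered range.
#' @return A numeric vector of length `4 * n_units`.
#' @export
encode_state <- function(state, n_units = 20, extent = 1) {
  deltas <- c(state$button - state$agent, state$food - state$agent)
  centers <- seq(-extent, extent, length.out = n_units)
  width <- centers[2] - centers[1]
  out <- lapply(deltas, function(d) exp(-(d - centers)^2 / (2 * width^2)))
  unlist(out, use.names = FALSE)
}

#' Expert demonstration for button-and-food
#'
#' The expert walks at constant speed in a straight line from the center
#' to the button, then from the button to the food, the time devoted to
#' each segment proportional to its length.  Actions are the per-step
#' velocities; states are the tuning-curve encodings seen before each
#' action.
#'
#' @param theta_food food angle (degrees, in `[30, 150]`).
#' @param T_steps episode length.
#' @param n_units tuning-curve units per scalar.
#' @return An object of class `"expert_demo"`: list with `states`
#'   (`4 n_units`-by-T), `actions` (2-by-T per-step velocities),
#'   `positions` (2-by-(T+1)), `pressed` (length T indicator after each
#'   action), `switch_step` and `theta_food`.
#' @export
expert_trajectory <- function(theta_food, T_steps = 80, n_units = 20) {
  st <- button_food_state(theta_food)
  L1 <- sqrt(sum(st$button^2))
  L2 <- sqrt(sum((st$food - st$button)^2))
  n1 <- max(1L, min(T_steps - 1L, round(T_steps * L1 / (L1 + L2))))
  n2 <- T_steps - n1
  seg1 <- outer(st$button, seq_len(n1) / n1)                 # 2 x n1
  seg2 <- st$button + outer(st$food - st$button, seq_len(n2) / n2)
  positions <- cbind(c(0, 0), seg1, seg2)                    # 2 x (T+1)
  actions <- positions[, -1, drop = FALSE] -
    positions[, -ncol(positions), drop = FALSE]
  states <- matrix(0, 4 * n_units, T_steps)
  s <- st
  pressed <- numeric(T_steps)
  for (t in seq_len(T_steps)) {
    states[, t] <- encode_state(s, n_units)
    s <- env_step(s, actions[, t])
    pressed[t] <- s$pressed
  }
  structure(list(states = states, actions = actions, positions = positions,
                 pressed = pressed, switch_step = n1,
                 theta_food = theta_food, n_units = n_units),
            class = "expert_demo")
}

#' One environment step
#'
#' Integrates the agent position with the commanded velocity and latches
#' the button indicator once the agent is within the contact radius of the
#' button.
#'
#' @param state a [button_food_state()].
#' @param action length-2 velocity `(vx, vy)`.
#' @param dt_env integration step of the environment.
#' @return The next `"button_food_state"`.
#' @export
env_step <- function(state, action, dt_env = 1) {
  state$agent <- state$agent + action * dt_env
  if (sqrt(sum((state$agent - state$button)^2)) <= state$contact_radius)
    state$pressed <- 1
  state$t <- state$t + 1L
  state
}

#' Final reward of an episode
#'
#' `r = pressed * g(d)` with `d` the final agent-food distance and
#' `g(d) = exp(-d / length_scale)`, a decreasing function normalized to
#' `[0, 1]` with `g(0) = 1`.  Episodes in which the button was never
#' pressed score 0 regardless of the final position.
#'
#' @param final_state the last [button_food_state()] of the episode.
#' @param length_scale decay length of the distance term.
#' @return A number in `[0, 1]`.
#' @export
episode_reward <- function(final_state, length_scale = 0.2) {
  d <- sqrt(sum((final_state$agent - final_state$food)^2))
  final_state$pressed * exp(-d / length_scale)
}

#' Closed-loop rollout of a spiking agent
#'
#' Couples the environment and the network: at every step the current
#' state is encoded, projected into the network, the network advances one
#' step, the readout of the filtered spikes is taken as the velocity
#' command, and the environment integrates it.
#'
#' @param agent a trained agent as returned by
#'   [train_behavioral_cloning()]: list with `w`, `readout`, `J_in`,
#'   `params`, `n_units`.
#' @param theta_food food angle for this episode (degrees).
#' @param T_steps episode length.
#' @return A list with `reward`, `final_state`, `positions`
#'   (2-by-(T+1)), `actions` (2-by-T) and the episode's [spike_raster()].
#' @export
run_closed_loop <- function(agent, theta_food, T_steps = 80) {
  params <- agent$params
  N <- params$N
  bm <- exp(-params$dt / params$tau_m)
  bs <- exp(-params$dt / params$tau_s)
  bro <- if (agent$readout$tau == 0) 0 else
    exp(-params$dt / agent$readout$tau)
  env <- button_food_state(theta_food)
  v <- rep(params$v_rest, N)
  s_hat <- s_bar_ro <- numeric(N)
  S <- matrix(0, N, T_steps)
  positions <- matrix(0, 2, T_steps + 1)
  actions <- matrix(0, 2, T_steps)
  for (t in seq_len(T_steps)) {
    I_t <- as.numeric(agent$J_in %*% encode_state(env, agent$n_units))
    s_new <- as.numeric(v - params$v_th > 0)
    drive <- as.numeric(agent$w %*% s_hat) + I_t + params$v_rest
    v <- bm * v + (1 - bm) * drive + params$w_res * s_new
    s_hat <- bs * s_hat + (1 - bs) * s_new
    s_bar_ro <- bro * s_bar_ro + (1 - bro) * s_new
    S[, t] <- s_new
    a <- as.numeric(agent$readout$B %*% s_bar_ro)
    env <- env_step(env, a)
    actions[, t] <- a
    positions[, t + 1] <- env$agent
  }
  list(reward = episode_reward(env), final_state = env,
       positions = positions, actions = actions,
       raster = spike_raster(S, params$dt))
}

#' Behavioral cloning of expert demonstrations
#'
#' Trains a recurrent spiking network to imitate a set of state-action
#' demonstrations.  For each demonstration the encoded states are
#' projected into the network by a fixed Gaussian input matrix; the
#' internal spike target is the response of the untrained network to the
#' states plus a random projection of the expert actions; the readout is
#' pre-trained on the pooled internal targets and then refined
#' concurrently during recurrent training (Adam, `config$eta_ro`).
#' Recurrent updates use the target-propagating rule through the feedback
#' matrix `D` (diagonal construction by default, as in the rank sweep of
#' the navigation task).
#'
#' @param demos list of [expert_trajectory()] demonstrations (or any
#'   objects with `states` I-by-T and `actions` O-by-T).
#' @param params a [network_params()].
#' @param R feedback rank.
#' @param config a [learning_config()]; `optimizer = "adam"` with
#'   `eta = eta_ro = 0.01` mirrors the navigation-task setting.
#' @param feedback_mode `"diagonal"` (default) or `"from_readout"`.
#' @param seed master seed (input projection, target projection, readout
#'   expansion, initial weights).
#' @param sigma_in scale of the input projection entries; `NULL` scales
#'   the typical input drive to `|v_rest|`.
#' @param sigma_w initial recurrent weight scale.
#' @param readout_epochs,readout_lr pre-training budget for the readout.
#' @return An agent: list with trained `w`, `readout`, `J_in`, `params`,
#'   `n_units`, the per-demo target rasters `s_star`, the pooled
#'   `"training_log"`-like metric vectors `mse` and `spike_err`
#'   (means across demonstrations per epoch), and `config`.
#' @export
train_behavioral_cloning <- function(demos, params, R,
                                     config = learning_config(
                                       eta = 0.01, eta_ro = 0.01,
                                       optimizer = "adam",
                                       train_readout = TRUE),
                                     feedback_mode = c("diagonal",
                                                       "from_readout"),
                                     seed = 1, sigma_in = NULL,
                                     sigma_w = 1,
                                     readout_epochs = 2000,
                                     readout_lr = 1e-2) {
  feedback_mode <- match.arg(feedback_mode)
  N <- params$N
  I_dim <- nrow(demos[[1]]$states)
  O <- nrow(demos[[1]]$actions)
  if (R < O || R > N) stop("need O <= R <= N")
  for (d in demos) {
    if (nrow(d$states) != I_dim || nrow(d$actions) != O ||
        ncol(d$states) != ncol(d$actions))
      stop("demonstrations must share state/action dimensions and T")
  }
  if (is.null(sigma_in)) {
    all_states <- do.call(cbind, lapply(demos, `[[`, "states"))
    rms <- sqrt(mean(colSums(all_states^2)))
    sigma_in <- abs(params$v_rest) / rms
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 1))
  J_in <- matrix(stats::rnorm(N * I_dim, sd = sigma_in), N, I_dim)

  all_actions <- do.call(cbind, lapply(demos, `[[`, "actions"))
  rms_a <- sqrt(mean(colSums(all_actions^2)))
  sigma_proj <- if (rms_a > 0) abs(params$v_rest) / rms_a else 1

  inputs <- lapply(demos, function(d) J_in %*% d$states)
  targets <- lapply(seq_along(demos), function(i) {
    generate_target_spikes(demos[[i]]$actions, inputs[[i]], params,
                           sigma_proj = sigma_proj,
                           seed = derive_seed(seed, 2))
  })
  s_bar_ro <- lapply(targets, function(tg)
    filter_spikes(tg$raster$spikes, params$tau_ro, params$dt))
  ro <- train_readout(do.call(cbind, s_bar_ro), all_actions,
                      lr = readout_lr, epochs = readout_epochs)
  ro$tau <- params$tau_ro
  Bp <- expand_readout(ro, R, seed = derive_seed(seed, 3))
  fb <- build_feedback(feedback_mode, R, N, B_plus = Bp,
                       seed = derive_seed(seed, 3))
  bundles <- lapply(seq_along(demos), function(i)
    make_generalized_target(Bp, targets[[i]]$raster, demos[[i]]$actions,
                            params$tau_star, params$dt))

  set.seed(derive_seed(seed, 4))
  w <- init_weights(N, sigma_w, params$zero_diag)
  E <- config$epochs
  mse <- se <- numeric(E)
  opt <- NULL; opt_ro <- NULL
  for (n in seq_len(E)) {
    m_ep <- s_ep <- 0
    for (i in seq_along(demos)) {
      res <- train_epoch(w, inputs[[i]], bundles[[i]], fb, config, params,
                         readout = ro, opt = opt)
      w <- res$w; opt <- res$opt
      m_ep <- m_ep + res$mse; s_ep <- s_ep + res$spike_err
      if (config$train_readout) {
        X <- filter_spikes(res$raster$spikes, ro$tau, params$dt)
        G <- -2 * ((bundles[[i]]$y_star - ro$B %*% X) %*% t(X)) / ncol(X)
        if (is.null(opt_ro)) opt_ro <- adam_init(dim(ro$B),
                                                 lr = config$eta_ro)
        upd <- adam_step(opt_ro, G)
        opt_ro <- upd$opt
        ro$B <- ro$B - upd$delta
      }
    }
    mse[n] <- m_ep / length(demos)
    se[n] <- s_ep / length(demos)
  }
  list(w = w, readout = ro, J_in = J_in, params = params,
       n_units = if (!is.null(demos[[1]]$n_units)) demos[[1]]$n_units
                 else I_dim %/% 4,
       s_star = lapply(targets, `[[`, "raster"),
       mse = mse, spike_err = se, config = config, feedback = fb,
       sigma_in = sigma_in, sigma_proj = sigma_proj, seed = seed)
}

#' Closed-loop generalization sweep over food angles
#'
#' Rolls the trained agent out for every angle in `theta_grid`,
#' `repetitions` times each, and tabulates the final rewards.
#'
#' @param agent a [train_behavioral_cloning()] agent (or any list with
#'   `w`, `readout`, `J_in`, `params`, `n_units`).
#' @param theta_grid food angles (degrees).
#' @param repetitions rollouts per angle (rollouts are deterministic, so
#'   repetitions matter only for externally perturbed agents).
#' @param T_steps episode length.
#' @return A data frame with columns `theta`, `rep`, `reward`, carrying
#'   the grand mean as attribute `"mean_reward"`.
#' @export
evaluate_generalization <- function(agent, theta_grid = seq(30, 150, 20),
                                    repetitions = 1, T_steps = 80) {
  rows <- expand.grid(rep = seq_len(repetitions), theta = theta_grid)
  rows$reward <- vapply(seq_len(nrow(rows)), function(i) {
    run_closed_loop(agent, rows$theta[i], T_steps)$reward
  }, numeric(1))
  out <- rows[, c("theta", "rep", "reward")]
  attr(out, "mean_reward") <- mean(out$reward)
  out
}
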