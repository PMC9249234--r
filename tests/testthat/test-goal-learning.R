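test_that("weight updates match a naive quadruple-loop oracle", {
  for (seed in 1:3) {
    tc <- toy_instance(N = 4, Tn = 10, O = 2, R = 3, seed = seed)
    D <- crossprod(tc$B_plus)
    got <- delta_w_target_form(D, tc$s_bar_star, tc$s_bar, tc$p, tc$e,
                               eta = 0.7)
    ref <- oracle_delta_w(D, tc$s_bar_star - tc$s_bar, tc$p, tc$e, 0.7)
    expect_lt(max(abs(got - ref)), 1e-12)

    Y_star <- tc$B_plus %*% tc$s_bar_star
    Y <- tc$B_plus %*% tc$s_bar
    got_e <- delta_w_error_form(tc$B_plus, Y_star, Y, tc$p, tc$e, eta = 0.7)
    ref_e <- oracle_delta_w(t(tc$B_plus), Y_star - Y, tc$p, tc$e, 0.7)
    expect_lt(max(abs(got_e - ref_e)), 1e-12)

    got_l <- delta_w_ltts(tc$s_bar_star, tc$s_bar, tc$p, tc$e, eta = 0.7)
    ref_l <- oracle_delta_w(diag(tc$N), tc$s_bar_star - tc$s_bar,
                            tc$p, tc$e, 0.7)
    expect_lt(max(abs(got_l - ref_l)), 1e-12)
  }
})

test_that("the three update forms coincide under the stated substitutions", {
  for (seed in 1:10) {
    tc <- toy_instance(N = 6, Tn = 12, O = 2, R = 5, seed = seed)
    # error form with Y* = B+ s_bar* equals target form with D = B+^T B+
    dw_err <- delta_w_error_form(tc$B_plus, tc$B_plus %*% tc$s_bar_star,
                                 tc$B_plus %*% tc$s_bar, tc$p, tc$e, 1)
    dw_tgt <- delta_w_target_form(crossprod(tc$B_plus), tc$s_bar_star,
                                  tc$s_bar, tc$p, tc$e, 1)
    expect_lt(max(abs(dw_err - dw_tgt)), 1e-12)
    # target form with identity feedback equals the local rule
    dw_id <- delta_w_target_form(diag(tc$N), tc$s_bar_star, tc$s_bar,
                                 tc$p, tc$e, 1)
    dw_ltts <- delta_w_ltts(tc$s_bar_star, tc$s_bar, tc$p, tc$e, 1)
    expect_lt(max(abs(dw_id - dw_ltts)), 1e-12)
  }
})

test_that("zero error or zero gating produce a zero update", {
  tc <- toy_instance(seed = 3)
  z <- delta_w_ltts(tc$s_bar, tc$s_bar, tc$p, tc$e, 1)
  expect_true(all(z == 0))
  z2 <- delta_w_target_form(crossprod(tc$B_plus), tc$s_bar_star, tc$s_bar,
                            tc$p * 0, tc$e, 1)
  expect_true(all(z2 == 0))
  Yx <- tc$B_plus %*% tc$s_bar
  expect_true(all(delta_w_error_form(tc$B_plus, Yx, Yx, tc$p, tc$e, 1) == 0))
})

test_that("the local rule touches only the perturbed postsynaptic row", {
  tc <- toy_instance(N = 5, Tn = 9, seed = 4)
  base <- delta_w_ltts(tc$s_bar_star, tc$s_bar, tc$p, tc$e, 1)
  s2 <- tc$s_bar
  s2[3, ] <- s2[3, ] + 0.25
  pert <- delta_w_ltts(tc$s_bar_star, s2, tc$p, tc$e, 1)
  changed <- which(rowSums(abs(pert - base)) > 0)
  expect_identical(changed, 3L)
})

test_that("spike error counts mismatches", {
  a <- matrix(0, 3, 4); b <- a
  expect_identical(spike_error(a, b), 0)
  a[1, 2] <- 1; b[3, 4] <- 1
  expect_identical(spike_error(a, b), 2)
  set.seed(5)
  x <- matrix(rbinom(60, 1, 0.4), 6, 10)
  y <- matrix(rbinom(60, 1, 0.4), 6, 10)
  ref <- 0
  for (i in 1:6) for (t in 1:10) ref <- ref + abs(x[i, t] - y[i, t])
  expect_equal(spike_error(x, y), ref)
  expect_error(spike_error(x, y[, 1:5]), "dimensions")
})

test_that("convergence time is the first crossing of half the initial error", {
  expect_identical(convergence_time(c(8, 7, 6, 5, 4.5, 4.2, 4)), 7L)
  expect_identical(convergence_time(rep(3, 50)), NA_integer_)
  set.seed(6)
  noisy <- 10 * exp(-(1:100) / 25) + runif(100)
  ref <- NA_integer_
  for (n in seq_along(noisy)) {
    if (noisy[n] <= noisy[1] / 2) { ref <- n; break }
  }
  expect_identical(convergence_time(noisy), ref)
})

test_that("halting condition bounds the update norm", {
  # if every mixed error |sum_k D[h,k] delta[k,t]| < eps then each entry of
  # the update is bounded by eta * eps * sum_t max_i p max_j e
  set.seed(7)
  N <- 8; Tn <- 14
  D <- crossprod(matrix(rnorm(N * N), N, N)) / N
  p <- matrix(runif(N * Tn), N, Tn)
  e <- matrix(runif(N * Tn), N, Tn)
  delta <- matrix(rnorm(N * Tn, sd = 1e-4), N, Tn)  # small spike errors
  mixed <- D %*% delta
  eps <- max(abs(mixed)) * 1.0000001
  dw <- delta_w_target_form(D, delta, matrix(0, N, Tn), p, e, eta = 0.3)
  bound <- 0.3 * eps * sum(apply(p[, -Tn, drop = FALSE], 2, max) *
                             apply(e[, -Tn, drop = FALSE], 2, max))
  expect_lte(max(abs(dw)), bound + 1e-12)
})

test_that("an epoch with zero learning rate leaves the weights unchanged", {
  p <- toy_params(N = 10)
  spec <- store_recall_spec(O = 2, T_steps = 40, seed = 2)
  task <- make_store_recall(spec, 10, p$dt)
  tgt <- suppressWarnings(generate_target_spikes(task$y_star, task$input, p,
                                                 seed = 3))
  ex <- expand_readout(matrix(0.1, 2, 10), 10, seed = 1)
  bundle <- make_generalized_target(ex, tgt$raster, task$y_star, p$tau_star)
  fb <- build_feedback("diagonal", 10, 10)
  cfg <- learning_config(eta = 0, epochs = 1)
  set.seed(8); w <- init_weights(10)
  res <- train_epoch(w, task$input, bundle, fb, cfg, p)
  expect_identical(res$w, w)
  expect_true(res$spike_err >= 0)
})

test_that("training epochs are deterministic given the seed", {
  p <- network_params(N = 20, tau_star = 0)
  spec <- store_recall_spec(T_steps = 50, seed = 5)
  cfg <- learning_config(eta = 0.05, epochs = 3, optimizer = "adam")
  r1 <- run_store_recall(spec, p, R = 20, cfg, feedback_mode = "diagonal",
                         seed = 4, readout_epochs = 50)
  r2 <- run_store_recall(spec, p, R = 20, cfg, feedback_mode = "diagonal",
                         seed = 4, readout_epochs = 50)
  expect_identical(r1$log$mse, r2$log$mse)
  expect_identical(r1$log$w, r2$log$w)
  expect_identical(r1$log$spike_err, r2$log$spike_err)
})

test_that("the clamped rule is rejected below full rank", {
  p <- toy_params(N = 6)
  spec <- store_recall_spec(O = 2, T_steps = 30, seed = 2)
  task <- make_store_recall(spec, 6, p$dt)
  tgt <- suppressWarnings(generate_target_spikes(task$y_star, task$input, p,
                                                 seed = 3))
  ex <- expand_readout(matrix(0.1, 2, 6), 4, seed = 1)
  bundle <- make_generalized_target(ex, tgt$raster, task$y_star, p$tau_star)
  fb <- build_feedback("diagonal", 4, 6)
  cfg <- learning_config(clamped = TRUE)
  expect_error(train_epoch(init_weights(6), task$input, bundle, fb, cfg, p),
               "full rank")
})

test_that("spike-cloning error decreases early in training across seeds", {
  p <- network_params(N = 30, tau_star = 0)
  ok <- 0
  for (seed in 1:5) {
    spec <- store_recall_spec(T_steps = 60, seed = derive_seed(seed, 3))
    cfg <- learning_config(eta = 0.1, epochs = 12, rule = "ltts",
                           optimizer = "adam", clamped = TRUE, margin = 0.3)
    run <- run_store_recall(spec, p, R = 30, cfg, feedback_mode = "diagonal",
                            seed = seed, readout_epochs = 50)
    if (run$log$spike_err[12] < run$log$spike_err[1]) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("behavioral cloning of a silent expert stays near zero output", {
  p <- network_params(N = 30)
  set.seed(9)
  states <- matrix(abs(rnorm(10 * 40)), 10, 40)
  demo <- list(states = states, actions = matrix(0, 2, 40))
  cfg <- learning_config(eta = 0.01, epochs = 10, optimizer = "adam",
                         train_readout = TRUE)
  ag <- suppressWarnings(train_behavioral_cloning(list(demo), p, R = 30, cfg,
                                                  seed = 1,
                                                  readout_epochs = 100))
  expect_lt(ag$mse[10], 1e-6)
})

test_that("cloning a linear expert approaches the readout limit", {
  p <- network_params(N = 80, tau_star = 2)
  set.seed(10)
  Tn <- 60
  tt <- seq(0, 1, length.out = Tn)
  states <- rbind(sin(2 * pi * tt), cos(2 * pi * tt),
                  sin(4 * pi * tt), tt) * 0.5 + 0.5
  A_map <- matrix(rnorm(2 * 4, sd = 0.02), 2, 4)
  demo <- list(states = states, actions = A_map %*% states)
  # input scale chosen for a ~20 Hz internal target, dense enough that the
  # filtered-trace basis spans the constraints
  si <- 2 * abs(p$v_rest) / sqrt(mean(colSums(states^2)))
  cfg <- learning_config(eta = 0.05, epochs = 250, optimizer = "adam",
                         clamped = TRUE, margin = 0.3, rule = "target_form")
  ag <- train_behavioral_cloning(list(demo), p, R = 80, cfg, seed = 2,
                                 sigma_in = si)
  expect_lt(ag$mse[250], 2 * ag$readout$residual + 1e-10)
  # identical seeds give identical logs
  ag2 <- train_behavioral_cloning(list(demo), p, R = 80, cfg, seed = 2,
                                  sigma_in = si)
  expect_identical(ag$mse, ag2$mse)
})

test_that("the online (per-step) schedule trains and stays deterministic", {
  p <- network_params(N = 20, tau_star = 0)
  spec <- store_recall_spec(O = 2, T_steps = 50, seed = 6)
  task <- make_store_recall(spec, 20, p$dt)
  tgt <- generate_target_spikes(task$y_star, task$input, p, seed = 2)
  ex <- expand_readout(matrix(0.1, 2, 20), 20, seed = 1)
  bundle <- make_generalized_target(ex, tgt$raster, task$y_star, 0)
  fb <- build_feedback("diagonal", 20, 20)
  cfg <- learning_config(eta = 0.2, epochs = 1, rule = "ltts",
                         schedule = "step")
  set.seed(3); w0 <- init_weights(20)
  a <- train_epoch(w0, task$input, bundle, fb, cfg, p)
  b <- train_epoch(w0, task$input, bundle, fb, cfg, p)
  expect_identical(a$w, b$w)
  expect_false(identical(a$w, w0))  # updates were applied along the way
  cfg0 <- learning_config(eta = 0, epochs = 1, rule = "ltts",
                          schedule = "step")
  expect_identical(train_epoch(w0, task$input, bundle, fb, cfg0, p)$w, w0)
  # clamping has no defined online form
  cfg_cl <- learning_config(schedule = "step", clamped = TRUE)
  expect_error(train_epoch(w0, task$input, bundle, fb, cfg_cl, p),
               "epoch schedule")
})

test_that("the free-trajectory margin reshapes the error without touching dynamics", {
  p <- network_params(N = 15, tau_star = 0)
  spec <- store_recall_spec(O = 2, T_steps = 40, seed = 9)
  task <- make_store_recall(spec, 15, p$dt)
  tgt <- generate_target_spikes(task$y_star, task$input, p, seed = 4)
  ex <- expand_readout(matrix(0.1, 2, 15), 15, seed = 1)
  bundle <- make_generalized_target(ex, tgt$raster, task$y_star, 0)
  fb <- build_feedback("diagonal", 15, 15)
  set.seed(5); w0 <- init_weights(15)
  plain <- train_epoch(w0, task$input, bundle, fb,
                       learning_config(eta = 0.1, rule = "ltts"), p)
  marged <- train_epoch(w0, task$input, bundle, fb,
                        learning_config(eta = 0.1, rule = "ltts",
                                        margin = 0.5), p)
  # same rollout (metrics identical), different error bookkeeping
  expect_identical(plain$spike_err, marged$spike_err)
  expect_identical(plain$raster$spikes, marged$raster$spikes)
  expect_false(identical(plain$w, marged$w))
})
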