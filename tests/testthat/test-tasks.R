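test_that("store-recall targets start at zero when phases are zero", {
  spec <- store_recall_spec(T_steps = 100, phase_range = c(0, 0), seed = 1)
  task <- make_store_recall(spec, N = 10)
  expect_true(all(abs(task$y_star[, 1]) < 1e-12))
})

test_that("store-recall amplitudes obey the triangle-inequality bound", {
  for (seed in 1:3) {
    task <- make_store_recall(store_recall_spec(T_steps = 300, seed = seed),
                              N = 5)
    expect_true(all(abs(task$y_star) <= 8))
    expect_true(all(task$A >= 0.5 & task$A <= 2))
  }
})

test_that("store-recall episodes are reproducible", {
  spec <- store_recall_spec(seed = 9)
  a <- make_store_recall(spec, N = 20)
  b <- make_store_recall(spec, N = 20)
  expect_identical(a$A, b$A)
  expect_identical(a$phi, b$phi)
  expect_identical(a$J_inp, b$J_inp)
  expect_identical(a$input, b$input)
})

test_that("targets are band-limited to the four stated frequencies", {
  # 1 s episode at 1 ms steps puts the 1, 2, 3, 5 Hz components on exact
  # DFT bins; all other bins must carry (numerically) zero power
  task <- make_store_recall(store_recall_spec(T_steps = 1000, seed = 4),
                            N = 2)
  for (k in 1:3) {
    amp <- abs(fft(task$y_star[k, ]))[2:500]  # bins 1..499 Hz
    on <- amp[c(1, 2, 3, 5)]
    off <- amp[-c(1, 2, 3, 5)]
    expect_gt(min(on), 1)
    expect_lt(max(off) / min(on), 1e-9)
  }
})

test_that("the clock tiles the episode with one active channel per step", {
  task <- make_store_recall(store_recall_spec(T_steps = 200, C = 5, seed = 2),
                            N = 4)
  expect_identical(dim(task$clock), c(5L, 200L))
  expect_true(all(colSums(task$clock) == 1))
  expect_true(all(rowSums(task$clock) == 40))
  # channels are contiguous and ordered
  expect_true(all(diff(apply(task$clock, 2, which.max)) >= 0))
})

test_that("tuning-curve encoding matches direct evaluation", {
  st <- button_food_state(75)
  st$agent <- c(0.13, -0.21)
  enc <- encode_state(st, n_units = 20)
  centers <- seq(-1, 1, length.out = 20)
  width <- centers[2] - centers[1]
  deltas <- c(st$button - st$agent, st$food - st$agent)
  ref <- numeric(80)
  for (d in 1:4) {
    for (u in 1:20) {
      ref[(d - 1) * 20 + u] <-
        exp(-(deltas[d] - centers[u])^2 / (2 * width^2))
    }
  }
  expect_lt(max(abs(enc - ref)), 1e-12)
})

test_that("encoding peaks at tuning-curve centers and mirrors symmetric inputs", {
  centers <- seq(-1, 1, length.out = 20)
  st <- button_food_state(90)
  # place the food so that its horizontal offset sits exactly on a center
  st$food <- c(centers[14], 0); st$button <- c(0, 0); st$agent <- c(0, 0)
  enc <- encode_state(st)
  expect_equal(enc[40 + 14], 1)  # third bank, unit 14, at its peak
  # symmetric offsets give mirrored activation patterns
  stp <- button_food_state(90); stp$agent <- c(0, 0)
  stp$button <- c(0.4, 0); stp$food <- c(0, 0)
  stm <- button_food_state(90); stm$agent <- c(0, 0)
  stm$button <- c(-0.4, 0); stm$food <- c(0, 0)
  bank_p <- encode_state(stp)[1:20]
  bank_m <- encode_state(stm)[1:20]
  expect_equal(bank_p, rev(bank_m), tolerance = 1e-12)
})

test_that("the encoder separates states beyond the tuning spacing", {
  grid <- seq(-0.9, 0.9, by = 0.3)  # coarser than the 2/19 spacing
  st <- button_food_state(90)
  encs <- sapply(grid, function(g) {
    st$agent <- c(g, 0)
    encode_state(st)
  })
  dmat <- as.matrix(dist(t(encs)))
  expect_gt(min(dmat[upper.tri(dmat)]), 1e-3)
})

test_that("the expert walks straight through the button to the food", {
  for (theta in c(30, 75, 122, 150)) {
    d <- expert_trajectory(theta)
    st <- button_food_state(theta)
    expect_lt(max(abs(d$positions[, 81] - st$food)), 1e-9)
    expect_lt(max(abs(d$positions[, d$switch_step + 1] - st$button)), 1e-9)
    # total path length equals the analytic two-segment length
    L1 <- 0.2
    L2 <- sqrt(sum((st$food - st$button)^2))
    steps <- sqrt(colSums(d$actions^2))
    expect_lt(abs(sum(steps) - (L1 + L2)), 1e-9)
    expect_identical(dim(d$states), c(80L, 80L))
  }
})

test_that("the environment latches the button and never releases it", {
  st <- button_food_state(90)
  st2 <- env_step(st, c(0, 0))
  expect_identical(st2$agent, st$agent)
  expect_identical(st2$pressed, 0)
  # replaying the expert presses the button exactly at the segment switch
  d <- expert_trajectory(90)
  s <- button_food_state(90)
  pressed <- numeric(80)
  for (t in 1:80) {
    s <- env_step(s, d$actions[, t])
    pressed[t] <- s$pressed
  }
  expect_true(all(pressed[d$switch_step:80] == 1))
  # the latch engages exactly when the path first enters the contact radius
  dists <- sqrt(colSums((d$positions[, -1] - s$button)^2))
  first_contact <- which(dists <= s$contact_radius)[1]
  expect_identical(which(pressed == 1)[1], first_contact)
  expect_true(all(diff(pressed) >= 0))  # monotone latch
})

test_that("reward gates on the button and decreases with distance", {
  s <- button_food_state(90)
  s$agent <- s$food          # at the food but the button was never pressed
  expect_identical(episode_reward(s), 0)
  # expert scores exactly 1
  d <- expert_trajectory(90)
  s <- button_food_state(90)
  for (t in 1:80) s <- env_step(s, d$actions[, t])
  expect_equal(episode_reward(s), 1)
  # pressed, monotone in final distance
  r <- vapply(c(0.1, 0.3, 0.6), function(dist) {
    s <- button_food_state(90)
    s$pressed <- 1
    s$agent <- s$food + c(dist, 0)
    episode_reward(s)
  }, numeric(1))
  expect_true(all(r > 0 & r < 1))
  expect_true(all(diff(r) < 0))
  expect_equal(r, exp(-c(0.1, 0.3, 0.6) / 0.2), tolerance = 1e-12)
})

test_that("an episode that stays away from the button scores zero", {
  s <- button_food_state(90)
  for (t in 1:40) s <- env_step(s, c(0, 0.02))  # walks away upward
  expect_identical(s$pressed, 0)
  expect_identical(episode_reward(s), 0)
})

test_that("an untrained zero-weight agent earns no reward", {
  p <- network_params(N = 20)
  agent <- list(w = matrix(0, 20, 20),
                readout = structure(list(B = matrix(0, 2, 20), tau = 10),
                                    class = "readout_matrix"),
                J_in = matrix(0, 20, 80), params = p, n_units = 20)
  gen <- evaluate_generalization(agent, theta_grid = c(50, 90, 130))
  expect_true(all(gen$reward == 0))
  expect_identical(nrow(gen), 3L)
})
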