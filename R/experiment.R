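#' Validate an experiment configuration
#'
#' Checks a nested configuration list (see [run_experiment()]) against the
#' package's schema and fills in defaults.  Violations are reported with
#' their field path (e.g. `network.N`).
#'
#' @param config a nested list, or a path to a YAML file.
#' @return The resolved configuration (invisibly classed
#'   `"experiment_config"`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  fail <- function(path, msg) stop(sprintf("config field `%s`: %s",
                                           path, msg), call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  net <- config$network
  if (is.null(net$N)) fail("network.N", "is required")
  if (!num1(net$N) || net$N < 1) fail("network.N", "must be a positive number")
  net_defaults <- list(dt = 1, tau_m = 8, tau_s = 2, tau_star = 2,
                       tau_ro = 10, v_th = 0, v_rest = -4, w_res = -20,
                       dv = 1, zero_diag = FALSE)
  for (nm in names(net_defaults))
    if (is.null(net[[nm]])) net[[nm]] <- net_defaults[[nm]]

  tg <- config$targets
  if (is.null(tg)) tg <- list()
  if (is.null(tg$R)) tg$R <- net$N
  if (!num1(tg$R) || tg$R < 1 || tg$R > net$N)
    fail("targets.R", "must satisfy 1 <= R <= network.N")
  if (is.null(tg$mode)) tg$mode <- "from_readout"
  if (!tg$mode %in% c("from_readout", "diagonal", "random_gaussian"))
    fail("targets.mode", "unknown feedback mode")

  lr <- config$learning
  if (is.null(lr)) lr <- list()
  lr_defaults <- list(eta = 0.05, eta_ro = 0.01, epochs = 100,
                      rule = "target_form", clamped = FALSE,
                      optimizer = "sgd", schedule = "epoch", epsilon = 0,
                      train_readout = FALSE)
  for (nm in names(lr_defaults))
    if (is.null(lr[[nm]])) lr[[nm]] <- lr_defaults[[nm]]
  if (!num1(lr$eta) || lr$eta <= 0) fail("learning.eta", "must be > 0")
  if (!num1(lr$epochs) || lr$epochs < 1)
    fail("learning.epochs", "must be >= 1")

  tk <- config$task
  if (is.null(tk)) tk <- list()
  if (is.null(tk$name)) tk$name <- "store_recall"
  if (!tk$name %in% c("store_recall", "button_food"))
    fail("task.name", "must be `store_recall` or `button_food`")
  if (tk$name == "store_recall") {
    tk_defaults <- list(O = 3, C = 5, T_steps = 200, sigma_inp = 10)
    for (nm in names(tk_defaults))
      if (is.null(tk[[nm]])) tk[[nm]] <- tk_defaults[[nm]]
  } else {
    tk_defaults <- list(theta_train = c(50, 90, 130), T_steps = 80,
                        theta_grid = seq(30, 150, by = 20))
    for (nm in names(tk_defaults))
      if (is.null(tk[[nm]])) tk[[nm]] <- tk_defaults[[nm]]
  }

  if (is.null(config$seed)) config$seed <- 1L
  if (!num1(config$seed)) fail("seed", "must be a number")

  structure(list(network = net, targets = tg, learning = lr, task = tk,
                 seed = as.integer(config$seed),
                 version = archive_version()),
            class = "experiment_config")
}

archive_version <- function() "spikerank-archive-1"

config_to_objects <- function(cfg) {
  net <- cfg$network
  params <- network_params(N = net$N, dt = net$dt, tau_m = net$tau_m,
                           tau_s = net$tau_s, tau_star = net$tau_star,
                           tau_ro = net$tau_ro, v_th = net$v_th,
                           v_rest = net$v_rest, w_res = net$w_res,
                           dv = net$dv, zero_diag = net$zero_diag)
  lc <- cfg$learning
  config <- learning_config(eta = lc$eta, eta_ro = lc$eta_ro,
                            epochs = lc$epochs, rule = lc$rule,
                            clamped = lc$clamped, optimizer = lc$optimizer,
                            schedule = lc$schedule, epsilon = lc$epsilon,
                            train_readout = lc$train_readout)
  list(params = params, config = config)
}

#' Run a configured experiment
#'
#' Dispatches on `task.name`: `"store_recall"` runs [run_store_recall()];
#' `"button_food"` trains a behavioral-cloning agent on the configured
#' expert conditions and evaluates it closed-loop over the angle grid.
#' When `out_dir` is given, the fully resolved configuration, per-epoch
#' metrics, final weights and final raster are archived there as plain
#' text (YAML / CSV / JSON), and can be reloaded with [load_archive()].
#'
#' @param config a nested list, a YAML path, or a validated
#'   `"experiment_config"`.
#' @param out_dir optional directory for the result archive.
#' @return An object of class `"result_archive"`: list with `config`,
#'   `metrics` (data frame: epoch, mse, spike_error), `w`, `raster`, and a
#'   task-specific `extra` (e.g. the generalization table).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "experiment_config")) config
         else validate_config(config)
  obj <- config_to_objects(cfg)
  if (cfg$task$name == "store_recall") {
    spec <- store_recall_spec(O = cfg$task$O, C = cfg$task$C,
                              T_steps = cfg$task$T_steps,
                              sigma_inp = cfg$task$sigma_inp,
                              seed = derive_seed(cfg$seed, 0))
    run <- run_store_recall(spec, obj$params, cfg$targets$R, obj$config,
                            feedback_mode = cfg$targets$mode,
                            seed = cfg$seed)
    metrics <- data.frame(epoch = seq_along(run$log$mse),
                          mse = run$log$mse,
                          spike_error = run$log$spike_err)
    res <- list(config = cfg, metrics = metrics, w = run$log$w,
                raster = run$log$raster,
                extra = list(readout_residual = run$readout$residual,
                             t_conv = convergence_time(run$log$mse)))
  } else {
    demos <- lapply(cfg$task$theta_train, expert_trajectory,
                    T_steps = cfg$task$T_steps)
    agent <- train_behavioral_cloning(demos, obj$params, cfg$targets$R,
                                      obj$config, seed = cfg$seed)
    gen <- evaluate_generalization(agent, cfg$task$theta_grid,
                                   T_steps = cfg$task$T_steps)
    metrics <- data.frame(epoch = seq_along(agent$mse), mse = agent$mse,
                          spike_error = agent$spike_err)
    res <- list(config = cfg, metrics = metrics, w = agent$w,
                raster = run_closed_loop(agent,
                                         cfg$task$theta_grid[1],
                                         cfg$task$T_steps)$raster,
                extra = list(generalization = gen,
                             mean_reward = attr(gen, "mean_reward")))
  }
  res <- structure(res, class = "result_archive")
  if (!is.null(out_dir)) save_archive(res, out_dir)
  res
}

#' @export
print.result_archive <- function(x, ...) {
  cat(sprintf("result_archive (%s): task %s, %d epochs\n",
              x$config$version, x$config$task$name, nrow(x$metrics)))
  invisible(x)
}

#' Save / load a result archive
#'
#' Archives are plain-text directories: `config.yaml` (resolved config and
#' version stamp), `metrics.csv`, `weights.csv`, `raster.csv` (tidy
#' `neuron,time` rows of spike events) and `extra.json`.  `load_archive()`
#' restores all stored fields; a version mismatch yields a warning and a
#' best-effort load.
#'
#' @param archive a `"result_archive"`.
#' @param path directory to write to / read from.
#' @return `save_archive()` returns `path` invisibly; `load_archive()` a
#'   `"result_archive"`.
#' @export
save_archive <- function(archive, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(archive$config), file.path(path, "config.yaml"))
  utils::write.csv(archive$metrics, file.path(path, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(archive$w),
                   file.path(path, "weights.csv"), row.names = FALSE)
  utils::write.csv(raster_to_table(archive$raster),
                   file.path(path, "raster.csv"), row.names = FALSE)
  jsonlite::write_json(archive$extra, file.path(path, "extra.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_archive
#' @export
load_archive <- function(path) {
  if (!dir.exists(path)) stop("no archive at ", path)
  cfg <- yaml::read_yaml(file.path(path, "config.yaml"))
  if (!identical(cfg$version, archive_version()))
    warning(sprintf("archive version %s does not match %s; loading anyway",
                    cfg$version, archive_version()))
  metrics <- utils::read.csv(file.path(path, "metrics.csv"))
  w <- as.matrix(utils::read.csv(file.path(path, "weights.csv")))
  dimnames(w) <- NULL
  rt <- utils::read.csv(file.path(path, "raster.csv"))
  extra <- jsonlite::read_json(file.path(path, "extra.json"),
                               simplifyVector = TRUE)
  Tn <- if (nrow(rt) > 0) rt$T[1] else cfg$task$T_steps
  structure(list(config = structure(cfg, class = "experiment_config"),
                 metrics = metrics, w = w,
                 raster = table_to_raster(rt, nrow(w), Tn),
                 extra = extra),
            class = "result_archive")
}

#' Tidy raster exports
#'
#' `raster_to_table()` lists spike events as `(neuron, time)` rows
#' (1-based indices), with the full dimensions kept in the first row's
#' companion columns `N` and `T`; `table_to_raster()` inverts it.
#'
#' @param raster a [spike_raster()] or matrix.
#' @param tab a data frame from `raster_to_table()`.
#' @param N,T_steps dimensions when reconstructing.
#' @return A data frame, or a [spike_raster()].
#' @export
raster_to_table <- function(raster) {
  S <- raster_matrix(raster)
  idx <- which(S == 1, arr.ind = TRUE)
  data.frame(neuron = idx[, 1], time = idx[, 2],
             N = rep(nrow(S), nrow(idx)), T = rep(ncol(S), nrow(idx)))
}

#' @rdname raster_to_table
#' @export
table_to_raster <- function(tab, N = NULL, T_steps = NULL) {
  if (is.null(N)) N <- tab$N[1]
  if (is.null(T_steps) || is.na(T_steps)) T_steps <- tab$T[1]
  S <- matrix(0, N, T_steps)
  if (nrow(tab) > 0) S[cbind(tab$neuron, tab$time)] <- 1
  spike_raster(S)
}

#' Sweep the (rank, tau-star) plane
#'
#' Runs the configured store-and-recall training for every combination of
#' feedback rank and spike-timing tolerance and tabulates the end-of-
#' training output error, spike error and convergence time, one row per
#' grid cell, ready for heat-map plotting.
#'
#' @param config a configuration accepted by [run_experiment()] (the
#'   `targets.R` and `network.tau_star` fields are overridden cell by
#'   cell).
#' @param ranks integer vector of feedback ranks.
#' @param tau_stars numeric vector of tolerances (ms; 0 allowed).
#' @return A data frame with columns `rank`, `tau_star`, `final_mse`,
#'   `final_spike_error`, `t_conv`.
#' @export
sweep_rank_tau <- function(config, ranks, tau_stars) {
  cfg <- if (inherits(config, "experiment_config")) config
         else validate_config(config)
  grid <- expand.grid(rank = ranks, tau_star = tau_stars)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$targets$R <- grid$rank[i]
    cfg_i$network$tau_star <- grid$tau_star[i]
    res <- run_experiment(cfg_i)
    E <- nrow(res$metrics)
    data.frame(rank = grid$rank[i], tau_star = grid$tau_star[i],
               final_mse = res$metrics$mse[E],
               final_spike_error = res$metrics$spike_error[E],
               t_conv = convergence_time(res$metrics$mse))
  })
  do.call(rbind, rows)
}
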