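# Experiment orchestration: one config object drives generator -> search ->
# final retraining -> metrics, with every artifact written to disk and a
# success flag evaluated against configured goal bounds.

#' Search goals and performance bounds
#'
#' The success criterion reads `metric + epsilon >= G` for each configured
#' metric. Defaults are the published comparison bounds: accuracy >= 74.8
#' (percent) with epsilon 1.5, AUC >= 0.91 with epsilon 0.2, kappa >= 0.776
#' with epsilon 0.02.
#'
#' @param accuracy,auc,kappa goal values `G` (accuracy in percent).
#' @param eps_accuracy,eps_auc,eps_kappa acceptable bounds `epsilon`.
#' @return a `search_goals` object.
#' @export
search_goals <- function(accuracy = 74.8, auc = 0.91, kappa = 0.776,
                         eps_accuracy = 1.5, eps_auc = 0.2, eps_kappa = 0.02) {
  structure(list(accuracy = accuracy, auc = auc, kappa = kappa,
                 eps_accuracy = eps_accuracy, eps_auc = eps_auc,
                 eps_kappa = eps_kappa),
            class = "search_goals")
}

#' Evaluate the success criterion
#'
#' @param metrics list with `accuracy` (in `[0,1]`), `auc`, `kappa`.
#' @param goals a [search_goals()].
#' @return named logical vector (`accuracy`, `auc`, `kappa`) plus an
#'   `overall` flag (any goal met).
#' @export
goal_success <- function(metrics, goals = search_goals()) {
  s <- c(accuracy = 100 * metrics$accuracy + goals$eps_accuracy >= goals$accuracy,
         auc = metrics$auc + goals$eps_auc >= goals$auc,
         kappa = metrics$kappa + goals$eps_kappa >= goals$kappa)
  c(s, overall = any(s, na.rm = TRUE))
}

#' Experiment configuration
#'
#' Exactly one data source: a [synth_spec()] (`data = spec`) or a directory
#' with an APTOS-dialect labels CSV (`data = list(dir =, labels_csv =)`).
#'
#' @param mode `"aco"` or `"pso"`.
#' @param data data source (see above).
#' @param search an [aco_config()] or [pso_config()] matching `mode`.
#' @param trainer a [trainer_spec()] for per-candidate fitness training.
#' @param final_epochs retraining epochs for the returned best model.
#' @param folds cross-validation folds for the final report (0 skips CV).
#' @param space a [search_space()].
#' @param rules a [constraint_set()].
#' @param goals a [search_goals()].
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @return an `experiment_config` object (validated).
#' @export
experiment_config <- function(mode = c("pso", "aco"), data, search,
                              trainer = trainer_spec(), final_epochs = 5L,
                              folds = 0L, space = NULL,
                              rules = constraint_set(),
                              goals = search_goals(), out_dir = tempfile("swarmnas_"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "aco" && !inherits(search, "aco_config")) {
    stop("mode 'aco' requires an aco_config")
  }
  if (mode == "pso" && !inherits(search, "pso_config")) {
    stop("mode 'pso' requires a pso_config")
  }
  ok_synth <- inherits(data, "synth_spec")
  ok_dir <- is.list(data) && !is.null(data$dir)
  if (!xor(ok_synth, ok_dir)) {
    stop("data must be exactly one of: a synth_spec, or list(dir=, labels_csv=)")
  }
  if (is.null(space)) {
    space <- if (mode == "aco") aco_space() else pso_space("desk")
  }
  structure(list(mode = mode, data = data, search = search, trainer = trainer,
                 final_epochs = as.integer(final_epochs), folds = as.integer(folds),
                 space = space, rules = rules, goals = goals,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run an end-to-end architecture-search experiment
#'
#' Loads or generates the dataset, runs the configured swarm search with a
#' trainer-backed fitness evaluator, retrains the best architecture for
#' `final_epochs`, scores it, evaluates the success criterion and writes
#' all artifacts (`best_architecture.json`, `history.csv`, `metrics.csv`,
#' `config.yaml`, `log.txt`) to `out_dir`. Deterministic given the config
#' seed.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print progress.
#' @return list with `best_arch`, `search` (raw search output), `metrics`,
#'   `success`, `cv` (when `folds > 0`), `paths`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- Sys.time()
  if (inherits(cfg$data, "synth_spec")) {
    ds <- generate_dataset(cfg$data)
    x <- ds$images; y <- ds$labels
  } else {
    ds <- read_dataset(cfg$data$dir,
                       cfg$data$labels_csv %||% file.path(cfg$data$dir, "labels.csv"))
    x <- ds$images; y <- ds$labels
  }
  n_classes <- length(unique(y))
  if (n_classes < 2L) stop("dataset must contain at least 2 classes")
  input_shape <- dim(x)[1:3]
  evaluator <- make_trainer_evaluator(x, y, cfg$trainer, n_classes = n_classes)
  search <- if (cfg$mode == "aco") {
    run_aco_search(cfg$search, evaluator, space = cfg$space, rules = cfg$rules,
                   input_shape = input_shape, verbose = verbose)
  } else {
    run_pso_search(cfg$search, evaluator, space = cfg$space, rules = cfg$rules,
                   input_shape = input_shape, verbose = verbose)
  }
  best_arch <- search$best_arch %||% search$gbest_arch
  # final retraining of the best architecture on the same 80/20 split
  folds5 <- stratified_kfold(y, 5L, seed = 99L)
  va <- folds5[[1]]; tr <- setdiff(seq_along(y), va)
  final_spec <- trainer_spec(epochs = cfg$final_epochs,
                             batch_size = cfg$trainer$batch_size,
                             image_size = cfg$trainer$image_size,
                             lr = cfg$trainer$lr, patience = cfg$trainer$patience,
                             seed = cfg$trainer$seed)
  net <- instantiate_network(best_arch, input_shape = input_shape,
                             n_classes = n_classes, seed = cfg$seed)
  scored <- train_and_score(net, x[, , , tr, drop = FALSE], y[tr],
                            x[, , , va, drop = FALSE], y[va], final_spec)
  metrics <- scored$result
  success <- goal_success(metrics, cfg$goals)
  cv <- NULL
  if (cfg$folds > 0L) {
    cv <- evaluate_cv(best_arch, x, y, folds = cfg$folds, spec = final_spec,
                      n_classes = n_classes, seed = cfg$seed)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    best_arch = file.path(cfg$out_dir, "best_architecture.json"),
    history = file.path(cfg$out_dir, "history.csv"),
    metrics = file.path(cfg$out_dir, "metrics.csv"),
    config = file.path(cfg$out_dir, "config.yaml"),
    log = file.path(cfg$out_dir, "log.txt")
  )
  architecture_to_json(best_arch, paths$best_arch)
  utils::write.csv(search$history, paths$history, row.names = FALSE)
  mrow <- data.frame(accuracy = metrics$accuracy, auc = metrics$auc,
                     kappa = metrics$kappa,
                     kappa_quadratic = metrics$kappa_quadratic,
                     parameter_count = metrics$parameter_count,
                     success = unname(success["overall"]))
  utils::write.csv(mrow, paths$metrics, row.names = FALSE)
  yaml::write_yaml(config_record(cfg), paths$config)
  writeLines(c(
    sprintf("swarmnas experiment (%s) seed %d", cfg$mode, cfg$seed),
    sprintf("evaluations: %d", nrow(search$history)),
    sprintf("best fitness: %.4f", search$best_fitness %||% search$gbest_fitness),
    sprintf("final accuracy/auc/kappa: %.4f / %.4f / %.4f",
            metrics$accuracy, metrics$auc, metrics$kappa),
    sprintf("success: %s", paste(names(success), unname(success),
                                 sep = "=", collapse = " ")),
    sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), paths$log)
  list(best_arch = best_arch, search = search, metrics = metrics,
       success = success, cv = cv, paths = paths)
}

# flat, YAML-serializable record of a config (replayable provenance)
config_record <- function(cfg) {
  list(
    mode = cfg$mode,
    seed = cfg$seed,
    data = if (inherits(cfg$data, "synth_spec")) {
      c(source = "synth", unclass(cfg$data))
    } else {
      list(source = "directory", dir = cfg$data$dir)
    },
    search = unclass(cfg$search),
    trainer = unclass(cfg$trainer),
    final_epochs = cfg$final_epochs,
    folds = cfg$folds,
    goals = unclass(cfg$goals),
    space = list(layer_vocab = cfg$space$layer_vocab,
                 perm_counts = as.list(cfg$space$perm_counts),
                 B_l = cfg$space$B_l, B_u = cfg$space$B_u)
  )
}

#' Load an experiment configuration from YAML
#'
#' The file mirrors [config_record()]: top-level `mode`, `seed`, `data`
#' (with `source: synth` fields or `source: directory`), `search`,
#' `trainer`, `final_epochs`, `folds`.
#'
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$mode)) stop("config must set mode: aco or pso")
  data <- if (identical(y$data$source, "synth")) {
    synth_spec(n_total = y$data$n_total,
               n_classes = y$data$n_classes %||% 5L,
               image_size = y$data$image_size %||% 64L,
               noise_sigma = y$data$noise_sigma %||% 0.05,
               class_proportions = if (is.null(y$data$class_proportions)) "aptos"
                                   else unlist(y$data$class_proportions),
               seed = y$data$seed %||% 1L)
  } else {
    list(dir = y$data$dir, labels_csv = y$data$labels_csv)
  }
  search <- if (y$mode == "aco") {
    do.call(aco_config, y$search[intersect(names(y$search),
      names(formals(aco_config)))])
  } else {
    ya <- y$search[intersect(names(y$search), names(formals(pso_config)))]
    ya$layer_probs <- if (is.null(ya$layer_probs)) {
      c(conv = 0.7, pool = 0.15, dense = 0.15)
    } else unlist(ya$layer_probs)
    do.call(pso_config, ya)
  }
  trainer <- if (is.null(y$trainer)) trainer_spec() else {
    do.call(trainer_spec, y$trainer[intersect(names(y$trainer),
      names(formals(trainer_spec)))])
  }
  experiment_config(mode = y$mode, data = data, search = search,
                    trainer = trainer,
                    final_epochs = y$final_epochs %||% 5L,
                    folds = y$folds %||% 0L,
                    out_dir = y$out_dir %||% tempfile("swarmnas_"),
                    seed = y$seed %||% 1L)
}
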