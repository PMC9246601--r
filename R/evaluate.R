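# The fitness contract: instantiate a candidate, train it briefly, score it
# on held-out data. Fitness is validation accuracy, the selection metric of
# the search.

#' Trainer settings
#'
#' @param epochs training epochs (0 = evaluate the untrained network).
#' @param batch_size minibatch size.
#' @param image_size square image side in pixels the data is expected at.
#' @param optimizer optimizer name (only `"adam"` is implemented).
#' @param lr learning rate.
#' @param patience early-stop rounds on validation accuracy (0 disables).
#' @param seed integer seed making training deterministic.
#' @return a `trainer_spec` object.
#' @export
trainer_spec <- function(epochs = 1L, batch_size = 32L, image_size = 32L,
                         optimizer = "adam", lr = 1e-3, patience = 0L,
                         seed = 1L) {
  stopifnot(epochs >= 0, image_size >= 8, patience >= 0)
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 image_size = as.integer(image_size), optimizer = optimizer,
                 lr = lr, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "trainer_spec")
}

#' Train a network and score it on a validation split
#'
#' Trains for `spec$epochs` epochs (early-stopping on validation accuracy
#' when `spec$patience > 0`), then reports accuracy, macro one-vs-rest AUC,
#' Cohen's kappa (unweighted and quadratic-weighted) and the trainable
#' parameter count. Fitness is the validation accuracy. A diverged run
#' (non-finite loss) yields fitness 0 with a warning. Deterministic given
#' `spec$seed`.
#'
#' @param net a `swarm_network` from [instantiate_network()].
#' @param x_train,y_train training images `(H, W, C, N)` and labels 0-based.
#' @param x_val,y_val validation split (>= 2 classes).
#' @param spec a [trainer_spec()].
#' @return list with `fitness`, `result` (an eval-result list: `accuracy`,
#'   `auc`, `per_class_auc`, `kappa`, `kappa_quadratic`, `parameter_count`,
#'   `confusion`), `history`, `diverged`.
#' @export
train_and_score <- function(net, x_train, y_train, x_val, y_val, spec) {
  stopifnot(inherits(net, "swarm_network"), inherits(spec, "trainer_spec"))
  if (length(unique(y_train)) < 2L || length(unique(y_val)) < 2L) {
    stop("both splits must contain at least 2 classes")
  }
  set.seed(spec$seed)
  tr <- train_network(net, x_train, y_train, epochs = spec$epochs,
                      batch_size = spec$batch_size, lr = spec$lr,
                      x_val = x_val, y_val = y_val, patience = spec$patience)
  net <- tr$net
  if (tr$diverged) {
    warning("training diverged (non-finite loss); fitness set to 0")
    return(list(fitness = 0, result = NULL, history = tr$history,
                diverged = TRUE, net = net))
  }
  probs <- predict_network(net, x_val, spec$batch_size)
  pred <- max.col(probs) - 1L
  cm <- confusion_matrix(y_val, pred, n_classes = net$n_classes)
  auc <- suppressWarnings(auc_ovr(probs, y_val))
  res <- list(
    accuracy = accuracy_from_confusion(cm),
    auc = auc$macro,
    per_class_auc = auc$per_class,
    kappa = suppressWarnings(cohen_kappa(cm, "none")),
    kappa_quadratic = suppressWarnings(cohen_kappa(cm, "quadratic")),
    parameter_count = network_parameters(net),
    confusion = cm
  )
  list(fitness = res$accuracy, result = res, history = tr$history,
       diverged = FALSE, net = net)
}

#' Build a trainer-backed fitness evaluator
#'
#' Returns a function `f(arch) -> fitness in [0, 1]` that instantiates the
#' candidate, trains it for `spec$epochs` on a stratified 80/20 split of
#' the supplied data, and returns the validation accuracy. Candidates that
#' fail to instantiate (e.g. pooling underflow) or diverge score 0, as the
#' search contract requires.
#'
#' @param x,y dataset images `(H, W, C, N)` and 0-based labels.
#' @param spec a [trainer_spec()].
#' @param n_classes number of classes.
#' @param split_seed seed for the 80/20 stratified split and for weight
#'   initialization, fixed across candidates so every architecture is
#'   compared on the same split from the same initialization draw.
#' @return function taking an [architecture()] and returning a fitness.
#' @export
make_trainer_evaluator <- function(x, y, spec, n_classes = 5L, split_seed = 99L) {
  folds <- stratified_kfold(y, 5L, seed = split_seed)
  val_idx <- folds[[1]]
  tr_idx <- setdiff(seq_along(y), val_idx)
  x_tr <- x[, , , tr_idx, drop = FALSE]; y_tr <- y[tr_idx]
  x_va <- x[, , , val_idx, drop = FALSE]; y_va <- y[val_idx]
  force(spec); force(n_classes)
  function(arch) {
    net <- instantiate_network(arch, input_shape = dim(x_tr)[1:3],
                               n_classes = n_classes, seed = split_seed)
    out <- suppressWarnings(
      train_and_score(net, x_tr, y_tr, x_va, y_va, spec))
    out$fitness
  }
}

#' Surrogate fitness evaluator for search diagnostics
#'
#' A deterministic, training-free fitness: the fraction of layer positions
#' whose kind matches a target architecture (aligned from the input end,
#' normalized by the longer length), squashed into `[0.05, 0.95]`. Useful
#' for exercising the search dynamics (budgets, monotonicity, determinism)
#' without any gradient computation.
#'
#' @param target an [architecture()]; defaults to the 17-layer particle
#'   swarm reference architecture [tdcn_pso_architecture()].
#' @return function taking an [architecture()] and returning a fitness.
#' @export
make_surrogate_evaluator <- function(target = tdcn_pso_architecture()) {
  tk <- arch_kinds(target)
  function(arch) {
    ak <- arch_kinds(arch)
    L <- max(length(ak), length(tk))
    m <- sum(ak[seq_len(min(length(ak), length(tk)))] ==
             tk[seq_len(min(length(ak), length(tk)))])
    0.05 + 0.9 * m / L
  }
}

#' The published 17-layer particle-swarm reference architecture
#'
#' @param input_shape image shape, default 128 x 128 x 3.
#' @return an [architecture()].
#' @export
tdcn_pso_architecture <- function(input_shape = c(128L, 128L, 3L)) {
  parse_architecture(
    "C2D | C2D | BN | DO | C2D | BN | MP | AP | MP | MP | DO | C2D | BN | F | DO | DE | BN",
    input_shape = input_shape)
}

#' Stratified k-fold cross-validated evaluation of an architecture
#'
#' For each fold, the network is re-instantiated, trained on the remaining
#' folds and scored on the held-out fold.
#'
#' @param arch an [architecture()].
#' @param x,y dataset images and 0-based labels.
#' @param folds number of folds.
#' @param spec a [trainer_spec()].
#' @param n_classes number of classes.
#' @param seed seed for the fold split.
#' @return list with per-fold `metrics` data frame (fold, accuracy, auc,
#'   kappa, kappa_quadratic) and `summary` (column means).
#' @export
evaluate_cv <- function(arch, x, y, folds = 10L, spec = trainer_spec(),
                        n_classes = 5L, seed = 1L) {
  fl <- stratified_kfold(y, folds, seed = seed)
  rows <- vector("list", length(fl))
  for (f in seq_along(fl)) {
    va <- fl[[f]]
    tr <- setdiff(seq_along(y), va)
    net <- instantiate_network(arch, input_shape = dim(x)[1:3],
                               n_classes = n_classes, seed = spec$seed + f)
    out <- train_and_score(net, x[, , , tr, drop = FALSE], y[tr],
                           x[, , , va, drop = FALSE], y[va], spec)
    r <- out$result
    rows[[f]] <- data.frame(fold = f,
                            accuracy = if (is.null(r)) 0 else r$accuracy,
                            auc = if (is.null(r)) NA_real_ else r$auc,
                            kappa = if (is.null(r)) NA_real_ else r$kappa,
                            kappa_quadratic = if (is.null(r)) NA_real_ else r$kappa_quadratic)
  }
  metrics <- do.call(rbind, rows)
  list(metrics = metrics,
       summary = colMeans(metrics[, -1, drop = FALSE], na.rm = TRUE))
}
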