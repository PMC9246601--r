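test_that("accuracy is the trace over the grand total", {
  expect_equal(accuracy_from_confusion(diag(c(3, 5, 7))), 1)
  expect_equal(accuracy_from_confusion(matrix(c(50, 10, 0, 40), 2)), 0.9)
  expect_equal(accuracy_from_confusion(matrix(c(0, 4, 6, 0), 2)), 0)
  expect_error(accuracy_from_confusion(matrix(0, 2, 2)), "empty")
  expect_error(accuracy_from_confusion(matrix(1, 2, 3)), "square")
})

test_that("one-vs-rest AUC matches the rank statistic conventions", {
  # binary labels (1,0,1,0), positive scores (0.9,0.8,0.3,0.2): 3/4 pairs
  scores <- cbind(1 - c(0.9, 0.8, 0.3, 0.2), c(0.9, 0.8, 0.3, 0.2))
  a <- auc_ovr(scores, c(1, 0, 1, 0))
  expect_equal(a$per_class[2], 0.75)

  # perfectly ordered scores give AUC 1
  sc <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(auc_ovr(sc, c(0, 0, 1, 1))$macro, 1)

  # all-identical scores give 0.5 under the tie convention
  expect_equal(auc_ovr(matrix(0.5, 6, 2), c(0, 1, 0, 1, 0, 1))$macro, 0.5)

  # a class with no positives is skipped with a warning
  set.seed(1)
  expect_warning(r <- auc_ovr(matrix(runif(18), 6, 3), c(0, 0, 0, 1, 1, 1)),
                 "no positives")
  expect_true(is.na(r$per_class[3]))
  expect_false(anyNA(r$per_class[1:2]))
})

test_that("AUC agrees with the pairwise-concordance oracle and pROC", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    labels <- sample(0:2, n, replace = TRUE)
    if (length(unique(labels)) < 3) next
    scores <- matrix(runif(3 * n), n, 3)
    if (i %% 4 == 0) scores <- round(scores, 1)  # force ties
    got <- auc_ovr(scores, labels)
    for (k in 1:3) {
      expect_equal(got$per_class[k], auc_pairs_oracle(scores[, k], labels == k - 1),
                   tolerance = 1e-12)
    }
  }
  # independent library cross-check on one binary instance
  set.seed(8)
  lab <- sample(0:1, 40, replace = TRUE)
  sc <- runif(40)
  ours <- auc_ovr(cbind(1 - sc, sc), lab)$per_class[2]
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  labels <- sample(0:2, 30, replace = TRUE)
  scores <- matrix(runif(90), 30, 3)
  a1 <- auc_ovr(scores, labels)$macro
  a2 <- auc_ovr(exp(3 * scores), labels)$macro
  a3 <- auc_ovr(qlogis(scores * 0.98 + 0.01), labels)$macro
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("Cohen's kappa follows the po/pe definition", {
  expect_equal(cohen_kappa(diag(c(4, 9, 2))), 1)
  # po = 0.8, pe = 0.52 -> (0.8 - 0.52) / 0.48
  expect_equal(cohen_kappa(matrix(c(25, 5, 5, 15), 2, byrow = TRUE)),
               0.28 / 0.48)
  # exact marginal independence gives kappa 0
  ind <- outer(c(10, 30), c(20, 20)) / 40
  expect_equal(cohen_kappa(ind), 0)
  expect_warning(k <- cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")
  expect_true(is.na(k))
})

test_that("kappa agrees with the direct po/pe oracle on random tables", {
  set.seed(17)
  for (i in 1:200) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 4), K)
    if (sum(cm) == 0) next
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (abs(1 - pe) < 1e-12) next
    expect_equal(cohen_kappa(cm), kappa_oracle(cm), tolerance = 1e-12)
  }
})

test_that("quadratic-weighted kappa penalizes distant disagreements", {
  # perfect agreement is still 1
  expect_equal(cohen_kappa(diag(c(5, 5, 5)), "quadratic"), 1)
  # off-by-two errors hurt more than off-by-one at equal counts
  near <- matrix(0, 3, 3); near[1, 1] <- 8; near[2, 3] <- 4; near[3, 3] <- 8
  far <- matrix(0, 3, 3); far[1, 1] <- 8; far[3, 1] <- 4; far[3, 3] <- 8
  k_near <- cohen_kappa(near, "quadratic")
  k_far <- cohen_kappa(far, "quadratic")
  expect_true(k_far < k_near)
})

test_that("stratified folds preserve per-class counts within one", {
  labels <- c(rep(0, 20), rep(1, 10))
  folds <- stratified_kfold(labels, 10, seed = 2)
  for (f in folds) {
    expect_identical(sum(labels[f] == 0), 2L)
    expect_identical(sum(labels[f] == 1), 1L)
  }
  # disjoint and covering
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels))

  expect_length(stratified_kfold(labels, 1)[[1]], 30)
  expect_error(stratified_kfold(c(rep("A", 5), rep("B", 20)), 10), "A")

  f1 <- stratified_kfold(labels, 5, seed = 9)
  f2 <- stratified_kfold(labels, 5, seed = 9)
  expect_identical(f1, f2)
})

test_that("parameter counting follows the layer conventions", {
  a <- architecture(list(layer_spec("C2D", filters = 2, kernel = 3),
                         layer_spec("F"),
                         layer_spec("DE", units = 3)),
                    input_shape = c(8, 8, 1))
  expect_equal(count_parameters(a), 407)  # 20 conv + 387 dense

  d <- architecture(list(layer_spec("DE", units = 1)))
  expect_equal(count_parameters(d, input_shape = 1L), 2)  # weight + bias

  # parameterless layers never change the count
  b <- architecture(list(layer_spec("C2D", filters = 2, kernel = 3),
                         layer_spec("MP", pool = 2),
                         layer_spec("AP", pool = 2),
                         layer_spec("F"),
                         layer_spec("DE", units = 3)),
                    input_shape = c(8, 8, 1))
  expect_equal(count_parameters(b),
               20 + (2 * 2 * 2) * 3 + 3)  # pooled to 2x2x2 before flatten

  # batch normalization contributes two trainable terms per channel
  bn <- architecture(list(layer_spec("C2D", filters = 4, kernel = 3),
                          layer_spec("BN"), layer_spec("F"),
                          layer_spec("DE", units = 2)),
                     input_shape = c(4, 4, 1))
  expect_equal(count_parameters(bn), (9 * 4 + 4) + 8 + (64 * 2 + 2))
})

test_that("instantiation validates shapes and is deterministic", {
  # the 17-layer reference architecture instantiates at 128 x 128 x 3
  net <- instantiate_network(tdcn_pso_architecture(), c(128, 128, 3),
                             n_classes = 5, seed = 1)
  expect_s3_class(net, "swarm_network")
  expect_gt(network_parameters(net), 0)

  # dense on an image input must fail
  expect_error(instantiate_network(architecture(list(layer_spec("DE", units = 4)),
                                                c(8, 8, 1)),
                                   c(8, 8, 1)),
               "DE.*flattened")

  # pooling below 1 x 1 names the offending layer
  deep_pool <- parse_architecture(paste(c(rep("MP", 5), "F", "DE"),
                                        collapse = " | "),
                                  input_shape = c(16, 16, 3))
  expect_error(instantiate_network(deep_pool, c(16, 16, 3)), "layer 5")

  n1 <- instantiate_network(tdcn_pso_architecture(c(32, 32, 3)), c(32, 32, 3),
                            seed = 42)
  n2 <- instantiate_network(tdcn_pso_architecture(c(32, 32, 3)), c(32, 32, 3),
                            seed = 42)
  expect_identical(n1$layers[[1]]$W, n2$layers[[1]]$W)
})

test_that("an untrained network scores near chance on balanced data", {
  ds <- tiny_dataset(seed = 3, n = 100)
  arch <- parse_architecture("C2D | MP | F | DE", input_shape = c(16, 16, 3))
  accs <- vapply(1:3, function(sd) {
    net <- instantiate_network(arch, c(16, 16, 3), n_classes = 5, seed = sd)
    out <- train_and_score(net, ds$images[, , , 1:60, drop = FALSE],
                           ds$labels[1:60],
                           ds$images[, , , 61:100, drop = FALSE],
                           ds$labels[61:100],
                           trainer_spec(epochs = 0, image_size = 16, seed = sd))
    out$result$accuracy
  }, numeric(1))
  expect_true(all(abs(accs - 0.2) <= 0.15))
})

test_that("training is deterministic given the trainer seed", {
  ds <- tiny_dataset(seed = 4, n = 80)
  arch <- parse_architecture("C2D | BN | MP | F | DE",
                             input_shape = c(16, 16, 3))
  run_once <- function() {
    net <- instantiate_network(arch, c(16, 16, 3), n_classes = 5, seed = 7)
    train_and_score(net, ds$images[, , , 1:50, drop = FALSE], ds$labels[1:50],
                    ds$images[, , , 51:80, drop = FALSE], ds$labels[51:80],
                    trainer_spec(epochs = 2, batch_size = 8, image_size = 16,
                                 seed = 11))
  }
  o1 <- run_once(); o2 <- run_once()
  expect_identical(o1$result$accuracy, o2$result$accuracy)
  expect_identical(o1$result$auc, o2$result$auc)
  expect_identical(o1$history, o2$history)
})

test_that("cross-validated evaluation returns per-fold metrics", {
  ds <- tiny_dataset(seed = 5, n = 100)
  arch <- parse_architecture("C2D | BN | MP | F | DE",
                             input_shape = c(16, 16, 3))
  cv <- evaluate_cv(arch, ds$images, ds$labels, folds = 3,
                    spec = trainer_spec(epochs = 1, batch_size = 8,
                                        image_size = 16, lr = 2e-3, seed = 2),
                    n_classes = 5, seed = 6)
  expect_identical(nrow(cv$metrics), 3L)
  expect_true(all(cv$metrics$accuracy >= 0 & cv$metrics$accuracy <= 1))
  expect_named(cv$summary, c("accuracy", "auc", "kappa", "kappa_quadratic"))
})
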