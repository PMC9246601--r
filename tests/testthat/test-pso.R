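test_that("swarm initialization is feasible and reproducible", {
  space <- pso_space("desk")
  cfg <- pso_config(runs = 1, iterations = 1, swarm_size = 20, image_size = 32,
                    seed = 3)
  set.seed(cfg$seed)
  s1 <- init_swarm(cfg, space)
  expect_length(s1, 20)
  for (p in s1) {
    expect_length(validate_architecture(p$arch), 0)
    expect_identical(format_architecture(p$pbest_arch),
                     format_architecture(p$arch))
  }
  set.seed(cfg$seed)
  s2 <- init_swarm(cfg, space)
  expect_identical(vapply(s1, function(p) format_architecture(p$arch), ""),
                   vapply(s2, function(p) format_architecture(p$arch), ""))
})

test_that("velocity degenerates correctly at the coefficient extremes", {
  space <- pso_space("desk")
  p_arch <- random_architecture(space, input_shape = c(32, 32, 3), seed = 1)
  g_arch <- random_architecture(space, input_shape = c(32, 32, 3), seed = 2)
  particle <- list(arch = p_arch, pbest_arch = p_arch, pbest_fitness = 0.5)

  set.seed(10)
  v1 <- compute_velocity(particle, g_arch, cg = 1)
  expect_false(any(v1 == "copy_from_pbest"))
  v0 <- compute_velocity(particle, g_arch, cg = 0)
  expect_false(any(v0 == "copy_from_gbest"))

  # identical particle, pbest and gbest -> pure keep
  same <- list(arch = p_arch, pbest_arch = p_arch, pbest_fitness = 0.5)
  vk <- compute_velocity(same, p_arch, cg = 0.5)
  expect_true(all(vk == "keep"))
})

test_that("slot decisions follow the Bernoulli(Cg) source rule", {
  # particle differing from both sources at every slot
  p_arch <- parse_architecture(paste(rep("C2D", 5), collapse = " | "))
  g_arch <- parse_architecture(paste(rep("DE", 5), collapse = " | "))
  b_arch <- parse_architecture(paste(rep("MP", 5), collapse = " | "))
  particle <- list(arch = p_arch, pbest_arch = b_arch, pbest_fitness = 0.5)
  set.seed(42)
  ops <- unlist(replicate(2000, compute_velocity(particle, g_arch, cg = 0.5),
                          simplify = FALSE))
  expect_equal(mean(ops == "copy_from_gbest"), 0.5, tolerance = 0.02)
})

test_that("applying a velocity rewrites slots and stays feasible", {
  space <- pso_space("desk")
  p_arch <- random_architecture(space, input_shape = c(32, 32, 3), seed = 4)
  g_arch <- random_architecture(space, input_shape = c(32, 32, 3), seed = 5)
  particle <- list(arch = p_arch, pbest_arch = p_arch, pbest_fitness = 0.4)

  # all-keep velocity is the identity
  keepv <- structure(rep("keep", length(p_arch)), class = "pso_velocity")
  same <- apply_velocity(particle, keepv, g_arch, space = space)
  expect_identical(format_architecture(same), format_architecture(p_arch))

  # full copy onto an equal-length particle reproduces gbest
  eqp <- list(arch = g_arch, pbest_arch = g_arch, pbest_fitness = 0.4)
  p2 <- list(arch = p_arch, pbest_arch = p_arch, pbest_fitness = 0.4)
  if (length(p_arch) == length(g_arch)) {
    allg <- structure(rep("copy_from_gbest", length(g_arch)),
                      class = "pso_velocity")
    got <- apply_velocity(p2, allg, g_arch, space = space)
    expect_identical(format_architecture(got), format_architecture(g_arch))
  }

  # any random velocity yields a feasible architecture
  for (sd in 1:15) {
    set.seed(sd)
    v <- compute_velocity(particle, g_arch, cg = 0.5)
    out <- apply_velocity(particle, v, g_arch, space = space)
    expect_length(validate_architecture(out), 0)
    # growth capped at B_u (or the particle's own length) plus repair edits
    expect_lte(length(out), max(space$B_u, length(p_arch)) + 2L)
  }
})

test_that("full gbest copy at equal lengths is idempotent", {
  space <- pso_space("desk")
  g_arch <- random_architecture(space, input_shape = c(32, 32, 3), seed = 6)
  particle <- list(arch = g_arch, pbest_arch = g_arch, pbest_fitness = 0.9)
  set.seed(8)
  v <- compute_velocity(particle, g_arch, cg = 1)
  expect_true(all(v == "keep"))
  out <- apply_velocity(particle, v, g_arch, space = space)
  expect_identical(format_architecture(out), format_architecture(g_arch))
})

test_that("PSO search spends exactly r x i x p evaluations with monotone gbest", {
  ce <- counting_evaluator(make_surrogate_evaluator())
  cfg <- pso_config(runs = 2, iterations = 3, swarm_size = 4, image_size = 32,
                    seed = 21)
  res <- run_pso_search(cfg, ce$fn, space = pso_space("desk"))
  expect_identical(ce$calls(), 24L)
  expect_identical(nrow(res$history), 24L)
  for (r in 1:2) {
    g <- res$history$gbest_fitness[res$history$run == r]
    expect_true(all(diff(g) >= 0))
  }
  expect_equal(res$gbest_fitness, max(res$per_run))
  # every intermediate architecture in the history is feasible
  for (s in res$history$notation) {
    expect_length(validate_architecture(parse_architecture(s)), 0)
  }
})

test_that("seeded PSO searches replay identically", {
  cfg <- pso_config(runs = 1, iterations = 3, swarm_size = 3, image_size = 32,
                    seed = 77)
  r1 <- run_pso_search(cfg, make_surrogate_evaluator(), space = pso_space("desk"))
  r2 <- run_pso_search(cfg, make_surrogate_evaluator(), space = pso_space("desk"))
  expect_identical(r1$history, r2$history)
  expect_identical(format_architecture(r1$gbest_arch),
                   format_architecture(r2$gbest_arch))
})

test_that("pbest fitness never decreases over iterations", {
  cfg <- pso_config(runs = 1, iterations = 4, swarm_size = 3, image_size = 32,
                    seed = 13)
  res <- run_pso_search(cfg, make_surrogate_evaluator(), space = pso_space("desk"))
  h <- res$history
  for (k in unique(h$particle)) {
    fit <- h$fitness[h$particle == k]
    running_best <- cummax(fit)
    expect_true(all(diff(running_best) >= 0))
  }
})
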