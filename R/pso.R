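# Particle-swarm architecture search. A particle is an architecture; its
# velocity is a per-slot block-copy plan over layer positions: keep the
# slot, copy it from the particle's personal best, or copy it from the
# swarm's global best, the latter with probability Cg. The continuous
# update's symbols (inertia w, acceleration c1, random draws r_t1, r_t2)
# are retained in the config as documented but unused fields; the discrete
# block-copy scheme is what moves particles.

#' PSO search settings
#'
#' @param runs number of independent runs `r` (published profile: 5).
#' @param iterations iterations `i` per run (published profile: 12).
#' @param swarm_size particles `p` per swarm (published profile: 20).
#' @param cg probability `Cg` in `[0, 1]` that a differing slot is copied
#'   from the global best rather than the personal best (published: 0.5).
#' @param epochs_particle training epochs per particle evaluation
#'   (published: 1).
#' @param epochs_gbest retraining epochs for the final global best
#'   (published: 100; scale down for desk-sized experiments).
#' @param image_size square image side in pixels (published: 128).
#' @param layer_probs sampling probabilities for conv / pool / dense trunk
#'   layers at initialization (published: 0.7 / 0.15 / 0.15).
#' @param seed integer seed for the whole search.
#' @param w,c1,r_t1,r_t2 coefficients of the continuous velocity update;
#'   documented correspondence only, not used by the discrete scheme.
#' @return a `pso_config` object.
#' @export
pso_config <- function(runs = 5L, iterations = 12L, swarm_size = 20L,
                       cg = 0.5, epochs_particle = 1L, epochs_gbest = 100L,
                       image_size = 128L,
                       layer_probs = c(conv = 0.7, pool = 0.15, dense = 0.15),
                       seed = 1L, w = NULL, c1 = NULL, r_t1 = NULL, r_t2 = NULL) {
  stopifnot(runs >= 1, iterations >= 1, swarm_size >= 1, cg >= 0, cg <= 1)
  structure(list(runs = as.integer(runs), iterations = as.integer(iterations),
                 swarm_size = as.integer(swarm_size), cg = cg,
                 epochs_particle = as.integer(epochs_particle),
                 epochs_gbest = as.integer(epochs_gbest),
                 image_size = as.integer(image_size),
                 layer_probs = layer_probs, seed = as.integer(seed),
                 w = w, c1 = c1, r_t1 = r_t1, r_t2 = r_t2),
            class = "pso_config")
}

layer_equal <- function(a, b) {
  !is.null(a) && !is.null(b) && identical(a$kind, b$kind) &&
    identical(a$params, b$params)
}

#' Initialize a particle swarm
#'
#' Draws `swarm_size` random feasible architectures; each particle's
#' personal best starts as itself (fitness unset). Deterministic given the
#' current RNG state.
#'
#' @param config a [pso_config()].
#' @param space a [search_space()].
#' @param rules a [constraint_set()].
#' @param input_shape image shape; defaults from `config$image_size`.
#' @return list of particles, each with `arch`, `pbest_arch`,
#'   `pbest_fitness`, `fitness`.
#' @export
init_swarm <- function(config, space, rules = constraint_set(),
                       input_shape = NULL) {
  if (is.null(input_shape)) {
    input_shape <- c(config$image_size, config$image_size, 3L)
  }
  lapply(seq_len(config$swarm_size), function(k) {
    arch <- random_architecture(space, rules, layer_probs = config$layer_probs,
                                input_shape = input_shape)
    list(arch = arch, pbest_arch = arch, pbest_fitness = -Inf,
         fitness = NA_real_)
  })
}

#' Compute a particle's block-copy velocity
#'
#' For each aligned slot (alignment from the input end): slots where the
#' particle already matches both its personal best and the global best are
#' kept; a differing slot is marked `copy_from_gbest` with probability
#' `cg`, else `copy_from_pbest`. Slots beyond the particle's current
#' length (up to the longer source) are append decisions drawn the same
#' way.
#'
#' @param particle a particle from [init_swarm()].
#' @param gbest the global-best [architecture()].
#' @param cg coefficient in `[0, 1]`.
#' @return character vector of operations (`"keep"`, `"copy_from_pbest"`,
#'   `"copy_from_gbest"`), class `pso_velocity`.
#' @export
compute_velocity <- function(particle, gbest, cg) {
  stopifnot(cg >= 0, cg <= 1)
  a <- particle$arch$layers
  pb <- particle$pbest_arch$layers
  gb <- gbest$layers
  L <- max(length(a), length(pb), length(gb))
  ops <- character(L)
  for (j in seq_len(L)) {
    aj <- if (j <= length(a)) a[[j]] else NULL
    pj <- if (j <= length(pb)) pb[[j]] else NULL
    gj <- if (j <= length(gb)) gb[[j]] else NULL
    matches_p <- is.null(pj) || layer_equal(aj, pj)
    matches_g <- is.null(gj) || layer_equal(aj, gj)
    if (!is.null(aj) && matches_p && matches_g) {
      ops[j] <- "keep"
    } else {
      ops[j] <- if (stats::runif(1) < cg) "copy_from_gbest" else "copy_from_pbest"
    }
  }
  structure(ops, class = "pso_velocity")
}

#' Apply a velocity to a particle
#'
#' Rewrites slots per operation (a copy from a source shorter than the slot
#' keeps the particle's own layer), truncates at the space's upper length
#' bound, and repairs the result into feasibility.
#'
#' @param particle a particle.
#' @param velocity a velocity from [compute_velocity()].
#' @param gbest the global-best [architecture()].
#' @param rules a [constraint_set()].
#' @param space a [search_space()] supplying the length bound `B_u`
#'   (optional; no truncation when missing).
#' @return the updated, feasible [architecture()].
#' @export
apply_velocity <- function(particle, velocity, gbest, rules = constraint_set(),
                           space = NULL) {
  a <- particle$arch$layers
  pb <- particle$pbest_arch$layers
  gb <- gbest$layers
  out <- list()
  for (j in seq_along(velocity)) {
    aj <- if (j <= length(a)) a[[j]] else NULL
    src <- switch(velocity[j],
      keep = aj,
      copy_from_pbest = if (j <= length(pb)) pb[[j]] else aj,
      copy_from_gbest = if (j <= length(gb)) gb[[j]] else aj,
      stop(sprintf("unknown velocity operation '%s'", velocity[j]))
    )
    if (!is.null(src)) out[[length(out) + 1L]] <- src
  }
  # cap growth at B_u without cutting into the particle's own length
  # (repair and BN/DO attachments can legitimately push past B_u)
  if (!is.null(space)) {
    cap <- max(space$B_u, length(a))
    if (length(out) > cap) out <- out[seq_len(cap)]
  }
  if (length(out) == 0L) out <- a  # degenerate: fall back to the particle
  # block copies may assemble two flattens (one from each parent): keep the
  # earliest so the at-most-one-F invariant holds before repair
  f_at <- which(vapply(out, `[[`, character(1), "kind") == "F")
  if (length(f_at) > 1L) out <- out[-f_at[-1]]
  repair_architecture(architecture(out, input_shape = particle$arch$input_shape),
                      rules)
}

# gbest tie-break: higher fitness, then fewer trainable parameters, then
# the earlier discovery (i.e. keep the incumbent)
better_candidate <- function(fit, arch, best_fit, best_arch, input_shape) {
  if (fit > best_fit) return(TRUE)
  if (fit < best_fit || is.null(best_arch)) return(fit > best_fit)
  pc_new <- tryCatch(count_parameters(arch, input_shape), error = function(e) Inf)
  pc_old <- tryCatch(count_parameters(best_arch, input_shape), error = function(e) Inf)
  pc_new < pc_old
}

#' Run the particle-swarm architecture search
#'
#' `runs` independent swarms of `swarm_size` particles evolve for
#' `iterations` iterations; iteration 1 evaluates the initial particles,
#' later iterations move each particle by [compute_velocity()] /
#' [apply_velocity()] before evaluating, so the training budget is exactly
#' `r * i * p` evaluator calls. Within a run the global-best fitness is
#' non-decreasing. Ties in fitness are broken toward the
#' smaller-parameter-count architecture, then the earlier discovery.
#' Deterministic given `config$seed` and a deterministic evaluator.
#'
#' @param config a [pso_config()].
#' @param evaluator function `f(architecture) -> fitness in [0, 1]`;
#'   evaluator errors score 0 and the search continues.
#' @param space a [search_space()] (default `pso_space("paper")`).
#' @param rules a [constraint_set()].
#' @param input_shape image shape; defaults from `config$image_size`.
#' @param final_evaluator optional function applied to the overall global
#'   best after the search (e.g. a longer retraining); its value is
#'   returned as `final`.
#' @param verbose print per-iteration progress.
#' @return list with `gbest_arch`, `gbest_fitness`, `history` (data frame:
#'   run, iteration, particle, fitness, gbest_fitness, notation),
#'   `per_run` (best fitness per run) and `final`.
#' @export
run_pso_search <- function(config, evaluator, space = pso_space("paper"),
                           rules = constraint_set(), input_shape = NULL,
                           final_evaluator = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pso_config"), is.function(evaluator))
  if (is.null(input_shape)) {
    input_shape <- c(config$image_size, config$image_size, 3L)
  }
  set.seed(config$seed)
  hist <- vector("list", config$runs * config$iterations * config$swarm_size)
  row <- 0L
  overall_fit <- -Inf; overall_arch <- NULL
  per_run <- numeric(config$runs)
  for (r in seq_len(config$runs)) {
    swarm <- init_swarm(config, space, rules, input_shape)
    gbest_fit <- -Inf; gbest_arch <- NULL
    for (it in seq_len(config$iterations)) {
      for (k in seq_len(config$swarm_size)) {
        part <- swarm[[k]]
        if (it > 1L) {
          vel <- compute_velocity(part, gbest_arch, config$cg)
          part$arch <- apply_velocity(part, vel, gbest_arch, rules, space)
        }
        fit <- tryCatch(evaluator(part$arch), error = function(e) {
          warning(sprintf("evaluator failed (run %d, iter %d, particle %d): %s",
                          r, it, k, conditionMessage(e)))
          0
        })
        fit <- max(0, min(1, fit))
        part$fitness <- fit
        if (fit > part$pbest_fitness) {
          part$pbest_fitness <- fit
          part$pbest_arch <- part$arch
        }
        if (better_candidate(fit, part$arch, gbest_fit, gbest_arch, input_shape)) {
          gbest_fit <- fit
          gbest_arch <- part$arch
        }
        swarm[[k]] <- part
        row <- row + 1L
        hist[[row]] <- data.frame(run = r, iteration = it, particle = k,
                                  fitness = fit, gbest_fitness = gbest_fit,
                                  notation = format_architecture(part$arch))
      }
      if (verbose) {
        message(sprintf("run %d iter %2d: gbest %.4f", r, it, gbest_fit))
      }
    }
    per_run[r] <- gbest_fit
    if (better_candidate(gbest_fit, gbest_arch, overall_fit, overall_arch,
                         input_shape)) {
      overall_fit <- gbest_fit
      overall_arch <- gbest_arch
    }
  }
  final <- if (!is.null(final_evaluator)) final_evaluator(overall_arch) else NULL
  list(gbest_arch = overall_arch, gbest_fitness = overall_fit,
       history = do.call(rbind, hist), per_run = per_run, final = final)
}
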