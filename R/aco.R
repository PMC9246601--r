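# Ant-colony-system architecture search. The layer-choice graph grows
# incrementally: a frontier node is expanded exactly once with every layer
# choice legal at that position, each new edge starting at pheromone tau0.
# Ants walk one layer per depth level under the ACS pseudo-random
# proportional rule; each chosen edge receives a local update toward tau0,
# and after every depth level the best ant's path receives a global update
# toward its fitness.

#' ACO search settings
#'
#' @param n_ants number of ants (the published profiles use 8 and 16).
#' @param depth maximum search depth (layers; the published profile is 32).
#' @param q0 ACS greediness in `[0, 1]`: probability of picking the
#'   maximum-pheromone edge outright.
#' @param rho evaporation rate in `(0, 1]`.
#' @param tau0 initial pheromone level (> 0).
#' @param image_size square image side in pixels (32 or 64 in the published
#'   profiles).
#' @param seed integer seed for the whole search.
#' @return an `aco_config` object.
#' @export
aco_config <- function(n_ants = 8L, depth = 32L, q0 = 0.5, rho = 0.1,
                       tau0 = 1.0, image_size = 32L, seed = 1L) {
  stopifnot(n_ants >= 1, depth >= 1, q0 >= 0, q0 <= 1,
            rho > 0, rho <= 1, tau0 > 0)
  structure(list(n_ants = as.integer(n_ants), depth = as.integer(depth),
                 q0 = q0, rho = rho, tau0 = tau0,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "aco_config")
}

new_graph_node <- function(layer = NULL) {
  e <- new.env(parent = emptyenv())
  e$layer <- layer
  e$children <- list()
  e$pher <- numeric(0)
  e$expanded <- FALSE
  e
}

# all (kind, parameter-permutation) choices legal after `path_kinds`:
# once a DE has been placed, only DE / BN / DO may follow (the flatten is
# supplied by the repair pass when the path becomes a network)
legal_layer_choices <- function(space, path_kinds) {
  vocab <- space$layer_vocab
  if (any(path_kinds == "DE")) {
    vocab <- intersect(vocab, c("DE", "BN", "DO"))
  }
  out <- list()
  for (k in vocab) {
    g <- space$grids[[k]]
    if (length(g) == 0L) {
      out[[length(out) + 1L]] <- layer_spec(k)
    } else {
      combos <- expand.grid(g, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(combos))) {
        out[[length(out) + 1L]] <-
          do.call(layer_spec, c(list(kind = k), as.list(combos[r, , drop = FALSE])))
      }
    }
  }
  out
}

expand_node <- function(node, space, path_kinds, tau0) {
  if (node$expanded) return(invisible(node))
  choices <- legal_layer_choices(space, path_kinds)
  node$children <- lapply(choices, new_graph_node)
  node$pher <- rep(tau0, length(choices))
  node$expanded <- TRUE
  invisible(node)
}

#' ACS edge selection
#'
#' With probability `q0` the child edge of maximal pheromone is chosen
#' (ties going to the lowest index); otherwise a child is sampled with
#' probability proportional to its pheromone.
#'
#' @param node a graph node with at least one child.
#' @param q0 greediness in `[0, 1]`.
#' @return the index of the chosen child edge.
#' @export
acs_select <- function(node, q0) {
  n <- length(node$children)
  if (n == 0L) stop("node has no children; expand before selecting")
  if (n == 1L) return(1L)
  if (stats::runif(1) < q0) {
    which.max(node$pher)
  } else {
    sample.int(n, 1L, prob = node$pher)
  }
}

#' ACS local pheromone update
#'
#' Evaporates a traversed edge toward the initial level:
#' `tau' = (1 - rho) * tau + rho * tau0`. Repeated local updates contract
#' the pheromone geometrically toward `tau0`, encouraging other ants to
#' explore new paths.
#'
#' @param tau current pheromone (> 0).
#' @param rho evaporation rate in `(0, 1]`.
#' @param tau0 initial pheromone.
#' @return updated pheromone value.
#' @export
local_pheromone_update <- function(tau, rho, tau0) {
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]")
  (1 - rho) * tau + rho * tau0
}

#' ACS global pheromone update
#'
#' Reinforces every edge on the best ant's path toward its fitness:
#' `tau' = (1 - rho) * tau + rho * f`. Edges off the path are untouched.
#'
#' @param ant an ant (list with `edges`, a list of `(node, index)` pairs,
#'   and evaluated `fitness` in `[0, 1]`).
#' @param rho evaporation rate in `(0, 1]`.
#' @return the ant, invisibly; the graph is updated in place.
#' @export
global_pheromone_update <- function(ant, rho) {
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]")
  if (is.null(ant$fitness) || is.na(ant$fitness)) {
    stop("ant has no evaluated fitness")
  }
  for (e in ant$edges) {
    node <- e$node
    node$pher[e$index] <- (1 - rho) * node$pher[e$index] + rho * ant$fitness
  }
  invisible(ant)
}

# an ant's traversed layers -> trainable architecture (repair supplies the
# flatten + dense tail when the path lacks them)
ant_to_architecture <- function(layers, input_shape, rules) {
  arch <- architecture(layers, input_shape = input_shape)
  repair_architecture(arch, rules)
}

#' Run the ant-colony architecture search
#'
#' Per depth level, every ant extends its path by one layer (ACS selection
#' + local update), each ant's path is repaired into a trainable
#' architecture and evaluated, and the level's best ant deposits a global
#' update. The training budget is exactly `n_ants * depth` evaluator
#' calls. Deterministic given `config$seed` and a deterministic evaluator.
#'
#' @param config an [aco_config()].
#' @param evaluator function `f(architecture) -> fitness in [0, 1]`; an
#'   evaluator error scores the candidate 0 and the search continues.
#' @param space a [search_space()] (default [aco_space()]).
#' @param rules a [constraint_set()].
#' @param input_shape image shape; defaults to
#'   `(image_size, image_size, 3)` from the config.
#' @param verbose print per-depth progress.
#' @return list with `best_arch`, `best_fitness`, `history` (data frame:
#'   depth, ant, fitness, best_so_far, notation) and the pheromone `graph`
#'   root.
#' @export
run_aco_search <- function(config, evaluator, space = aco_space(),
                           rules = constraint_set(),
                           input_shape = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "aco_config"), is.function(evaluator))
  if (is.null(input_shape)) {
    input_shape <- c(config$image_size, config$image_size, 3L)
  }
  set.seed(config$seed)
  root <- new_graph_node()
  ants <- lapply(seq_len(config$n_ants), function(a) {
    list(node = root, layers = list(), edges = list(), fitness = NA_real_)
  })
  hist <- vector("list", config$n_ants * config$depth)
  best_fit <- -Inf
  best_arch <- NULL
  row <- 0L
  for (d in seq_len(config$depth)) {
    for (a in seq_len(config$n_ants)) {
      ant <- ants[[a]]
      path_kinds <- vapply(ant$layers, `[[`, character(1), "kind")
      expand_node(ant$node, space, path_kinds, config$tau0)
      idx <- acs_select(ant$node, config$q0)
      ant$node$pher[idx] <- local_pheromone_update(ant$node$pher[idx],
                                                   config$rho, config$tau0)
      chosen <- ant$node$children[[idx]]
      ant$edges[[length(ant$edges) + 1L]] <- list(node = ant$node, index = idx)
      ant$layers[[length(ant$layers) + 1L]] <- chosen$layer
      ant$node <- chosen
      ants[[a]] <- ant
    }
    # evaluate all ants at this depth
    level_fit <- numeric(config$n_ants)
    for (a in seq_len(config$n_ants)) {
      arch <- ant_to_architecture(ants[[a]]$layers, input_shape, rules)
      fit <- tryCatch(evaluator(arch), error = function(e) {
        warning(sprintf("evaluator failed at depth %d ant %d: %s",
                        d, a, conditionMessage(e)))
        0
      })
      fit <- max(0, min(1, fit))
      ants[[a]]$fitness <- fit
      level_fit[a] <- fit
      if (fit > best_fit) {
        best_fit <- fit
        best_arch <- arch
      }
      row <- row + 1L
      hist[[row]] <- data.frame(depth = d, ant = a, fitness = fit,
                                best_so_far = best_fit,
                                notation = format_architecture(arch))
    }
    global_pheromone_update(ants[[which.max(level_fit)]], config$rho)
    if (verbose) {
      message(sprintf("depth %2d: best %.4f (overall %.4f)",
                      d, max(level_fit), best_fit))
    }
  }
  list(best_arch = best_arch, best_fitness = best_fit,
       history = do.call(rbind, hist), graph = root)
}
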