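# Search-space definition and the cardinality calculus. A space is a layer
# vocabulary with per-kind parameter grids (whose sizes are the permutation
# counts P_i), plus length bounds [B_l, B_u].

#' Define a layer search space
#'
#' @param kinds named list: names are layer kinds (subset of
#'   [LAYER_KINDS]), values are named lists of parameter grids (vectors of
#'   allowed values). Parameterless kinds take `list()`.
#' @param B_l,B_u minimum / maximum number of layers drawn for a candidate.
#' @param bn_prob probability that a sampled C2D/DE layer is followed by a
#'   BN layer during random generation (default 1: layer outputs are batch
#'   normalized, the published initialization setting).
#' @param do_prob probability that a sampled C2D/DE block is followed by a
#'   DO layer (rate `do_rate`) during random generation.
#' @param do_rate dropout rate attached by the generator.
#' @return a `search_space` with fields `layer_vocab`, `grids`,
#'   `perm_counts` (product of grid sizes per kind), `t_l` (vocabulary
#'   cardinality), `B_l`, `B_u`.
#' @export
search_space <- function(kinds, B_l, B_u, bn_prob = 1.0, do_prob = 0.3,
                         do_rate = 0.5) {
  stopifnot(is.list(kinds), length(kinds) >= 1L)
  vocab <- names(kinds)
  if (is.null(vocab) || !all(vocab %in% LAYER_KINDS)) {
    stop("kinds must be a named list over the layer vocabulary")
  }
  if (!(B_l >= 1 && B_l <= B_u)) stop("need 1 <= B_l <= B_u")
  perm <- vapply(kinds, function(g) {
    if (length(g) == 0L) 1 else prod(vapply(g, length, integer(1)))
  }, numeric(1))
  structure(list(layer_vocab = vocab, grids = kinds, perm_counts = perm,
                 t_l = length(vocab), B_l = as.integer(B_l),
                 B_u = as.integer(B_u), bn_prob = bn_prob,
                 do_prob = do_prob, do_rate = do_rate),
            class = "search_space")
}

#' Ant-colony search space
#'
#' Vocabulary `[C2D, MP, BN, DE]` with permutation counts `[9, 2, 1, 4]`:
#' C2D filters {32,64,128} x kernel {1,3,5}; MP pool {2,3}; BN
#' parameterless; DE units {64,128,256,512}.
#'
#' @param B_l,B_u length bounds (depth-bounded search; defaults 1 and 32).
#' @return a [search_space()].
#' @export
aco_space <- function(B_l = 1L, B_u = 32L) {
  search_space(
    kinds = list(
      C2D = list(filters = c(32L, 64L, 128L), kernel = c(1L, 3L, 5L)),
      MP  = list(pool = c(2L, 3L)),
      BN  = list(),
      DE  = list(units = c(64L, 128L, 256L, 512L))
    ),
    B_l = B_l, B_u = B_u
  )
}

#' Particle-swarm search space
#'
#' The `"paper"` profile uses the published initialization ranges: conv
#' outputs 3-256, kernel 3/5/7, dense units 1-300, bounds B_l = 3 and
#' B_u = 20, vocabulary `[C2D, MP, AP, DE]` (t_l = 4). The `"desk"` profile
#' is the package's scaled-down study space for CPU-sized experiments:
#' conv filters {4,8,16}, kernel 3, dense units {8,16,32,64}, B_u = 8.
#'
#' @param profile `"paper"` or `"desk"`.
#' @return a [search_space()].
#' @export
pso_space <- function(profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    search_space(
      kinds = list(
        C2D = list(filters = 3:256, kernel = c(3L, 5L, 7L)),
        MP  = list(pool = 2L),
        AP  = list(pool = 2L),
        DE  = list(units = 1:300)
      ),
      B_l = 3L, B_u = 20L
    )
  } else {
    search_space(
      kinds = list(
        C2D = list(filters = c(4L, 8L, 16L), kernel = 3L),
        MP  = list(pool = 2L),
        AP  = list(pool = 2L),
        DE  = list(units = c(8L, 16L, 32L, 64L))
      ),
      B_l = 3L, B_u = 8L
    )
  }
}

#' Search-space cardinality (exact)
#'
#' Number of layer-kind sequences of bounded length over a vocabulary of
#' size `t_l`: the sum of `t_l^b` for `b` from `B_l` to `B_u`. Computed in
#' exact arbitrary-precision arithmetic ([bigint()]); the value for
#' `(4, 3, 20)` already exceeds 1.4 trillion.
#'
#' @param t_l vocabulary cardinality (>= 1).
#' @param B_l,B_u length bounds, `1 <= B_l <= B_u`.
#' @return a [bigint()].
#' @examples
#' format(count_search_space(4, 3, 20))
#' @export
count_search_space <- function(t_l, B_l, B_u) {
  if (!(t_l >= 1)) stop("t_l must be >= 1")
  if (!(B_l >= 1 && B_l <= B_u)) stop("need 1 <= B_l <= B_u")
  total <- bigint(0)
  for (b in seq(B_l, B_u)) total <- big_add(total, big_pow(bigint(t_l), b))
  total
}

#' Parameterized search-space size for a fixed layer sequence
#'
#' Two readings of the per-kind permutation calculus over counts `P` and
#' layer multiplicities `n`:
#' `as_printed` returns the literal sum of powers `sum_i P_i^(n_i)`;
#' `combinatorial` returns the product of powers `prod_i P_i^(n_i)` — the
#' number of distinct parameterizations of a fixed sequence. Both are kept
#' because the two readings differ and each answers a different question
#' (see the methods vignette).
#'
#' @param P integer vector of per-kind parameter permutation counts.
#' @param n integer vector of per-kind layer multiplicities, same length.
#' @param mode `"as_printed"` or `"combinatorial"`.
#' @return a [bigint()].
#' @export
count_parameterized_space <- function(P, n, mode = c("as_printed", "combinatorial")) {
  mode <- match.arg(mode)
  if (length(P) != length(n)) stop("P and n must have the same length")
  if (any(P < 1) || any(n < 0)) stop("need all P >= 1 and n >= 0")
  if (mode == "as_printed") {
    out <- bigint(0)
    for (i in seq_along(P)) out <- big_add(out, big_pow(bigint(P[i]), n[i]))
  } else {
    out <- bigint(1)
    for (i in seq_along(P)) out <- big_mul(out, big_pow(bigint(P[i]), n[i]))
  }
  out
}

#' Models trained by an ant-colony search
#'
#' Each ant is evaluated once per depth level, so the training budget is
#' `ants * depth`.
#'
#' @param ants,depth strictly positive integers.
#' @return integer count.
#' @export
count_models_aco <- function(ants, depth) {
  if (!(ants >= 1 && depth >= 1)) stop("ants and depth must be >= 1")
  as.numeric(ants) * as.numeric(depth)
}

#' Models trained by a particle-swarm search
#'
#' Every particle update counts as one new model, so the budget over `r`
#' runs of `i` iterations with swarm size `p` is `r * i * p`.
#'
#' @param r,i,p strictly positive integers.
#' @return integer count.
#' @export
count_models_pso <- function(r, i, p) {
  if (!(r >= 1 && i >= 1 && p >= 1)) stop("r, i and p must be >= 1")
  as.numeric(r) * as.numeric(i) * as.numeric(p)
}

# Sample the "trunk" layer kinds (conv / pooling / dense) i.i.d. from the
# configured probabilities; pooling resolves to MP or AP by a fair coin when
# both are in the vocabulary.
sample_trunk_kinds <- function(b, space,
                               layer_probs = c(conv = 0.7, pool = 0.15, dense = 0.15)) {
  groups <- c("conv", "pool", "dense")
  if (!all(groups %in% names(layer_probs))) {
    stop("layer_probs must name conv, pool and dense")
  }
  p <- layer_probs[groups]
  if (abs(sum(p) - 1) > 1e-8) stop("layer probabilities must sum to 1")
  draw <- sample(groups, b, replace = TRUE, prob = p)
  vapply(draw, function(g) {
    switch(g,
      conv = "C2D",
      dense = "DE",
      pool = {
        pools <- intersect(c("MP", "AP"), space$layer_vocab)
        if (length(pools) == 0L) stop("space has no pooling kind")
        if (length(pools) == 1L) pools else sample(pools, 1L)
      })
  }, character(1), USE.NAMES = FALSE)
}

# uniform draw of one concrete parameterization of `kind` from the space grid
sample_layer_params <- function(kind, space) {
  g <- space$grids[[kind]]
  if (is.null(g) || length(g) == 0L) return(list())
  lapply(g, function(vals) if (length(vals) == 1L) vals else sample(vals, 1L))
}

#' Draw a random feasible architecture
#'
#' Samples a layer count `b` uniformly in `[B_l, B_u]`, draws `b` trunk
#' layers i.i.d. from `layer_probs` (convolution 0.7, pooling 0.15, dense
#' 0.15 by default), with parameters uniform on the space grids. Dense
#' layers are stably moved after the convolutional trunk, a flatten is
#' inserted before the first dense layer, and BN / DO layers are attached
#' after conv/dense layers with probabilities `space$bn_prob` /
#' `space$do_prob`. The result always passes [validate_architecture()].
#'
#' @param space a [search_space()].
#' @param rules a [constraint_set()].
#' @param layer_probs named probabilities for `conv`, `pool`, `dense`.
#' @param input_shape image shape `(H, W, C)`.
#' @param seed optional integer; when given the draw is deterministic.
#' @return an [architecture()].
#' @export
random_architecture <- function(space, rules = constraint_set(),
                                layer_probs = c(conv = 0.7, pool = 0.15, dense = 0.15),
                                input_shape = c(64L, 64L, 3L), seed = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (!is.null(seed)) set.seed(seed)
  if (space$B_u < 1L) stop("infeasible bounds")
  b <- if (space$B_l == space$B_u) space$B_l else
    sample(seq(space$B_l, space$B_u), 1L)
  kinds <- sample_trunk_kinds(b, space, layer_probs)
  # stable partition: conv/pool trunk first, dense tail after — keeps the
  # sampled kind multiset intact while satisfying the ordering rules
  kinds <- c(kinds[kinds != "DE"], kinds[kinds == "DE"])
  layers <- list()
  for (k in kinds) {
    layers[[length(layers) + 1L]] <-
      do.call(layer_spec, c(list(kind = k), sample_layer_params(k, space)))
    if (k %in% c("C2D", "DE")) {
      if (stats::runif(1) < space$bn_prob) {
        layers[[length(layers) + 1L]] <- layer_spec("BN")
      }
      if (stats::runif(1) < space$do_prob) {
        layers[[length(layers) + 1L]] <- layer_spec("DO", rate = space$do_rate)
      }
    }
  }
  arch <- architecture(layers, input_shape = input_shape)
  repair_architecture(arch, rules)
}
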