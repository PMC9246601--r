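# Shared fixtures: brute-force oracles and scaled-down datasets, all built
# in code at test time.

# exhaustive count of layer-kind sequences with lengths in [B_l, B_u] over
# a vocabulary of t_l symbols (independent oracle for the closed form)
enumerate_sequences <- function(t_l, B_l, B_u) {
  total <- 0
  for (b in B_l:B_u) {
    total <- total + nrow(expand.grid(rep(list(seq_len(t_l)), b)))
  }
  total
}

# pairwise-concordance AUC oracle: fraction of positive-negative pairs
# ranked correctly, ties counted 0.5
auc_pairs_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (s in sp) tot <- tot + sum(s > sn) + 0.5 * sum(s == sn)
  tot / (length(sp) * length(sn))
}

# direct po/pe kappa oracle
kappa_oracle <- function(cm) {
  tot <- sum(cm)
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  (po - pe) / (1 - pe)
}

# evaluator wrapper that counts calls (for budget assertions)
counting_evaluator <- function(f) {
  calls <- 0L
  list(
    fn = function(arch) {
      calls <<- calls + 1L
      f(arch)
    },
    calls = function() calls
  )
}

# a tiny trainable dataset for fast end-to-end checks: balanced classes,
# 16 x 16 pixels, low noise
tiny_dataset <- function(seed = 1L, n = 150L) {
  generate_dataset(synth_spec(n, image_size = 16L, noise_sigma = 0.02,
                              class_proportions = "uniform", seed = seed))
}

# the desk-scale trainer profile used across search-quality tests
desk_trainer <- function(epochs = 1L, seed = 1L) {
  trainer_spec(epochs = epochs, batch_size = 8L, image_size = 32L,
               lr = 2e-3, seed = seed)
}
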