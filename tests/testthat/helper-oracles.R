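# Independent oracles and tiny fixtures used across test files.

# Exact two-sided binomial p by full outcome enumeration
# (minimum-likelihood convention): sum of P(X = j) over all j whose
# probability does not exceed that of the observed k.
binom_p_enum <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-10)])
}

# AUC by exhaustive pairwise concordance (ties get half credit).
auc_enum <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Deterministic noiseless profile: responses land exactly on targets.
noiseless_profile <- function(...) {
  args <- list(heading_noise_sd = 0, thigmotaxis_weight = 0,
               landmark_approach_weight = 0, recall_noise_sd = 0,
               center_attraction = 0, landmark_attraction = 0,
               between_subject_cv = 0)
  do.call(behavior_profile, utils::modifyList(args, list(...)))
}

# A small fully deterministic scored cohort for model plumbing tests.
tiny_scores <- function(n_per_group = 6, seed = 101,
                        spec = cohort_spec(n_per_group,
                                           seed = seed,
                                           simulate_paths = FALSE)) {
  score_cohort(simulate_cohort(spec))
}
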