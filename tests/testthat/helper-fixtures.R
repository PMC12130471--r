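# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_config <- function(...) {
  simulation_config(n_healthy = 6, n_patients = 6, cells_per_donor = 400,
                    seed = 42, ...)
}

tiny_cohort <- function() cached("tiny_cohort", function() simulate_cohort(tiny_config()))

# Full-scale study-condition cohort (50 + 50 donors, 5000 cells/donor),
# shared by the parameter-recovery and trajectory checks.
study_cohort <- function() cached("study_cohort", function() {
  simulate_cohort(simulation_config(seed = 101))
})

study_profiles <- function() cached("study_profiles", function() {
  co <- study_cohort()
  thr <- derive_marker_thresholds(co$cell_table, seed = 1)
  subset_frequencies(classify_subsets(co$cell_table, thr))
})

tiny_gated <- function() cached("tiny_gated", function() {
  co <- tiny_cohort()
  thr <- derive_marker_thresholds(co$cell_table, seed = 1)
  classify_subsets(co$cell_table, thr)
})

# --- independent oracles ----------------------------------------------------

# Shannon entropy by direct summation (independent of the implementation).
shannon_oracle <- function(sizes) {
  total <- sum(sizes)
  acc <- 0
  for (s in sizes) acc <- acc - (s / total) * log(s / total)
  acc
}

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins, probabilities from choose() directly.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  prob_a <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  }
  p_obs <- prob_a(tab[1, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob_a, numeric(1))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by exhaustive pairwise comparison (ties count one half), in the
# "lower score predicts the event" orientation.
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p < q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# All partitions of n into at most s positive parts (clone-size vectors).
partitions_up_to <- function(n, s, max_part = n) {
  if (n == 0) return(list(integer(0)))
  if (s == 0) return(list())
  out <- list()
  for (first in seq_len(min(n, max_part))) {
    for (rest in partitions_up_to(n - first, s - 1, first)) {
      out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}
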