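# Independent brute-force oracles used across tests. These deliberately
# avoid the package's dynamic-programming code path: scoring goes through
# the exported per-element functions (local_evidence, transition_potential)
# and inference enumerates all K^T labelings.

# all contiguous, centre-containing subsets of a (2m-1)-wide offset window
# with length >= m, found by filtering every subset of the window
brute_force_patterns <- function(m) {
  offsets <- -(m - 1):(m - 1)
  n <- length(offsets)
  keep <- list()
  for (mask in seq_len(2^n) - 1L) {
    members <- offsets[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L]
    if (length(members) < m) next
    if (!0 %in% members) next
    if (length(members) > 1 && any(diff(members) != 1L)) next
    keep[[length(keep) + 1L]] <- range(members)
  }
  keep
}

# per-locus local evidence matrix built one call at a time from the exported
# single-window function, truncating the window at sequence ends
oracle_evidence <- function(values, model) {
  T_ <- length(values)
  half <- model$m - 1L
  L <- matrix(NA_real_, T_, model$K)
  for (t in seq_len(T_)) {
    idx <- max(1L, t - half):min(T_, t + half)
    for (k in seq_len(model$K)) {
      L[t, k] <- local_evidence(
        values[idx], model$states[k], model,
        offsets = idx - t
      )
    }
  }
  L
}

# exhaustive enumeration over all K^T labelings of the chain objective:
# sum_t local_evidence + sum_{t>1} transition_potential. The transition term
# only depends on whether the state changes (the change mass is split
# uniformly), so per gap it is evaluated once for "same" and once for
# "different" through the exported function.
oracle_chain <- function(values, pos, model) {
  T_ <- length(values)
  K <- model$K
  L <- oracle_evidence(values, model)
  d_mb <- diff(pos) / 1e6
  labelings <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  scores <- numeric(nrow(labelings))
  for (t in seq_len(T_)) {
    scores <- scores + L[(labelings[, t] - 1L) * T_ + t]
  }
  if (T_ > 1) {
    for (t in 2:T_) {
      same <- transition_potential(
        model$states[1], model$states[1], d_mb[t - 1], model
      )
      diff_ <- transition_potential(
        model$states[1], model$states[2], d_mb[t - 1], model
      )
      scores <- scores +
        ifelse(labelings[, t - 1] == labelings[, t], same, diff_)
    }
  }
  log_Z <- log(sum(exp(scores - max(scores)))) + max(scores)
  marginals <- matrix(0, T_, K)
  w <- exp(scores - log_Z)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) {
      marginals[t, k] <- sum(w[labelings[, t] == k])
    }
  }
  list(
    best_score = max(scores),
    log_Z = log_Z,
    best_path_probability = exp(max(scores) - log_Z),
    marginals = marginals
  )
}

# a random single-chromosome probe tibble
random_probes <- function(T_, spacing_bp = 10000, sd = 0.3) {
  tibble::tibble(
    marker = sprintf("m%03d", seq_len(T_)),
    chrom = "chr1",
    pos = cumsum(sample(1:3, T_, replace = TRUE)) * spacing_bp,
    log2ratio = rnorm(T_, 0, sd)
  )
}

test_model_3k <- function(sds = 0.2) {
  crp_model(states = 1:3, means = c(-0.45, 0, 0.38), sds = sds, m = 4)
}
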