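#' Pattern-based local evidence for one marker's copy-number state
#'
#' Scores how strongly the observations around a marker support a given
#' copy-number state at that marker. Every candidate CNA pattern (a
#' contiguous run of at least `m` window positions containing the centre,
#' see [enumerate_patterns()]) assigns its member observations to the
#' centre's state; the pattern's term is the joint Gaussian log-likelihood of
#' those observations under that state. Because patterns contain between `m`
#' and `2m - 1` observations the raw terms are on different scales, so each
#' is rescaled to the geometric mean of its likelihood factors -- the mean
#' log-likelihood over the pattern's offsets. The local evidence is the
#' maximum rescaled term: the pattern matching the true underlying run
#' structure scores highest.
#'
#' Near sequence ends, patterns are intersected with the offsets actually
#' available; the centre observation is always present.
#'
#' @param window Numeric vector of observations at consecutive offsets around
#'   the centre marker.
#' @param state Copy-number state to score (in `model$states`).
#' @param model A [crp_model()].
#' @param offsets Integer offsets (relative to the centre) of the `window`
#'   entries; must contain 0. Defaults to the full symmetric window
#'   `-(m-1):(m-1)`, requiring `length(window) == 2m - 1`.
#'
#' @return A single log-evidence value on the per-observation scale.
#' @examples
#' mod <- crp_model_3state()
#' # a constant window scores the plain emission log-likelihood
#' local_evidence(rep(0, 7), 2, mod)
#' @export
local_evidence <- function(window, state, model, offsets = NULL) {
  if (length(window) == 0L) abort("`window` must contain observations.")
  half <- model$m - 1L
  if (is.null(offsets)) {
    if (length(window) != 2L * half + 1L) {
      abort(sprintf(
        "With default offsets, `window` must have %d observations.",
        2L * half + 1L
      ))
    }
    offsets <- (-half):half
  }
  offsets <- as.integer(offsets)
  if (length(offsets) != length(window)) {
    abort("`offsets` must match `window` in length.")
  }
  if (!0L %in% offsets) abort("`offsets` must contain the centre (0).")
  ll <- emission_loglik(window, state, model)
  terms <- vapply(
    seq_len(nrow(model$patterns)),
    function(p) {
      keep <- offsets >= model$patterns$from[p] & offsets <= model$patterns$to[p]
      if (!any(keep)) {
        return(-Inf)
      }
      mean(ll[keep])
    },
    numeric(1)
  )
  max(terms)
}

# T x K local-evidence matrix, vectorized over loci via cumulative sums.
# Patterns are contiguous offset runs, so each term is a clipped rolling mean
# of the emission log-likelihood column.
local_evidence_matrix <- function(values, model) {
  T_ <- length(values)
  E <- emission_loglik_matrix(values, model)
  L <- matrix(-Inf, T_, model$K)
  t_idx <- seq_len(T_)
  for (k in seq_len(model$K)) {
    cs <- c(0, cumsum(E[, k]))
    best <- rep(-Inf, T_)
    for (p in seq_len(nrow(model$patterns))) {
      lo <- pmax(t_idx + model$patterns$from[p], 1L)
      hi <- pmin(t_idx + model$patterns$to[p], T_)
      term <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      best <- pmax(best, term)
    }
    L[, k] <- best
  }
  L
}
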