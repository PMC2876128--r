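#' Inter-marker state-change probability from Haldane's map function
#'
#' Maps the physical distance between two consecutive markers to the
#' probability that the copy-number state changes between them, via Haldane's
#' map function `theta = 0.5 * (1 - exp(-2 * rho * d))` with `rho` the
#' genetic map rate in Morgan per megabase. Nearby markers are therefore very
#' likely to share a state while distant markers are nearly independent
#' (theta approaches 1/2). The result is clamped to
#' `[theta_floor, 0.5)` so log-potentials stay finite.
#'
#' @param d_mb Non-negative distance(s) between consecutive markers, in Mb.
#' @param morgans_per_mb Map rate rho (> 0), Morgan/Mb.
#' @param theta_floor Lower clamp in (0, 0.5).
#'
#' @return Numeric vector of change probabilities in `[theta_floor, 0.5)`.
#' @examples
#' transition_theta(0) # theta_floor
#' transition_theta(100) # (1 - exp(-2)) / 2 ~= 0.432
#' @export
transition_theta <- function(d_mb, morgans_per_mb = 0.01, theta_floor = 1e-10) {
  if (any(!is.finite(d_mb)) || any(d_mb < 0)) {
    abort("`d_mb` must be finite and non-negative.")
  }
  theta <- 0.5 * (1 - exp(-2 * morgans_per_mb * d_mb))
  pmin(pmax(theta, theta_floor), 0.5 - .Machine$double.eps)
}

#' Log transition potential between copy-number states of adjacent markers
#'
#' Staying in the same state scores `log(1 - theta)`; changing state scores
#' `log(theta) - log(K - 1)`, i.e. the change probability is split uniformly
#' over the `K - 1` alternative states, so for a fixed previous state the
#' exponentiated potentials over current states sum to one.
#'
#' @param y_prev,y_curr Copy-number states (members of `model$states`).
#' @param d_mb Distance between the two markers in Mb.
#' @param model A [crp_model()].
#'
#' @return Log-potential (single numeric; vectorized over states of equal
#'   length).
#' @examples
#' m <- crp_model()
#' sum(exp(sapply(0:4, function(y) transition_potential(2, y, 0.01, m)))) # 1
#' @export
transition_potential <- function(y_prev, y_curr, d_mb, model) {
  i <- state_index(y_prev, model)
  j <- state_index(y_curr, model)
  theta <- transition_theta(
    d_mb, model$transition$morgans_per_mb, model$transition$theta_floor
  )
  ifelse(i == j, log1p(-theta), log(theta) - log(model$K - 1))
}

# per-step log transition matrix [from, to] for one inter-marker gap
transition_logmat <- function(theta, K) {
  mat <- matrix(log(theta) - log(K - 1), K, K)
  diag(mat) <- log1p(-theta)
  mat
}

#' Gaussian emission log-likelihood of a log2-ratio under a copy-number state
#'
#' Each copy-number state `i` emits log2-ratios as `N(mu_i, sigma_i^2)`.
#'
#' @param x Observed log2-ratio(s).
#' @param state A copy-number state in `model$states`.
#' @param model A [crp_model()].
#'
#' @return Log-density values, same length as `x`.
#' @examples
#' emission_loglik(0, 2, crp_model()) # peak density at the state mean
#' @export
emission_loglik <- function(x, state, model) {
  idx <- state_index(state, model)
  dnorm(x, model$emission$mean[idx], model$emission$sd[idx], log = TRUE)
}

# T x K matrix of emission log-likelihoods for all states
emission_loglik_matrix <- function(values, model) {
  out <- vapply(
    seq_len(model$K),
    function(k) {
      dnorm(values, model$emission$mean[k], model$emission$sd[k], log = TRUE)
    },
    numeric(length(values))
  )
  matrix(out, nrow = length(values), ncol = model$K)
}
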