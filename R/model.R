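#' Construct a conditional random pattern (CRP) model
#'
#' Bundles the state space (the copy numbers considered), Gaussian emission
#' parameters per state, the distance-dependent transition parameters, and the
#' candidate CNA pattern set for the chosen minimum run length `m`.
#'
#' The default five-state model covers copy numbers 0--4. The means for one
#' and three copies (-0.45 and 0.38) are the empirical log2-ratio shifts of
#' single-copy deletions and three-copy amplifications on compressed
#' SNP-array data; the means for zero and four copies (-2.0 and 0.8) are
#' extrapolations beyond what arrays measure reliably and should be
#' overridden when calibration data exist. A three-state loss/normal/gain
#' configuration is available via [crp_model_3state()].
#'
#' @param states Integer copy numbers, strictly increasing, at least two.
#' @param means Named or positional numeric vector of per-state emission
#'   means (log2-ratio units), non-decreasing in copy number. May also be a
#'   data frame with columns `state`, `mean`, `sd` (as returned by
#'   [fit_emission_params()]), in which case `sds` is ignored.
#' @param sds Per-state emission standard deviations (> 0); recycled if
#'   length 1.
#' @param m Minimum CNA run length in markers (window is `2m - 1` wide).
#' @param morgans_per_mb Genetic map rate rho used in Haldane's map function,
#'   Morgan per megabase. Default 0.01 (the 1 cM/Mb genome average).
#' @param theta_floor Lower clamp for the inter-marker change probability
#'   theta, keeping transition log-potentials finite at zero distance.
#' @param normal_state Copy number treated as "normal" (non-aberrant);
#'   defaults to 2 when present, else the middle state.
#'
#' @return An object of class `crp_model`: a list with elements `states`,
#'   `emission` (tibble `state`, `mean`, `sd`), `transition` (list
#'   `morgans_per_mb`, `theta_floor`), `patterns` (see
#'   [enumerate_patterns()]), `m`, `K`, and `normal_state`.
#'
#' @examples
#' crp_model()
#' crp_model_3state()
#' @export
crp_model <- function(states = 0:4,
                      means = c(-2.0, -0.45, 0, 0.38, 0.8),
                      sds = 0.25,
                      m = 4,
                      morgans_per_mb = 0.01,
                      theta_floor = 1e-10,
                      normal_state = NULL) {
  states <- as.integer(states)
  K <- length(states)
  if (K < 2L) abort("At least two copy-number states are required.")
  if (any(diff(states) <= 0L)) abort("`states` must be strictly increasing.")
  if (is.data.frame(means)) {
    emission <- as_tibble(means)
    if (!all(c("state", "mean", "sd") %in% names(emission))) {
      abort("An emission data frame needs columns `state`, `mean`, `sd`.")
    }
    idx <- match(states, emission$state)
    if (anyNA(idx)) {
      abort(sprintf(
        "Emission parameters missing for state(s): %s.",
        paste(states[is.na(idx)], collapse = ", ")
      ))
    }
    emission <- emission[idx, c("state", "mean", "sd")]
  } else {
    if (length(means) != K) abort("`means` must have one value per state.")
    sds <- rep_len(as.numeric(sds), K)
    emission <- tibble(state = states, mean = as.numeric(means), sd = sds)
  }
  if (any(!is.finite(emission$mean)) || any(!is.finite(emission$sd))) {
    abort("Emission means and sds must be finite.")
  }
  if (any(emission$sd <= 0)) abort("Emission sds must be positive.")
  if (any(diff(emission$mean) < 0)) {
    abort("Emission means must be non-decreasing in copy number.")
  }
  if (!is.numeric(morgans_per_mb) || morgans_per_mb <= 0) {
    abort("`morgans_per_mb` must be positive.")
  }
  if (!is.numeric(theta_floor) || theta_floor <= 0 || theta_floor >= 0.5) {
    abort("`theta_floor` must lie in (0, 0.5).")
  }
  if (is.null(normal_state)) {
    normal_state <- if (2L %in% states) 2L else states[ceiling(K / 2)]
  }
  normal_state <- as.integer(normal_state)
  if (!normal_state %in% states) abort("`normal_state` must be one of `states`.")
  structure(
    list(
      states = states,
      emission = emission,
      transition = list(
        morgans_per_mb = as.numeric(morgans_per_mb),
        theta_floor = as.numeric(theta_floor)
      ),
      patterns = enumerate_patterns(m),
      m = as.integer(m),
      K = K,
      normal_state = normal_state
    ),
    class = "crp_model"
  )
}

#' @rdname crp_model
#' @param ... Passed on to [crp_model()].
#' @details `crp_model_3state()` is the loss/normal/gain configuration with
#'   means `c(-0.27, 0, 0.27)` and common sd 0.1, the setting used for
#'   array-CGH-style single-chromosome data.
#' @export
crp_model_3state <- function(means = c(-0.27, 0, 0.27), sds = 0.1, ...) {
  crp_model(states = 1:3, means = means, sds = sds, ...)
}

#' @export
print.crp_model <- function(x, ...) {
  cat(sprintf(
    "<crp_model> K = %d states {%s}, m = %d (%d patterns), rho = %g Morgan/Mb\n",
    x$K, paste(x$states, collapse = ", "), x$m, nrow(x$patterns),
    x$transition$morgans_per_mb
  ))
  cat("emission:\n")
  print(x$emission)
  invisible(x)
}

# index of each state in the model's state vector; errors on unknown states
state_index <- function(state, model) {
  idx <- match(state, model$states)
  if (anyNA(idx)) {
    abort(sprintf(
      "Unknown copy-number state(s): %s.",
      paste(unique(state[is.na(idx)]), collapse = ", ")
    ))
  }
  idx
}

# preference order for Viterbi tie-breaking: closest to the normal state,
# lower copy number first among equidistant states
state_preference <- function(model) {
  order(abs(model$states - model$normal_state), model$states)
}
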