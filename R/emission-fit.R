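#' Estimate Gaussian emission parameters from labelled regions
#'
#' Emission means and standard deviations are estimated from markers whose
#' copy number is already known -- typically whole-chromosome monosomy and
#' trisomy regions confirmed by cytogenetics. Per state present in the
#' labels, the mean is the sample mean of its log2-ratios and the sd the
#' sample standard deviation (n - 1 denominator). States without labelled
#' markers keep their `fallback` values.
#'
#' @param labelled A data frame with columns `log2ratio` (observed values)
#'   and `copy_number` (known state per marker).
#' @param states Integer copy numbers the returned table must cover; default
#'   the states appearing in `labelled` plus those in `fallback`.
#' @param fallback Optional emission tibble (`state`, `mean`, `sd`) -- e.g.
#'   `crp_model()$emission` -- supplying parameters for unlabelled states.
#'
#' @return An emission tibble (`state`, `mean`, `sd`) suitable for
#'   [crp_model()]'s `means` argument. A state with exactly one labelled
#'   marker is an error (its sd is undefined); fitted means that are not
#'   non-decreasing in copy number trigger a warning, since downstream
#'   model construction will refuse them.
#'
#' @examples
#' known <- tibble::tibble(
#'   log2ratio = c(0.3, 0.5), copy_number = c(2L, 2L)
#' )
#' fit_emission_params(known) # mu = 0.4, sd ~= 0.141
#' @export
fit_emission_params <- function(labelled, states = NULL, fallback = NULL) {
  if (!is.data.frame(labelled) ||
    !all(c("log2ratio", "copy_number") %in% names(labelled))) {
    abort("`labelled` must have `log2ratio` and `copy_number` columns.")
  }
  if (!is.null(fallback)) {
    fallback <- as_tibble(fallback)
    if (!all(c("state", "mean", "sd") %in% names(fallback))) {
      abort("`fallback` must have `state`, `mean`, `sd` columns.")
    }
  }
  observed <- sort(unique(as.integer(labelled$copy_number)))
  if (is.null(states)) {
    states <- sort(union(observed, fallback$state))
  }
  states <- sort(as.integer(states))
  out <- tibble(state = states, mean = NA_real_, sd = NA_real_)
  if (!is.null(fallback)) {
    idx <- match(out$state, fallback$state)
    out$mean <- fallback$mean[idx]
    out$sd <- fallback$sd[idx]
  }
  for (s in intersect(states, observed)) {
    v <- labelled$log2ratio[labelled$copy_number == s]
    if (length(v) == 1L) {
      abort(sprintf(
        "State %d has a single labelled marker; its sd is undefined.", s
      ))
    }
    out$mean[out$state == s] <- mean(v)
    out$sd[out$state == s] <- sd(v)
  }
  if (anyNA(out$mean) || anyNA(out$sd)) {
    miss <- out$state[is.na(out$mean) | is.na(out$sd)]
    abort(sprintf(
      "No labelled markers and no fallback for state(s): %s.",
      paste(miss, collapse = ", ")
    ))
  }
  if (any(diff(out$mean) < 0)) {
    warn("Fitted emission means are not non-decreasing in copy number.")
  }
  out
}
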