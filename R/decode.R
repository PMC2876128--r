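#' Decode copy-number states along ordered marker series
#'
#' Runs exact inference for the conditional random pattern model on a probe
#' table: the Viterbi dynamic programme finds the highest-scoring copy-number
#' path under the summed transition potentials and pattern-based local
#' evidence, the forward recursion yields the log-normalizer `Z(x)`, and
#' forward-backward yields per-locus posterior state probabilities.
#' Chromosomes are decoded independently; no transition links the last marker
#' of one chromosome to the first of the next. All recursions run in log
#' space, so sequences of up to millions of markers decode without
#' underflow. Exact ties in the Viterbi maximisation are broken toward the
#' state closest to the normal copy number.
#'
#' @param probes A data frame with columns `marker`, `chrom`, `pos`
#'   (1-based base-pair position, strictly increasing within a chromosome)
#'   and `log2ratio`. Extra columns are ignored.
#' @param model A [crp_model()].
#'
#' @return An object of class `crp_fit` with elements
#'   \describe{
#'     \item{data}{per-marker tibble: input columns plus `copy_number` (the
#'       Viterbi call) and `posterior_of_call` (posterior probability of the
#'       called state).}
#'     \item{posteriors}{per-marker tibble of posterior probabilities, one
#'       `p_cn<state>` column per state; rows sum to 1.}
#'     \item{segments}{maximal constant-state runs, see
#'       [segments_from_path()].}
#'     \item{chromosomes}{per-chromosome tibble with `n_markers`,
#'       `delta_final` (best final Viterbi log-score), `log_Z`, and
#'       `path_probability = exp(delta_final - log_Z)`.}
#'     \item{model}{the model used.}
#'   }
#'   [tidy()] returns the per-marker calls, [glance()] a one-row summary,
#'   and [autoplot()] a log2-ratio track with the inferred copy numbers.
#'
#' @examples
#' mod <- crp_model_3state()
#' probes <- tibble::tibble(
#'   marker = paste0("s", 1:60), chrom = "chr1", pos = 1:60 * 10000,
#'   log2ratio = c(rnorm(20, 0, 0.1), rnorm(20, 0.27, 0.1), rnorm(20, 0, 0.1))
#' )
#' fit <- viterbi_decode(probes, mod)
#' fit$segments
#' @export
viterbi_decode <- function(probes, model) {
  probes <- validate_probes(probes)
  chroms <- unique(probes$chrom)
  fits <- lapply(chroms, function(ch) {
    sub <- probes[probes$chrom == ch, , drop = FALSE]
    decode_chain(sub$log2ratio, sub$pos, model)
  })
  names(fits) <- chroms

  post_cols <- paste0("p_cn", model$states)
  data <- probes
  data$copy_number <- unname(unlist(
    lapply(fits, function(f) model$states[f$path])
  ))
  post <- do.call(rbind, lapply(fits, `[[`, "posteriors"))
  colnames(post) <- post_cols
  data$posterior_of_call <- post[cbind(
    seq_len(nrow(data)), match(data$copy_number, model$states)
  )]
  posteriors <- dplyr::bind_cols(
    probes[, c("marker", "chrom", "pos")], as_tibble(post)
  )
  chromosomes <- tibble(
    chrom = chroms,
    n_markers = unname(vapply(fits, function(f) length(f$path), integer(1))),
    delta_final = unname(vapply(fits, `[[`, numeric(1), "delta_final")),
    log_Z = unname(vapply(fits, `[[`, numeric(1), "log_Z"))
  )
  chromosomes$path_probability <-
    exp(chromosomes$delta_final - chromosomes$log_Z)
  segments <- segments_from_path(
    data,
    path = data$copy_number,
    posterior_of_call = data$posterior_of_call,
    min_run = model$m
  )
  structure(
    list(
      data = data, posteriors = posteriors, segments = segments,
      chromosomes = chromosomes, model = model
    ),
    class = "crp_fit"
  )
}

#' Normalized probability of the best copy-number labeling
#'
#' Computes `exp(max_y delta_T(y) - log Z(x))`: the probability mass that the
#' single best Viterbi path carries out of all `K^T` labelings. The
#' normalizer is computed by the forward (sum-product) recursion over the
#' same potentials, in log space. With several chromosomes the per-chromosome
#' probabilities multiply (chromosomes are decoded independently).
#'
#' @inheritParams viterbi_decode
#' @return A single probability in `(0, 1]`.
#' @export
path_normalized_probability <- function(probes, model) {
  probes <- validate_probes(probes)
  logp <- vapply(unique(probes$chrom), function(ch) {
    sub <- probes[probes$chrom == ch, , drop = FALSE]
    f <- decode_chain(sub$log2ratio, sub$pos, model)
    f$delta_final - f$log_Z
  }, numeric(1))
  exp(sum(logp))
}

#' Per-locus posterior copy-number probabilities
#'
#' Forward-backward marginals over the same potentials as
#' [viterbi_decode()]: for every marker, the probability of each copy-number
#' state given the whole chromosome's observations. Rows sum to one.
#'
#' @inheritParams viterbi_decode
#' @return A tibble with `marker`, `chrom`, `pos` and one `p_cn<state>`
#'   column per model state.
#' @export
posterior_marginals <- function(probes, model) {
  viterbi_decode(probes, model)$posteriors
}

# single-chromosome exact inference; values/pos already validated
decode_chain <- function(values, pos, model) {
  T_ <- length(values)
  L <- local_evidence_matrix(values, model)
  if (T_ == 1L) {
    theta <- numeric(0)
  } else {
    theta <- transition_theta(
      diff(pos) / 1e6,
      model$transition$morgans_per_mb, model$transition$theta_floor
    )
  }
  res <- .crp_chain_dp(
    L, log1p(-theta), log(theta) - log(model$K - 1),
    as.integer(state_preference(model) - 1L)
  )
  res
}

validate_probes <- function(probes) {
  if (!is.data.frame(probes)) abort("`probes` must be a data frame.")
  need <- c("marker", "chrom", "pos", "log2ratio")
  missing <- setdiff(need, names(probes))
  if (length(missing) > 0) {
    abort(sprintf(
      "`probes` is missing column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  probes <- as_tibble(probes)
  if (nrow(probes) == 0L) abort("`probes` contains no markers.")
  ord <- order(match(probes$chrom, unique(probes$chrom)), probes$pos)
  probes <- probes[ord, , drop = FALSE]
  bad <- !is.finite(probes$log2ratio)
  if (any(bad)) {
    abort(sprintf(
      "Non-finite log2-ratio at marker(s): %s.",
      paste(utils::head(probes$marker[bad], 5), collapse = ", ")
    ))
  }
  for (ch in unique(probes$chrom)) {
    p <- probes$pos[probes$chrom == ch]
    if (any(diff(p) <= 0)) {
      abort(sprintf(
        "Positions must be strictly increasing within chromosome %s.", ch
      ))
    }
  }
  probes
}

#' @export
print.crp_fit <- function(x, ...) {
  ab <- sum(x$segments$state != x$model$normal_state)
  cat(sprintf(
    "<crp_fit> %d markers on %d chromosome(s); %d segment(s), %d aberrant\n",
    nrow(x$data), nrow(x$chromosomes), nrow(x$segments), ab
  ))
  print(x$segments)
  invisible(x)
}
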