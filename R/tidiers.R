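#' Tidy a decoded copy-number fit
#'
#' @param x A [viterbi_decode()] result.
#' @param ... Unused.
#' @return The per-marker call tibble (`marker`, `chrom`, `pos`,
#'   `log2ratio`, `copy_number`, `posterior_of_call`).
#' @export
tidy.crp_fit <- function(x, ...) {
  x$data
}

#' @rdname tidy.crp_fit
#' @return `glance()` returns a one-row tibble: marker and chromosome
#'   counts, model size (`K`, `m`), the joint normalized best-path
#'   probability across chromosomes, and segment counts.
#' @export
glance.crp_fit <- function(x, ...) {
  tibble(
    n_markers = nrow(x$data),
    n_chromosomes = nrow(x$chromosomes),
    K = x$model$K,
    m = x$model$m,
    log_path_probability = sum(
      x$chromosomes$delta_final - x$chromosomes$log_Z
    ),
    path_probability = exp(sum(
      x$chromosomes$delta_final - x$chromosomes$log_Z
    )),
    n_segments = nrow(x$segments),
    n_aberrant_segments = sum(x$segments$state != x$model$normal_state)
  )
}

#' Tidy an evaluation result
#'
#' @param x A [compute_metrics()] result.
#' @param ... Unused.
#' @return A long tibble with columns `metric` and `value` for the seven
#'   metrics; `glance()` returns the one-row wide form with the contingency
#'   counts appended.
#' @export
tidy.crp_metrics <- function(x, ...) {
  tibble(
    metric = c("sr", "sp", "rr", "rp", "hr", "hp", "f"),
    value = c(x$sr, x$sp, x$rr, x$rp, x$hr, x$hp, x$f)
  )
}

#' @rdname tidy.crp_metrics
#' @export
glance.crp_metrics <- function(x, ...) {
  dplyr::bind_cols(as_tibble(unclass(x)), attr(x, "counts"))
}

#' Plot a decoded copy-number track
#'
#' Log2-ratios per marker with the inferred copy number overlaid; aberrant
#' segments are shaded. One facet per chromosome.
#'
#' @param object A [viterbi_decode()] result.
#' @param chromosomes Optional subset of chromosomes to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crp_fit <- function(object, chromosomes = NULL, ...) {
  data <- object$data
  segs <- object$segments
  if (!is.null(chromosomes)) {
    data <- data[data$chrom %in% chromosomes, , drop = FALSE]
    segs <- segs[segs$chrom %in% chromosomes, , drop = FALSE]
  }
  segs <- segs[segs$state != object$model$normal_state, , drop = FALSE]
  ggplot2::ggplot(data, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_rect(
      data = segs,
      ggplot2::aes(
        xmin = .data$start_bp, xmax = .data$end_bp,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.15
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$log2ratio),
      size = 0.4, alpha = 0.5
    ) +
    ggplot2::geom_step(
      ggplot2::aes(y = .data$copy_number - object$model$normal_state),
      colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "position (bp)", y = "log2 ratio",
      subtitle = "red step: inferred copy number (offset from normal)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the seven evaluation metrics
#'
#' @param object A [compute_metrics()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of the seven metrics.
#' @export
autoplot.crp_metrics <- function(object, ...) {
  long <- tidy(object)
  long$metric <- factor(long$metric, levels = long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' Plot a simulated dataset
#'
#' Shows one simulated unit (sequence or sample) with planted regions
#' shaded.
#'
#' @param object A [simulate_sequences()] or [simulate_array_design()]
#'   result.
#' @param which Sequence chromosome id or sample name to plot (default the
#'   first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crp_sim <- function(object, which = NULL, ...) {
  probes <- object$probes
  truth <- object$truth
  if ("sample" %in% names(probes)) {
    which <- which %||% probes$sample[1]
    probes <- probes[probes$sample == which, , drop = FALSE]
    truth <- truth[truth$sample == which, , drop = FALSE]
  } else {
    which <- which %||% probes$chrom[1]
    probes <- probes[probes$chrom == which, , drop = FALSE]
    truth <- truth[truth$chrom == which, , drop = FALSE]
  }
  ggplot2::ggplot(probes, ggplot2::aes(x = .data$pos, y = .data$log2ratio)) +
    ggplot2::geom_rect(
      data = truth,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.2
    ) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      title = which, x = "position (bp)",
      y = "log2 ratio"
    ) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
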