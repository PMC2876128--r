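#' Collapse a per-marker copy-number path into segments
#'
#' Maximal runs of constant copy number within each chromosome become
#' segments. Segments partition the markers: the marker-index intervals are
#' 0-based half-open and their lengths sum to the number of markers per
#' chromosome. Base-pair intervals follow the BED convention (0-based
#' half-open), so a segment covering markers at 1-based positions
#' `p_i .. p_j` spans `[p_i - 1, p_j)`. Segments shorter than `min_run`
#' markers are flagged (`short = TRUE`) but kept: the minimum-run assumption
#' lives in the evidence function, and callers decide whether to filter.
#'
#' @param probes Probe table (see [viterbi_decode()]); `marker`, `chrom`,
#'   `pos` are used.
#' @param path Integer copy-number call per marker, same length as
#'   `nrow(probes)`.
#' @param posterior_of_call Optional per-marker posterior probability of the
#'   called state; segment `mean_probability` is its mean (NA when absent).
#' @param min_run Segments with fewer markers are flagged short.
#'
#' @return A tibble with one row per segment: `chrom`, `start_index`,
#'   `end_index` (0-based half-open marker indices within the chromosome),
#'   `start_bp`, `end_bp`, `state`, `n_markers`, `mean_probability`,
#'   `short`.
#' @export
segments_from_path <- function(probes, path, posterior_of_call = NULL,
                               min_run = 4L) {
  if (!is.data.frame(probes) ||
    !all(c("chrom", "pos") %in% names(probes))) {
    abort("`probes` must have `chrom` and `pos` columns.")
  }
  if (length(path) != nrow(probes)) {
    abort("`path` must have one state per probe row.")
  }
  if (!is.null(posterior_of_call) &&
    length(posterior_of_call) != length(path)) {
    abort("`posterior_of_call` must match `path` in length.")
  }
  chroms <- unique(probes$chrom)
  out <- lapply(chroms, function(ch) {
    in_ch <- probes$chrom == ch
    pos <- probes$pos[in_ch]
    y <- path[in_ch]
    r <- rle(y)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    mp <- if (is.null(posterior_of_call)) {
      rep(NA_real_, length(end))
    } else {
      pc <- posterior_of_call[in_ch]
      vapply(
        seq_along(end),
        function(i) mean(pc[(start[i] + 1L):end[i]]), numeric(1)
      )
    }
    tibble(
      chrom = ch,
      start_index = as.integer(start),
      end_index = as.integer(end),
      start_bp = pos[start + 1L] - 1,
      end_bp = pos[end],
      state = r$values,
      n_markers = as.integer(r$lengths),
      mean_probability = mp,
      short = r$lengths < min_run
    )
  })
  dplyr::bind_rows(out)
}

#' Reassign low-confidence aberrant segments to the normal state
#'
#' When parameter bias produces too many aberrant calls, segments whose mean
#' posterior falls below a threshold can be dropped: their markers are
#' reassigned to the model's normal copy number and the per-marker
#' posteriors of that state replace `posterior_of_call`. Segments are then
#' recomputed, so adjacent normal runs merge.
#'
#' @param fit A [viterbi_decode()] result.
#' @param min_probability Aberrant segments with `mean_probability` below
#'   this value are reassigned; 0 (default) disables filtering.
#' @return A `crp_fit` with updated `data` and `segments`.
#' @export
filter_segments <- function(fit, min_probability = 0) {
  stopifnot(inherits(fit, "crp_fit"))
  if (min_probability < 0 || min_probability > 1) {
    abort("`min_probability` must lie in [0, 1].")
  }
  if (min_probability == 0) {
    return(fit)
  }
  model <- fit$model
  drop <- fit$segments$state != model$normal_state &
    fit$segments$mean_probability < min_probability
  if (!any(drop)) {
    return(fit)
  }
  data <- fit$data
  normal_col <- paste0("p_cn", model$normal_state)
  for (i in which(drop)) {
    seg <- fit$segments[i, ]
    rows <- which(data$chrom == seg$chrom &
      data$pos > seg$start_bp & data$pos <= seg$end_bp)
    data$copy_number[rows] <- model$normal_state
    data$posterior_of_call[rows] <- fit$posteriors[[normal_col]][rows]
  }
  fit$data <- data
  fit$segments <- segments_from_path(
    data, data$copy_number, data$posterior_of_call,
    min_run = model$m
  )
  fit
}
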