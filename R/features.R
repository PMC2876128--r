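#' Normalize sample intensities to a common autosomal mean
#'
#' SNP arrays differ in overall brightness, so samples are made comparable by
#' linearly rescaling each sample's intensities until its mean over autosomal
#' markers equals a common target. Sex chromosomes (any `chrom` matching X,
#' Y or M, with or without a `chr` prefix) are rescaled with the same factor
#' but excluded from the mean.
#'
#' @param intensities A data frame with columns `marker`, `chrom`, `pos`
#'   followed by one numeric intensity column per sample (values >= 0,
#'   markers sorted by chromosome and position, ids unique).
#' @param target_mean The common autosomal mean after scaling (default 1000).
#'
#' @return The intensity tibble with every sample column rescaled.
#' @export
normalize_to_common_mean <- function(intensities, target_mean = 1000) {
  intensities <- validate_intensities(intensities)
  if (target_mean <= 0) abort("`target_mean` must be positive.")
  auto <- is_autosome(intensities$chrom)
  if (!any(auto)) abort("No autosomal markers found.")
  for (s in sample_columns(intensities)) {
    mu <- mean(intensities[[s]][auto])
    if (mu <= 0) {
      abort(sprintf("Sample %s has non-positive autosomal mean.", s))
    }
    intensities[[s]] <- intensities[[s]] * (target_mean / mu)
  }
  intensities
}

#' Select best-fit reference samples for a test sample
#'
#' Under the assumption that reference samples carry two copies nearly
#' everywhere, a good reference for a given test sample is one whose
#' marker-by-marker log2 intensity ratio against the test is flat. Each
#' candidate is scored by the standard deviation over markers of
#' `log2(test / reference)`; the `m_refs` candidates with the smallest score
#' are selected. The criterion is scale-blind (a reference equal to twice
#' the test also scores 0), which is why intensities are mean-normalized
#' first.
#'
#' @param intensities Normalized intensity table (see
#'   [normalize_to_common_mean()]).
#' @param test_sample Name of the test sample column.
#' @param m_refs Number of references to select (default 3).
#'
#' @return A tibble of class `crp_best_fit` with columns `reference` and
#'   `fit_score`, the selected references in ascending score order;
#'   attribute `test_sample` records the test column.
#' @export
select_best_fit_references <- function(intensities, test_sample, m_refs = 3) {
  intensities <- validate_intensities(intensities)
  samples <- sample_columns(intensities)
  if (!test_sample %in% samples) {
    abort(sprintf("Test sample %s not found.", test_sample))
  }
  candidates <- setdiff(samples, test_sample)
  if (m_refs < 1 || m_refs > length(candidates)) {
    abort(sprintf(
      "`m_refs` must be between 1 and %d (available references).",
      length(candidates)
    ))
  }
  x <- intensities[[test_sample]]
  scores <- vapply(candidates, function(r) {
    ratio <- log2(x / intensities[[r]])
    sd(ratio[is.finite(ratio)])
  }, numeric(1))
  ord <- order(scores)[seq_len(m_refs)]
  structure(
    tibble(reference = candidates[ord], fit_score = unname(scores[ord])),
    test_sample = test_sample,
    class = c("crp_best_fit", class(tibble()))
  )
}

#' Extract log2-ratio probe series against a best-fit reference average
#'
#' The log2-ratio feature at marker `i` is
#' `log2(test_i / mean(reference_i))`, the reference value being the average
#' over the selected best-fit references. Under the two-copy reference
#' assumption the feature is ~0 at two copies, negative for losses and
#' positive for gains.
#'
#' @inheritParams select_best_fit_references
#' @param selection A [select_best_fit_references()] result, or a character
#'   vector of reference sample names.
#'
#' @return A probe tibble (`marker`, `chrom`, `pos`, `log2ratio`) sorted by
#'   chromosome and position, ready for [viterbi_decode()].
#' @export
log2_ratio_series <- function(intensities, test_sample, selection) {
  intensities <- validate_intensities(intensities)
  refs <- if (is.data.frame(selection)) selection$reference else selection
  if (length(refs) == 0L) abort("`selection` names no references.")
  samples <- sample_columns(intensities)
  missing <- setdiff(c(test_sample, refs), samples)
  if (length(missing) > 0) {
    abort(sprintf(
      "Sample column(s) not found: %s.", paste(missing, collapse = ", ")
    ))
  }
  ref_mean <- rowMeans(as.matrix(intensities[, unique(refs), drop = FALSE]))
  if (any(ref_mean <= 0)) {
    bad <- intensities$marker[ref_mean <= 0]
    abort(sprintf(
      "Zero reference mean at marker(s): %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  tibble(
    marker = intensities$marker,
    chrom = intensities$chrom,
    pos = intensities$pos,
    log2ratio = log2(intensities[[test_sample]] / ref_mean)
  )
}

validate_intensities <- function(intensities) {
  if (!is.data.frame(intensities) ||
    !all(c("marker", "chrom", "pos") %in% names(intensities))) {
    abort("Intensity tables need `marker`, `chrom`, `pos` plus sample columns.")
  }
  if (anyDuplicated(intensities$marker)) {
    abort("Duplicate marker ids in intensity table.")
  }
  samples <- sample_columns(intensities)
  if (length(samples) == 0L) abort("No sample columns found.")
  for (s in samples) {
    if (any(intensities[[s]] < 0, na.rm = TRUE)) {
      abort(sprintf("Sample %s has negative intensities.", s))
    }
  }
  intensities <- as_tibble(intensities)
  intensities[
    order(match(intensities$chrom, unique(intensities$chrom)), intensities$pos),
  ]
}

sample_columns <- function(intensities) {
  setdiff(names(intensities), c("marker", "chrom", "pos"))
}

is_autosome <- function(chrom) {
  !toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "Y", "M", "MT")
}
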