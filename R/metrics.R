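#' Contingency counts between called and true CNA regions
#'
#' Builds the marker-level and region-level contingency counts underlying
#' the seven evaluation metrics. A marker is aberrant when its copy number
#' differs from `normal_state`. At the marker level the binary
#' aberrant/normal confusion is counted over all markers. At the region
#' level, a truth region counts as detected when at least one of its markers
#' is called aberrant (and missed when all are); a predicted region -- a
#' maximal run of consecutive aberrant calls within a chromosome -- counts
#' as true when at least one of its markers lies inside some truth region.
#' Copy-number values are ignored for detection: a gain called where a loss
#' was planted still detects the region.
#'
#' @param calls Per-marker call table with columns `chrom`, `pos`,
#'   `copy_number` (e.g. `tidy()` of a [viterbi_decode()] fit).
#' @param truth Truth region table with columns `chrom`, `start`, `end`
#'   (0-based half-open bp) and `copy_number`; regions within a chromosome
#'   must not overlap.
#' @param normal_state Copy number treated as normal (default 2).
#'
#' @return A one-row tibble of class `crp_contingency` with columns
#'   `snp_tp`, `snp_fp`, `snp_fn`, `snp_tn`, `region_detected`,
#'   `region_missed`, `pred_region_true`, `pred_region_false`.
#' @export
contingency <- function(calls, truth, normal_state = 2L) {
  if (!is.data.frame(calls) ||
    !all(c("chrom", "pos", "copy_number") %in% names(calls))) {
    abort("`calls` needs `chrom`, `pos`, `copy_number` columns.")
  }
  if (!is.data.frame(truth) ||
    !all(c("chrom", "start", "end") %in% names(truth))) {
    abort("`truth` needs `chrom`, `start`, `end` columns.")
  }
  calls <- as_tibble(calls)
  calls <- calls[
    order(match(calls$chrom, unique(calls$chrom)), calls$pos), ,
    drop = FALSE
  ]
  if (anyDuplicated(calls[, c("chrom", "pos")])) {
    abort("Duplicate markers in `calls`.")
  }
  truth <- as_tibble(truth)
  if (!"copy_number" %in% names(truth)) truth$copy_number <- NA_integer_
  truth <- truth[
    is.na(truth$copy_number) | truth$copy_number != normal_state, ,
    drop = FALSE
  ]
  for (ch in unique(truth$chrom)) {
    r <- truth[truth$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
      abort(sprintf("Overlapping truth regions on chromosome %s.", ch))
    }
  }

  pred_ab <- calls$copy_number != normal_state
  truth_ab <- rep(FALSE, nrow(calls))
  region_of <- rep(NA_integer_, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    inside <- calls$chrom == truth$chrom[i] &
      calls$pos > truth$start[i] & calls$pos <= truth$end[i]
    truth_ab[inside] <- TRUE
    region_of[inside] <- i
  }

  snp_tp <- sum(pred_ab & truth_ab)
  snp_fp <- sum(pred_ab & !truth_ab)
  snp_fn <- sum(!pred_ab & truth_ab)
  snp_tn <- sum(!pred_ab & !truth_ab)

  detected <- vapply(seq_len(nrow(truth)), function(i) {
    any(pred_ab[!is.na(region_of) & region_of == i])
  }, logical(1))
  region_detected <- sum(detected)
  region_missed <- nrow(truth) - region_detected

  # predicted regions: maximal aberrant runs within each chromosome
  pred_true <- 0L
  pred_false <- 0L
  for (ch in unique(calls$chrom)) {
    in_ch <- calls$chrom == ch
    r <- rle(pred_ab[in_ch])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- truth_ab[in_ch]
    for (j in which(r$values)) {
      if (any(hit[starts[j]:ends[j]])) {
        pred_true <- pred_true + 1L
      } else {
        pred_false <- pred_false + 1L
      }
    }
  }

  structure(
    tibble(
      snp_tp = snp_tp, snp_fp = snp_fp, snp_fn = snp_fn, snp_tn = snp_tn,
      region_detected = region_detected, region_missed = region_missed,
      pred_region_true = pred_true, pred_region_false = pred_false
    ),
    class = c("crp_contingency", class(tibble()))
  )
}

#' The seven CNA evaluation metrics from contingency counts
#'
#' SNP-level recall and precision (`sr`, `sp`) come from the marker
#' confusion; region-level recall and precision (`rr`, `rp`) from detected
#' truth regions and true predicted regions. The hybrid metrics multiply the
#' two levels (`hr = sr * rr`, `hp = sp * rp`) and the f-score is the
#' harmonic mean of `hp` and `hr`. A 0/0 ratio scores 1 when the
#' corresponding error count is also zero (a degenerate but perfect empty
#' case) and 0 otherwise.
#'
#' @param counts A [contingency()] result (or any one-row data frame with
#'   the same columns).
#' @return A one-row tibble of class `crp_metrics` with columns `sr`, `sp`,
#'   `rr`, `rp`, `hr`, `hp`, `f`; the counts are carried in the `counts`
#'   attribute.
#' @examples
#' m <- compute_metrics(tibble::tibble(
#'   snp_tp = 8, snp_fp = 6, snp_fn = 2, snp_tn = 84,
#'   region_detected = 1, region_missed = 0,
#'   pred_region_true = 1, pred_region_false = 0
#' ))
#' m$f
#' @export
compute_metrics <- function(counts) {
  need <- c(
    "snp_tp", "snp_fp", "snp_fn", "snp_tn", "region_detected",
    "region_missed", "pred_region_true", "pred_region_false"
  )
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    abort(sprintf(
      "`counts` needs columns: %s.", paste(need, collapse = ", ")
    ))
  }
  if (nrow(counts) != 1L) abort("`counts` must have exactly one row.")
  if (any(unlist(counts[need]) < 0)) abort("Counts must be non-negative.")
  ratio <- function(num, den, err) {
    if (den > 0) num / den else if (err == 0) 1 else 0
  }
  sr <- ratio(counts$snp_tp, counts$snp_tp + counts$snp_fn, counts$snp_fp)
  sp <- ratio(counts$snp_tp, counts$snp_tp + counts$snp_fp, counts$snp_fn)
  rr <- ratio(
    counts$region_detected,
    counts$region_detected + counts$region_missed,
    counts$pred_region_false
  )
  rp <- ratio(
    counts$pred_region_true,
    counts$pred_region_true + counts$pred_region_false,
    counts$region_missed
  )
  hr <- sr * rr
  hp <- sp * rp
  f <- if (hp + hr > 0) 2 * hp * hr / (hp + hr) else 0
  structure(
    tibble(sr = sr, sp = sp, rr = rr, rp = rp, hr = hr, hp = hp, f = f),
    counts = as_tibble(counts[need]),
    class = c("crp_metrics", class(tibble()))
  )
}

#' Evaluate per-marker copy-number calls against truth regions
#'
#' Convenience wrapper: [contingency()] then [compute_metrics()].
#'
#' @inheritParams contingency
#' @return A `crp_metrics` one-row tibble.
#' @export
evaluate_calls <- function(calls, truth, normal_state = 2L) {
  compute_metrics(contingency(calls, truth, normal_state))
}
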