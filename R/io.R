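#' Read and write probe tables
#'
#' Probe tables are tab-separated with a header row `marker`, `chrom`,
#' `pos`, `log2ratio` (positions 1-based), sorted by chromosome and
#' position; lines starting with `#` are comments. Extra columns (e.g.
#' `sample`) are preserved.
#'
#' @param path File path.
#' @return `read_probes()` returns a probe tibble.
#' @export
read_probes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos", "log2ratio")
  if (!all(need %in% names(df))) {
    abort(sprintf(
      "%s: expected tab-separated columns %s.", path,
      paste(need, collapse = ", ")
    ))
  }
  as_tibble(df)
}

#' @rdname read_probes
#' @param probes Probe tibble to write.
#' @export
write_probes <- function(probes, path) {
  utils::write.table(probes, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read and write BED-style region tables
#'
#' Regions use BED conventions: tab-separated, no header, 0-based half-open
#' `chrom`, `start`, `end` with a fourth `copy_number` column; `#` lines are
#' comments. `write_segments_bed()` writes decoded segments with three extra
#' columns (`n_markers`, `mean_probability`, `short`).
#'
#' @param path File path.
#' @return `read_regions()` returns a tibble with `chrom`, `start`, `end`,
#'   `copy_number`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path,
    header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE
  )
  if (ncol(df) < 4) {
    abort(sprintf("%s: expected BED3+1 (chrom, start, end, copy_number).", path))
  }
  names(df)[1:4] <- c("chrom", "start", "end", "copy_number")
  as_tibble(df[, 1:4])
}

#' @rdname read_regions
#' @param regions Region tibble (`chrom`, `start`, `end`, `copy_number`).
#' @export
write_regions <- function(regions, path) {
  utils::write.table(
    regions[, c("chrom", "start", "end", "copy_number")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname read_regions
#' @param segments Segment tibble from [segments_from_path()].
#' @export
write_segments_bed <- function(segments, path) {
  out <- segments[, c(
    "chrom", "start_bp", "end_bp", "state", "n_markers",
    "mean_probability", "short"
  )]
  out$mean_probability <- sprintf("%.6f", out$mean_probability)
  out$short <- as.integer(out$short)
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a model configuration file
#'
#' YAML configuration with optional keys `states`, `means`, `sds`, `m`,
#' `morgans_per_mb`, `theta_floor`, `normal_state` (passed to
#' [crp_model()]) and `min_probability` (segment filter threshold, default
#' 0). Omitted keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `model` (a [crp_model()]) and
#'   `min_probability`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(
    names(cfg),
    c(
      "states", "means", "sds", "m", "morgans_per_mb", "theta_floor",
      "normal_state"
    )
  )]
  model <- do.call(crp_model, args)
  list(
    model = model,
    min_probability = if (is.null(cfg$min_probability)) {
      0
    } else {
      cfg$min_probability
    }
  )
}

#' @rdname read_probes
#' @param fit A [viterbi_decode()] result.
#' @export
write_per_snp <- function(fit, path) {
  stopifnot(inherits(fit, "crp_fit"))
  out <- fit$data[, c(
    "marker", "chrom", "pos", "log2ratio", "copy_number",
    "posterior_of_call"
  )]
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
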