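#' Enumerate copy-number dependency patterns
#'
#' A CNA run is assumed to span at least `m` consecutive markers. To score the
#' copy number of the marker at the centre of a `2m - 1`-wide window, every
#' contiguous run of at least `m` window positions that contains the centre is
#' a candidate pattern: the set of neighbouring observations sharing the
#' centre's copy-number state. There are `m + (m - 1) + ... + 1 = m(m+1)/2`
#' such runs. With the default `m = 4` (seven-marker window) this yields the
#' ten classical patterns, labelled `A`--`J`.
#'
#' @param m Minimum CNA run length in markers (positive integer).
#'
#' @return A tibble of class `crp_patterns` with one row per pattern and
#'   columns `pattern` (id), `from`, `to` (inclusive offset bounds relative to
#'   the centre marker, so the offsets are `from:to`), `length`, and `label`
#'   (letters `A`, `B`, ... for `m = 4`, otherwise `NA`). The attribute
#'   `m` stores the run length; `window` stores the offsets
#'   `-(m-1):(m-1)`.
#'
#' @examples
#' enumerate_patterns(4) # ten patterns over a 7-marker window
#' nrow(enumerate_patterns(3)) # 6
#' @export
enumerate_patterns <- function(m) {
  if (length(m) != 1L || !is.numeric(m) || is.na(m) || m < 1 || m != round(m)) {
    abort("`m` must be a single positive integer.")
  }
  m <- as.integer(m)
  half <- m - 1L
  runs <- list()
  for (len in m:(2L * m - 1L)) {
    # a run of `len` offsets [a, a + len - 1] within [-half, half] containing 0
    starts <- seq(max(-half, -(len - 1L)), min(0L, half - len + 1L))
    for (a in starts) {
      runs[[length(runs) + 1L]] <- c(a, a + len - 1L)
    }
  }
  out <- tibble(
    pattern = sprintf("p%02d", seq_along(runs)),
    from = vapply(runs, `[`, integer(1), 1L),
    to = vapply(runs, `[`, integer(1), 2L),
  )
  out$length <- out$to - out$from + 1L
  out$label <- NA_character_
  if (m == 4L) {
    # classical lettering of the ten 7-marker patterns; the two length-6 runs
    # are lettered in start-descending order (H = {-2..+3}, I = {-3..+2})
    key <- paste(out$from, out$to)
    letter <- c(
      "-3 0" = "A", "-2 1" = "B", "-1 2" = "C", "0 3" = "D",
      "-3 1" = "E", "-2 2" = "F", "-1 3" = "G",
      "-2 3" = "H", "-3 2" = "I", "-3 3" = "J"
    )
    out$label <- unname(letter[key])
  }
  structure(out,
    m = m, window = (-half):half,
    class = c("crp_patterns", class(out))
  )
}

#' @export
print.crp_patterns <- function(x, ...) {
  cat(sprintf(
    "<crp_patterns> m = %d, window = %d markers, %d patterns\n",
    attr(x, "m"), 2L * attr(x, "m") - 1L, nrow(x)
  ))
  NextMethod()
}
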