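#' Simulate log2-ratio sequences with planted CNA regions
#'
#' Generates the sequence-level validation design: independent log2-ratio
#' sequences of 300 points, each carrying four non-overlapping CNA regions
#' of 5, 10, 20 and 40 markers with the aberrant mean 0.4 and normal mean 0,
#' plus Gaussian noise `N(0, sigma)` on every point with
#' `sigma = aberrant_mean / SNR`. The default SNR ladder is 2, 1.3, 1.
#' Regions are placed uniformly at random with at least `gap` normal markers
#' between them so that adjacent regions cannot merge. Region order along
#' the sequence is shuffled per sequence.
#'
#' @param n_sequences Sequences per SNR level (default 100).
#' @param length Markers per sequence (default 300).
#' @param region_lengths CNA region lengths in markers (default 5, 10, 20, 40).
#' @param aberrant_mean Log2-ratio mean inside regions (default 0.4).
#' @param normal_mean Log2-ratio mean outside regions (default 0).
#' @param snr Signal-to-noise levels, `aberrant_mean / sigma`.
#' @param aberrant_copy Copy number recorded for the planted regions
#'   (default 3, a gain).
#' @param gap Minimum normal markers between regions (default 5).
#' @param spacing_bp Inter-marker spacing in base pairs (default 10000).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return An object of class `crp_sim`: a list with
#'   `probes` (tibble `snr`, `chrom` -- one pseudo-chromosome per sequence
#'   -- `marker`, `pos`, `log2ratio`), `truth` (tibble `snr`, `chrom`,
#'   `start`, `end` in 0-based half-open bp, `copy_number`, `n_markers`),
#'   and `config`.
#' @export
simulate_sequences <- function(n_sequences = 100, length = 300,
                               region_lengths = c(5, 10, 20, 40),
                               aberrant_mean = 0.4, normal_mean = 0,
                               snr = c(2, 1.3, 1), aberrant_copy = 3L,
                               gap = 5L, spacing_bp = 10000, seed = NULL) {
  if (any(snr <= 0)) abort("`snr` levels must be positive.")
  if (n_sequences < 1) abort("`n_sequences` must be at least 1.")
  n_reg <- base::length(region_lengths)
  need <- sum(region_lengths) + gap * (n_reg - 1L)
  if (need > length) {
    abort(sprintf(
      "Regions (%d markers incl. gaps) do not fit in %d markers.",
      need, length
    ))
  }
  config <- list(
    design = "sequences", n_sequences = n_sequences, length = length,
    region_lengths = region_lengths, aberrant_mean = aberrant_mean,
    normal_mean = normal_mean, snr = snr, aberrant_copy = aberrant_copy,
    gap = gap, spacing_bp = spacing_bp, seed = seed
  )
  pos <- seq_len(length) * spacing_bp
  probes <- list()
  truth <- list()
  idx <- 0L
  for (s in snr) {
    sigma <- aberrant_mean / s
    for (i in seq_len(n_sequences)) {
      idx <- idx + 1L
      res <- with_sim_seed(child_seed(seed, idx), {
        lens <- sample(region_lengths)
        starts <- place_regions(lens, length, gap)
        clean <- rep(normal_mean, length)
        for (r in seq_along(lens)) {
          clean[starts[r]:(starts[r] + lens[r] - 1L)] <- aberrant_mean
        }
        list(
          values = clean + rnorm(length, 0, sigma),
          starts = starts, lens = lens
        )
      })
      ch <- sprintf("seq%04d", i)
      probes[[idx]] <- tibble(
        snr = s, chrom = ch,
        marker = sprintf("%s_m%04d", ch, seq_len(length)),
        pos = pos, log2ratio = res$values
      )
      ord <- order(res$starts)
      truth[[idx]] <- tibble(
        snr = s, chrom = ch,
        start = pos[res$starts[ord]] - 1,
        end = pos[res$starts[ord] + res$lens[ord] - 1L],
        copy_number = as.integer(aberrant_copy),
        n_markers = as.integer(res$lens[ord])
      )
    }
  }
  new_crp_sim(dplyr::bind_rows(probes), dplyr::bind_rows(truth), config)
}

#' Simulate the genome-wide SNP-array validation design
#'
#' Re-expresses the 500K-array validation design at log2-ratio level: for
#' each reference sample and SNR level, two genomes are simulated -- one
#' carrying single-copy deletions, one three-copy amplifications -- with
#' exactly one CNA region per autosome (22 regions per sample) whose length
#' is uniform on `region_length_range` markers. Aberrant markers take the
#' configured log2-ratio mean for their copy state (defaults -0.45 for one
#' copy and 0.38 for three copies, the empirical shifts on compressed array
#' data); all other markers are 0. Gaussian noise with
#' `sigma = |region mean| / SNR` is added to every marker of the sample.
#' The default configuration (3 references x 3 SNR levels x 2 copy states)
#' yields 18 samples.
#'
#' @param n_autosomes Autosomes simulated per sample (default 22).
#' @param markers_per_chromosome Markers per autosome (default 150; must
#'   accommodate the largest region).
#' @param region_length_range Inclusive bounds of the uniform region length
#'   in markers (default 4 to 100).
#' @param snr SNR levels (default 5, 2, 1.25).
#' @param references Reference sample names (default three).
#' @param deletion_mean,amplification_mean Log2-ratio means of one-copy and
#'   three-copy regions.
#' @param spacing_bp Inter-marker spacing in base pairs.
#' @param seed Integer seed.
#'
#' @return A `crp_sim` whose `probes` carry a `sample` column
#'   (`<reference>_snr<level>_<del|amp>`) alongside `chrom`, `marker`,
#'   `pos`, `log2ratio`, and whose `truth` lists 22 regions per sample.
#' @export
simulate_array_design <- function(n_autosomes = 22,
                                  markers_per_chromosome = 150,
                                  region_length_range = c(4, 100),
                                  snr = c(5, 2, 1.25),
                                  references = c("ref1", "ref2", "ref3"),
                                  deletion_mean = -0.45,
                                  amplification_mean = 0.38,
                                  spacing_bp = 10000, seed = NULL) {
  if (any(snr <= 0)) abort("`snr` levels must be positive.")
  if (region_length_range[1] < 1 ||
    region_length_range[2] < region_length_range[1]) {
    abort("`region_length_range` must be increasing and positive.")
  }
  config <- list(
    design = "array", n_autosomes = n_autosomes,
    markers_per_chromosome = markers_per_chromosome,
    region_length_range = region_length_range, snr = snr,
    references = references, deletion_mean = deletion_mean,
    amplification_mean = amplification_mean, spacing_bp = spacing_bp,
    seed = seed,
    noise_model = "sigma = |region mean| / SNR at log2-ratio level"
  )
  states <- tibble(
    kind = c("del", "amp"),
    copy_number = c(1L, 3L),
    mean = c(deletion_mean, amplification_mean)
  )
  pos <- seq_len(markers_per_chromosome) * spacing_bp
  probes <- list()
  truth <- list()
  idx <- 0L
  for (ref in references) {
    for (s in snr) {
      for (k in seq_len(nrow(states))) {
        idx <- idx + 1L
        sample_name <- sprintf(
          "%s_snr%s_%s", ref, format(s, trim = TRUE), states$kind[k]
        )
        mu <- states$mean[k]
        sigma <- abs(mu) / s
        sim <- with_sim_seed(child_seed(seed, idx), {
          lapply(seq_len(n_autosomes), function(chri) {
            len <- sample_region_length(
              region_length_range, markers_per_chromosome
            )
            start <- sample.int(markers_per_chromosome - len + 1L, 1L)
            clean <- rep(0, markers_per_chromosome)
            clean[start:(start + len - 1L)] <- mu
            list(
              values = clean + rnorm(markers_per_chromosome, 0, sigma),
              start = start, len = len
            )
          })
        })
        probes[[idx]] <- tibble(
          sample = sample_name,
          chrom = rep(
            paste0("chr", seq_len(n_autosomes)),
            each = markers_per_chromosome
          ),
          marker = sprintf(
            "chr%d_m%04d",
            rep(seq_len(n_autosomes), each = markers_per_chromosome),
            rep(seq_len(markers_per_chromosome), n_autosomes)
          ),
          pos = rep(pos, n_autosomes),
          log2ratio = unlist(lapply(sim, `[[`, "values"))
        )
        truth[[idx]] <- tibble(
          sample = sample_name,
          chrom = paste0("chr", seq_len(n_autosomes)),
          start = pos[vapply(sim, `[[`, integer(1), "start")] - 1,
          end = pos[
            vapply(sim, `[[`, integer(1), "start") +
              vapply(sim, `[[`, integer(1), "len") - 1L
          ],
          copy_number = states$copy_number[k],
          n_markers = vapply(sim, `[[`, integer(1), "len")
        )
      }
    }
  }
  new_crp_sim(dplyr::bind_rows(probes), dplyr::bind_rows(truth), config)
}

#' Add Gaussian noise at a given signal-to-noise ratio
#'
#' Adds `N(0, sigma)` draws with `sigma = reference_signal / snr` to a
#' vector of clean values.
#'
#' @param values Clean numeric values.
#' @param snr Positive signal-to-noise ratio.
#' @param reference_signal The signal magnitude the SNR is defined against
#'   (default: the largest absolute clean value).
#' @param seed Optional integer seed.
#' @return `values` plus noise.
#' @export
add_noise <- function(values, snr, reference_signal = max(abs(values)),
                      seed = NULL) {
  if (length(snr) != 1 || !is.finite(snr) || snr <= 0) {
    abort("`snr` must be a single positive number.")
  }
  with_sim_seed(seed, values + rnorm(length(values), 0, reference_signal / snr))
}

new_crp_sim <- function(probes, truth, config) {
  structure(
    list(probes = probes, truth = truth, config = config),
    class = "crp_sim"
  )
}

#' @export
print.crp_sim <- function(x, ...) {
  unit <- if ("sample" %in% names(x$probes)) "sample" else "sequence"
  n <- base::length(unique(x$probes[[if (unit == "sample") {
    "sample"
  } else {
    "chrom"
  }]]))
  cat(sprintf(
    "<crp_sim> %s design: %d %ss, %d markers, %d truth regions\n",
    x$config$design, n, unit, nrow(x$probes), nrow(x$truth)
  ))
  invisible(x)
}

# uniformly place non-overlapping regions (given order) with >= gap markers
# between consecutive regions; returns start indices (1-based)
place_regions <- function(lens, total, gap) {
  n <- base::length(lens)
  slack <- total - sum(lens) - gap * (n - 1L)
  if (slack < 0) abort("Regions cannot be placed.")
  cuts <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  starts <- integer(n)
  at <- 1L
  for (i in seq_len(n)) {
    extra <- cuts[i] - if (i == 1L) 0L else cuts[i - 1L]
    at <- at + extra
    starts[i] <- at
    at <- at + lens[i] + gap
  }
  starts
}

sample_region_length <- function(range, markers) {
  for (try in 1:100) {
    len <- sample(seq(range[1], range[2]), 1L)
    if (len <= markers) {
      return(as.integer(len))
    }
  }
  abort("Chromosome too short for the configured region lengths.")
}

# derive a reproducible child seed; NULL seed leaves the RNG untouched
child_seed <- function(seed, index) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) + 48271 * index) %% 2147483647)
}

with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
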