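marker_grid <- function(n = 100) {
  tibble::tibble(
    marker = sprintf("m%03d", seq_len(n)), chrom = "chr1",
    pos = seq_len(n) * 1000
  )
}

# truth/calls built from 0-based marker index ranges [from, to)
region_bp <- function(from, to, copy_number = 3L) {
  tibble::tibble(
    chrom = "chr1", start = from * 1000, end = to * 1000,
    copy_number = copy_number
  )
}

test_that("contingency counts follow from direct set arithmetic", {
  grid <- marker_grid(100)
  truth <- region_bp(10, 20) # markers 10..19 (0-based)
  calls <- grid
  calls$copy_number <- 2L
  calls$copy_number[13:26] <- 3L # markers 12..25
  counts <- contingency(calls, truth)
  expect_equal(counts$snp_tp, 8L)
  expect_equal(counts$snp_fn, 2L)
  expect_equal(counts$snp_fp, 6L)
  expect_equal(counts$snp_tn, 84L)
  expect_equal(counts$region_detected, 1L)
  expect_equal(counts$region_missed, 0L)
  expect_equal(counts$pred_region_true, 1L)
  expect_equal(counts$pred_region_false, 0L)
})

test_that("perfect and empty predictions hit the contingency extremes", {
  grid <- marker_grid(60)
  truth <- dplyr::bind_rows(region_bp(5, 15), region_bp(30, 40, 1L))
  perfect <- calls_from_truth(grid, truth)
  counts <- contingency(perfect, truth)
  expect_equal(counts$snp_fp + counts$snp_fn, 0L)
  expect_equal(counts$region_missed, 0L)
  expect_true(all(unlist(compute_metrics(counts)) == 1))
  empty <- grid
  empty$copy_number <- 2L
  counts0 <- contingency(empty, truth)
  expect_equal(counts0$snp_tp, 0L)
  expect_equal(counts0$region_detected, 0L)
  expect_equal(counts0$pred_region_true + counts0$pred_region_false, 0L)
  m0 <- compute_metrics(counts0)
  expect_equal(m0$sr, 0)
  expect_equal(m0$rr, 0)
  expect_equal(m0$f, 0)
})

test_that("one overlapping marker is enough to detect a region", {
  grid <- marker_grid(50)
  truth <- region_bp(10, 30)
  calls <- grid
  calls$copy_number <- 2L
  calls$copy_number[11] <- 3L # a single marker inside the region
  counts <- contingency(calls, truth)
  expect_equal(counts$region_detected, 1L)
  expect_equal(counts$pred_region_true, 1L)
  # a gain called over a planted loss still detects the region
  truth_loss <- region_bp(10, 30, copy_number = 1L)
  expect_equal(contingency(calls, truth_loss)$region_detected, 1L)
})

test_that("overlapping truth regions and duplicate calls are rejected", {
  grid <- marker_grid(30)
  calls <- grid
  calls$copy_number <- 2L
  bad_truth <- dplyr::bind_rows(region_bp(5, 15), region_bp(10, 20))
  expect_error(contingency(calls, bad_truth), "Overlapping")
  dup <- dplyr::bind_rows(calls, calls[1, ])
  expect_error(contingency(dup, region_bp(5, 15)), "Duplicate")
  expect_error(
    compute_metrics(dplyr::mutate(
      contingency(calls, region_bp(5, 15)),
      snp_tp = -1
    )),
    "non-negative"
  )
})

test_that("hybrid metrics are the straight products and f their harmonic mean", {
  set.seed(14)
  for (i in 1:20) {
    counts <- tibble::tibble(
      snp_tp = sample(0:500, 1), snp_fp = sample(0:100, 1),
      snp_fn = sample(0:100, 1), snp_tn = sample(0:5000, 1),
      region_detected = sample(0:22, 1), region_missed = sample(0:22, 1),
      pred_region_true = sample(0:30, 1), pred_region_false = sample(0:30, 1)
    )
    m <- compute_metrics(counts)
    expect_equal(m$hr, m$sr * m$rr, tolerance = 1e-12)
    expect_equal(m$hp, m$sp * m$rp, tolerance = 1e-12)
    if (m$hp + m$hr > 0) {
      expect_equal(m$f, 2 * m$hp * m$hr / (m$hp + m$hr), tolerance = 1e-12)
    } else {
      expect_equal(m$f, 0)
    }
    vals <- unlist(m[1, c("sr", "sp", "rr", "rp", "hr", "hp", "f")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(m$f, max(m$hp, m$hr) + 1e-12)
  }
})

test_that("the published product-convention benchmark is reproduced", {
  # every hybrid and f cell follows from the printed sr/sp/rr/rp cells
  # under the straight-product convention, to the printed precision
  with(benchmark_product, {
    expect_true(all(abs(sr * rr - hr) < 0.001))
    expect_true(all(abs(sp * rp - hp) < 0.001))
    expect_true(all(abs(2 * hp * hr / (hp + hr) - f) < 0.001))
  })
  # spot-check through compute_metrics itself with counts engineered to
  # reproduce the first benchmark row's four base ratios exactly:
  # sr = 0.9718 = 1723/1773, sp = 0.9857 = 1723/1748 (approx), etc.
  row <- benchmark_product[1, ]
  den <- 10000
  counts <- tibble::tibble(
    snp_tp = round(row$sr * den), snp_fn = den - round(row$sr * den),
    snp_fp = round(round(row$sr * den) / row$sp) - round(row$sr * den),
    snp_tn = 0,
    region_detected = 20, region_missed = 2, # 0.9091
    pred_region_true = 20, pred_region_false = 8 # 0.7143
  )
  m <- compute_metrics(counts)
  expect_equal(m$hr, row$hr, tolerance = 0.001)
  expect_equal(m$hp, row$hp, tolerance = 0.001)
  expect_equal(m$f, row$f, tolerance = 0.001)
})

test_that("the second published benchmark uses crossed products instead", {
  # its hybrid cells match sp*rr and sr*rp, not sr*rr and sp*rp: the two
  # published tables are mutually inconsistent, and this package follows
  # the straight-product convention of the first
  with(benchmark_crossed, {
    expect_true(all(abs(sp * rr - hr) < 0.001))
    expect_true(all(abs(sr * rp - hp) < 0.001))
    expect_true(all(abs(2 * hp * hr / (hp + hr) - f) < 0.001))
    expect_gt(max(abs(sr * rr - hr)), 0.01) # straight products do NOT fit
  })
})

test_that("adding correct calls helps and spurious regions hurt precision", {
  grid <- marker_grid(80)
  truth <- dplyr::bind_rows(region_bp(10, 20), region_bp(50, 70))
  calls <- grid
  calls$copy_number <- 2L
  calls$copy_number[52:65] <- 3L
  base <- compute_metrics(contingency(calls, truth))
  more <- calls
  more$copy_number[12:18] <- 3L # detects the first region too
  better <- compute_metrics(contingency(more, truth))
  expect_gte(better$sr, base$sr)
  expect_gte(better$rr, base$rr)
  spurious <- calls
  spurious$copy_number[75:78] <- 3L # an isolated false region
  worse <- compute_metrics(contingency(spurious, truth))
  expect_lte(worse$rp, base$rp)
})
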