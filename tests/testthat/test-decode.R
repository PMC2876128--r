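test_that("exact inference matches exhaustive enumeration on small chains", {
  set.seed(42)
  model <- test_model_3k(sds = 0.3)
  for (i in 1:25) {
    T_ <- sample(1:8, 1)
    probes <- random_probes(T_, sd = 0.4)
    oracle <- oracle_chain(probes$log2ratio, probes$pos, model)
    fit <- viterbi_decode(probes, model)
    expect_equal(fit$chromosomes$delta_final, oracle$best_score,
      tolerance = 1e-9
    )
    expect_equal(fit$chromosomes$log_Z, oracle$log_Z, tolerance = 1e-9)
    expect_equal(
      path_normalized_probability(probes, model),
      oracle$best_path_probability,
      tolerance = 1e-9
    )
    post <- as.matrix(fit$posteriors[, paste0("p_cn", model$states)])
    expect_equal(post, oracle$marginals,
      tolerance = 1e-9,
      ignore_attr = TRUE
    )
    # the Viterbi path attains the enumerated best score
    L <- oracle_evidence(probes$log2ratio, model)
    path_idx <- match(fit$data$copy_number, model$states)
    score <- sum(L[cbind(seq_len(T_), path_idx)])
    if (T_ > 1) {
      d <- diff(probes$pos) / 1e6
      for (t in 2:T_) {
        score <- score + transition_potential(
          fit$data$copy_number[t - 1], fit$data$copy_number[t], d[t - 1],
          model
        )
      }
    }
    expect_equal(score, oracle$best_score, tolerance = 1e-9)
  }
})

test_that("a sequence sitting at the normal mean decodes to a constant path", {
  model <- crp_model() # 5 states, means -2, -0.45, 0, 0.38, 0.8
  probes <- tibble::tibble(
    marker = paste0("m", 1:50), chrom = "chr2", pos = 1:50 * 5000,
    log2ratio = rep(0, 50)
  )
  fit <- viterbi_decode(probes, model)
  expect_true(all(fit$data$copy_number == 2))
  expect_equal(nrow(fit$segments), 1L)
  expect_equal(fit$segments$n_markers, 50L)
})

test_that("a high-SNR 40-marker gain is recovered without false positives", {
  set.seed(7)
  sigma <- 0.4 / 5
  model <- crp_model(states = 1:3, means = c(-0.4, 0, 0.4), sds = sigma)
  values <- rnorm(300, 0, sigma)
  values[131:170] <- rnorm(40, 0.4, sigma)
  probes <- tibble::tibble(
    marker = paste0("m", 1:300), chrom = "chr1", pos = 1:300 * 10000,
    log2ratio = values
  )
  fit <- viterbi_decode(probes, model)
  expect_true(all(fit$data$copy_number[131:170] == 3))
  expect_true(all(fit$data$copy_number[-(131:170)] == 2))
  # interior posteriors of the called state are near-certain
  post <- fit$posteriors$p_cn3[135:166]
  expect_true(all(post > 0.99))
})

test_that("exact Viterbi ties break toward the normal state", {
  # identical emission parameters for all states: every labeling with no
  # state change scores the same, so the tie-break decides
  model <- crp_model(
    states = 1:3, means = c(0, 0, 0), sds = 0.2,
    normal_state = 2
  )
  probes <- random_probes(20)
  fit <- viterbi_decode(probes, model)
  expect_true(all(fit$data$copy_number == 2))
})

test_that("posterior rows always sum to one", {
  set.seed(99)
  model <- crp_model()
  for (i in 1:5) {
    probes <- random_probes(sample(2:60, 1), sd = 0.6)
    post <- posterior_marginals(probes, model)
    sums <- rowSums(post[, paste0("p_cn", model$states)])
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("single-locus normalized probability is the softmax maximum", {
  model <- test_model_3k()
  probes <- tibble::tibble(
    marker = "m1", chrom = "chr1", pos = 1000, log2ratio = 0.3
  )
  ev <- vapply(
    model$states,
    function(s) local_evidence(0.3, s, model, offsets = 0),
    numeric(1)
  )
  expect_equal(
    path_normalized_probability(probes, model),
    max(exp(ev)) / sum(exp(ev)),
    tolerance = 1e-12
  )
  p <- path_normalized_probability(random_probes(30), model)
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("chromosomes decode independently", {
  set.seed(3)
  model <- test_model_3k()
  p1 <- random_probes(12)
  p2 <- random_probes(9)
  p2$chrom <- "chr2"
  both <- dplyr::bind_rows(p1, p2)
  fit_both <- viterbi_decode(both, model)
  fit1 <- viterbi_decode(p1, model)
  fit2 <- viterbi_decode(p2, model)
  expect_equal(
    fit_both$data$copy_number,
    c(fit1$data$copy_number, fit2$data$copy_number)
  )
  expect_equal(
    path_normalized_probability(both, model),
    path_normalized_probability(p1, model) *
      path_normalized_probability(p2, model),
    tolerance = 1e-12
  )
})

test_that("malformed probe tables are rejected with informative errors", {
  model <- test_model_3k()
  probes <- random_probes(10)
  bad <- probes
  bad$log2ratio[4] <- NA
  expect_error(viterbi_decode(bad, model), "m004")
  expect_error(
    viterbi_decode(probes[0, ], model), "no markers"
  )
  dup <- probes
  dup$pos[2] <- dup$pos[1]
  expect_error(viterbi_decode(dup, model), "strictly increasing")
  expect_error(viterbi_decode(probes[, 1:3], model), "log2ratio")
})

test_that("isolated single-marker outliers are never called aberrant", {
  set.seed(21)
  sigma <- 0.1
  model <- crp_model(states = 1:3, means = c(-0.4, 0, 0.4), sds = sigma, m = 4)
  for (rep in 1:20) {
    values <- rnorm(41, 0, sigma)
    values[21] <- sample(c(-1, 1), 1) * 4 * sigma # <= 4 sd excursion
    probes <- tibble::tibble(
      marker = paste0("m", 1:41), chrom = "chr1", pos = 1:41 * 10000,
      log2ratio = values
    )
    fit <- viterbi_decode(probes, model)
    expect_true(all(fit$data$copy_number == 2))
  }
})
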