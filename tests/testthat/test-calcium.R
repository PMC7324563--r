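# Calcium dF/F quantification, the acceptance rule and cell classification.

test_that("dF/F is the percentage change over the baseline mean", {
  t <- 0:99
  expect_equal(delta_f_over_f(t, rep(80, 100), c(0, 20)), rep(0, 100))
  f <- c(rep(100, 50), rep(150, 50))
  dff <- delta_f_over_f(t, f, c(0, 49))
  expect_equal(dff[60], 50)
  expect_error(delta_f_over_f(t, rep(0, 100), c(0, 20)), "positive")
})

test_that("dF/F is invariant under uniform gain", {
  t <- 0:99
  withr::with_seed(9, f <- 100 + stats::rnorm(100, 0, 5))
  base <- delta_f_over_f(t, f, c(0, 30))
  for (c in c(0.5, 2, 100)) {
    expect_equal(delta_f_over_f(t, c * f, c(0, 30)), base)
  }
})

test_that("response AUC integrates only the positive part", {
  t <- 0:99
  expect_equal(response_auc(t, rep(0, 100), c(10, 30)), 0)
  # square pulse +10% lasting 20 s -> 200 % s
  dff <- ifelse(t >= 40 & t <= 60, 10, 0)
  expect_equal(response_auc(t, dff, c(40, 60)), 200)
  # sub-baseline excursions contribute nothing
  expect_equal(response_auc(t, rep(-5, 100), c(10, 30)), 0)
  expect_error(response_auc(t, dff, c(200, 300)), "fewer than 2")
})

test_that("the acceptance rule needs >= 2 elicitations and peak >= 2x fluctuation", {
  expect_true(accept_response(2, 3, 1))
  expect_false(accept_response(3, 1.5, 1))
  expect_false(accept_response(1, 5, 1))
  # boundary: inclusive semantics on both criteria
  expect_true(accept_response(2, 2, 1))
  expect_error(accept_response(2, 3, 0), "baseline_fluctuation")
})

test_that("acceptance is monotone in peak and elicitation count", {
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(0:4, 1)
      peak <- stats::runif(1, 0, 5)
      if (accept_response(n, peak, 1)) {
        expect_true(accept_response(n + 1, peak, 1))
        expect_true(accept_response(n, peak + 1, 1))
      }
    }
  })
})

test_that("classification follows the secretagogue response profile", {
  expect_equal(classify_cell(c(KCl = TRUE, G16.7 = TRUE)), "beta")
  expect_equal(classify_cell(c(carbachol = TRUE, KCl = FALSE)), "acinar")
  expect_equal(classify_cell(c(CCK8 = TRUE, KCl = FALSE)), "acinar")
  # KCl-only responders (alpha-like) stay unclassified
  expect_equal(classify_cell(c(KCl = TRUE, G16.7 = FALSE, carbachol = FALSE)),
               "unclassified")
  expect_equal(classify_cell(c(KCl = FALSE, G16.7 = FALSE)), "unclassified")
})

test_that("labels are recovered at high SNR and acceptance collapses at low SNR", {
  hits <- vapply(1:3, function(seed) {
    cs <- synth_calcium_set(n_beta = 20, n_acinar = 20, n_silent = 10,
                            amplitude = 20, noise_sd = 5, seed = seed)
    expect_equal(cs$truth$snr, 4)
    r <- analyze_calcium_set(cs$time, cs$traces, cs$windows,
                             cs$baseline_window)
    mean(r$class == cs$truth$expected_class)
  }, 1)
  expect_gte(mean(hits), 0.95)

  low <- synth_calcium_set(n_beta = 20, n_acinar = 20, n_silent = 10,
                           amplitude = 5, noise_sd = 5, seed = 1)
  expect_equal(low$truth$snr, 1)
  r <- analyze_calcium_set(low$time, low$traces, low$windows,
                           low$baseline_window)
  # acceptance collapses towards the 2-sigma false-positive floor
  expect_lt(mean(r$class != "unclassified"), 0.2)
})

test_that("zero-amplitude traces are rejected by the 2-sigma rule", {
  cs <- synth_calcium_set(n_beta = 0, n_acinar = 0, n_silent = 25,
                          amplitude = 0, noise_sd = 5, seed = 3)
  r <- analyze_calcium_set(cs$time, cs$traces, cs$windows, cs$baseline_window)
  expect_lt(mean(r$class != "unclassified"), 0.2)
})
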