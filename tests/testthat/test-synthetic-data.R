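# Generator contracts: determinism, analytic invertibility, and the
# red/green/yellow bookkeeping of the timelapse generator.

test_that("generators are bit-identical under a fixed seed", {
  a1 <- synth_assays(noise_sd = 15, seed = 42)
  a2 <- synth_assays(noise_sd = 15, seed = 42)
  expect_identical(a1$assays, a2$assays)
  expect_false(identical(a1$assays,
                         synth_assays(noise_sd = 15, seed = 43)$assays))

  t1 <- synth_secretion_trace(seed = 42)
  t2 <- synth_secretion_trace(seed = 42)
  expect_identical(t1$trace, t2$trace)

  c1 <- synth_calcium_set(n_beta = 3, n_acinar = 3, n_silent = 2, seed = 42)
  c2 <- synth_calcium_set(n_beta = 3, n_acinar = 3, n_silent = 2, seed = 42)
  expect_identical(c1$traces, c2$traces)

  i1 <- synth_timelapse(size = 96, days = 0:2, seed = 42)
  i2 <- synth_timelapse(size = 96, days = 0:2, seed = 42)
  expect_identical(i1$series$images, i2$series$images)
})

test_that("generators do not disturb the global RNG state", {
  withr::with_seed(1, before <- stats::runif(1))
  set.seed(1)
  invisible(synth_assays(noise_sd = 5, seed = 99))
  expect_identical(stats::runif(1), before)
})

test_that("evaporation inflation is cancelled exactly by the correction", {
  a <- synth_assays(evaporation_rate = 0.1, noise_sd = 0, seed = 1)
  expect_equal(unique(a$assays$osm_culture), 300 * 1.1)
  fl <- compute_flux(a$assays)
  expect_equal(fl$gcr, unname(a$truth$true_gcr[fl$group]), tolerance = 1e-12)
  expect_error(synth_assays(evaporation_rate = -0.1), "non-negative")
})

test_that("calcium amplitude at exactly twice the noise is boundary-accepted", {
  # noiseless traces, amplitude equal to 2 x an imposed fluctuation:
  # inclusive >= semantics keeps the response accepted at the boundary
  cs <- synth_calcium_set(n_beta = 1, n_acinar = 0, n_silent = 0,
                          amplitude = 10, noise_sd = 0, seed = 1)
  res <- analyze_calcium_trace(cs$time, cs$traces[, 1], cs$windows,
                               cs$baseline_window)
  rec <- res$records[res$records$stimulus == "G16.7", ]
  expect_true(accept_response(rec$n_elicited, peak = 10,
                              baseline_fluctuation = 5))
  expect_false(accept_response(rec$n_elicited, peak = 10 - 1e-9,
                               baseline_fluctuation = 5 + 1e-9))
})

test_that("timelapse truth obeys the lineage-tracing bookkeeping", {
  tl <- synth_timelapse(size = 128, conversion_rate = 4,
                        dsred_halflife_days = 1.5, days = 0:7, seed = 2)
  tr <- tl$truth$fractions
  # green (EGFP) is cumulative; yellow is not (it decays away)
  expect_true(all(diff(tr$green_pct) >= 0))
  expect_true(any(diff(tr$yellow_pct) < 0))
  expect_true(all(tr$yellow_pct <= pmin(tr$red_pct, tr$green_pct) + 1e-12))
  # control series: green constant after islet labelling at day 1
  ctl <- synth_timelapse(size = 128, conversion_rate = 0, days = 0:7, seed = 2)
  g <- ctl$truth$fractions$green_pct
  expect_equal(g[1], 0)
  expect_true(all(diff(g[-1]) == 0))
  expect_error(synth_timelapse(size = 64, tissue_radius = 40), "fit")
})

test_that("converted red intensity halves after one half-life", {
  hl <- 2
  tl <- synth_timelapse(size = 96, conversion_rate = 0, n_islets = 1,
                        dsred_halflife_days = hl, noise_sd = 0,
                        days = c(0, 1, 1 + hl), seed = 5)
  imgs <- tl$series$images
  islet <- imgs[[2]]$green > 0      # converted (islet) pixels, labelled day 1
  expect_gt(sum(islet), 0)
  full <- max(imgs[[1]]$red)
  expect_equal(unique(round(imgs[[3]]$red[islet], 8)), full / 2)
})
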