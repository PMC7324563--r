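# Seeded synthetic-data generators with known ground truth.
#
# Every generator draws all randomness from a single passed seed (no hidden
# global state: the RNG state is restored afterwards) and returns both the
# dataset and a `truth` list sufficient to regenerate it bit-identically
# and to score recovery by the corresponding analysis stage.

#' Synthetic daily medium assay table
#'
#' Emulates daily medium sampling with matched blanks: osmolarity of the
#' culture sample is inflated by evaporation
#' (`osm_culture = osm_blank * (1 + evaporation_rate)`), and analyte levels
#' are constructed to be exactly consistent with the per-group true GCR and
#' LPR over the culture interval, before Gaussian measurement noise is
#' added. At zero noise, [gcr()] and [lpr()] recover the true rates exactly
#' for any evaporation rate (the osmolarity correction cancels the
#' inflation algebraically).
#'
#' @param true_gcr,true_lpr Named numeric vectors of true rates per group,
#'   (ug/h)/ug DNA.
#' @param evaporation_rate Fractional osmolarity inflation per sample,
#'   >= 0.
#' @param noise_sd Gaussian SD added to analyte measurements, ug.
#' @param days Number of culture days (one sample per day), >= 1.
#' @param replicates Replicates per group and day.
#' @param delta_time Culture interval per sample, h.
#' @param dna_mass DNA normaliser, ug.
#' @param g_blank,l_blank,osm_blank Blank values (ug, ug, mOsm).
#' @param seed Integer seed controlling all randomness.
#' @return List with `assays` (tibble, see [compute_flux()]) and `truth`.
#' @export
synth_assays <- function(true_gcr = c(transwell = 2.0, pfc = 1.0),
                         true_lpr = c(transwell = 2.4, pfc = 0.8),
                         evaporation_rate = 0.1, noise_sd = 0,
                         days = 10, replicates = 3, delta_time = 12,
                         dna_mass = 10, g_blank = 1000, l_blank = 50,
                         osm_blank = 300, seed = 1) {
  if (days < 1) stop("days must be >= 1")
  if (evaporation_rate < 0 || noise_sd < 0)
    stop("rates and noise must be non-negative")
  groups <- names(true_gcr)
  if (is.null(groups) || !identical(groups, names(true_lpr)))
    stop("true_gcr and true_lpr must be named by the same groups")
  grid <- expand.grid(day = seq_len(days), group = groups,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  osm_culture <- osm_blank * (1 + evaporation_rate)
  ratio <- osm_culture / osm_blank
  g_true <- unname((g_blank - true_gcr[grid$group] * dna_mass * delta_time) * ratio)
  l_true <- unname((l_blank + true_lpr[grid$group] * dna_mass * delta_time) * ratio)
  withr::with_seed(seed, {
    assays <- tibble::tibble(
      day = grid$day, group = grid$group, replicate = grid$replicate,
      g_blank = g_blank,
      g_culture = g_true + stats::rnorm(nrow(grid), 0, noise_sd),
      l_blank = l_blank,
      l_culture = l_true + stats::rnorm(nrow(grid), 0, noise_sd),
      osm_blank = osm_blank, osm_culture = osm_culture,
      delta_time = delta_time, dna_mass = dna_mass
    )
  })
  list(assays = assays,
       truth = list(generator = "synth_assays", seed = seed,
                    true_gcr = true_gcr, true_lpr = true_lpr,
                    evaporation_rate = evaporation_rate,
                    noise_sd = noise_sd))
}

#' Synthetic perifusion secretion trace
#'
#' Baseline 1 plus stimulus-locked responses for each schedule segment:
#' within a responding segment the signal rises by the segment amplitude
#' and decays exponentially, emulating a secretory burst. Gaussian noise is
#' added on top.
#'
#' @param schedule Stimulus schedule tibble ([default_schedule()]).
#' @param amplitudes Named numeric vector of response amplitudes per
#'   segment label (labels absent from the schedule are ignored); >= 0.
#' @param baseline Baseline level.
#' @param noise_sd Gaussian noise SD.
#' @param decay_min Exponential decay time constant of responses, min.
#' @param interval Sampling cadence, min.
#' @param seed Integer seed.
#' @return List with `trace` (tibble `time_min`, `value`) and `truth`.
#' @export
synth_secretion_trace <- function(schedule = default_schedule(),
                                  amplitudes = c("G16.7" = 3, "G3+KCl" = 4),
                                  baseline = 1, noise_sd = 0.05,
                                  decay_min = 10, interval = 1, seed = 1) {
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  validate_schedule(schedule)
  t_end <- max(schedule$start_min + schedule$duration_min)
  time <- seq(0, t_end, by = interval)
  signal <- rep(baseline, length(time))
  for (i in seq_len(nrow(schedule))) {
    amp <- amplitudes[schedule$label[i]]
    if (is.na(amp) || amp == 0) next
    s0 <- schedule$start_min[i]
    s1 <- s0 + schedule$duration_min[i]
    in_seg <- time >= s0 & time < s1
    signal[in_seg] <- signal[in_seg] +
      baseline * amp * exp(-(time[in_seg] - s0) / decay_min)
  }
  withr::with_seed(seed, {
    value <- pmax(signal + stats::rnorm(length(time), 0, noise_sd), 0)
  })
  list(trace = tibble::tibble(time_min = time, value = value),
       truth = list(generator = "synth_secretion_trace", seed = seed,
                    amplitudes = amplitudes, baseline = baseline,
                    noise_sd = noise_sd))
}

#' Stimulus windows for synthetic calcium runs
#'
#' Each stimulus is applied twice (so that the >= 2 elicitation acceptance
#' criterion is satisfiable): high glucose, KCl and carbachol windows over
#' a 660 s run with a 60 s baseline.
#'
#' @return Data frame with `label`, `start`, `end` (s).
#' @export
calcium_stim_windows <- function() {
  data.frame(
    label = c("G16.7", "G16.7", "KCl", "KCl", "carbachol", "carbachol"),
    start = c(60, 180, 300, 390, 480, 570),
    end = c(120, 240, 330, 420, 540, 630)
  )
}

#' Synthetic calcium trace set with known cell labels
#'
#' Generates raw Fluo-4-like fluorescence traces (baseline `f0` a.u. with
#' Gaussian noise) for a mixture of beta cells (respond to high glucose and
#' KCl), acinar cells (respond to carbachol only) and silent cells.
#' Responses are square pulses of height `amplitude` percent of baseline
#' over each matching stimulus window. SNR is `amplitude` divided by the
#' baseline noise in dF/F percent units (`100 * noise_sd / f0`).
#'
#' @param n_beta,n_acinar,n_silent Cell counts per class.
#' @param amplitude Response amplitude, percent of baseline.
#' @param noise_sd Gaussian noise SD on the raw fluorescence (a.u.).
#' @param f0 Baseline fluorescence, a.u.
#' @param windows Stimulus windows ([calcium_stim_windows()]).
#' @param dt Frame interval, s.
#' @param seed Integer seed.
#' @return List with `time`, `traces` (time x cell matrix), `windows`,
#'   `baseline_window`, and `truth` (per-cell class labels, snr).
#' @export
synth_calcium_set <- function(n_beta = 20, n_acinar = 20, n_silent = 10,
                              amplitude = 20, noise_sd = 5, f0 = 100,
                              windows = calcium_stim_windows(), dt = 2,
                              seed = 1) {
  if (amplitude < 0) stop("amplitudes must be >= 0")
  classes <- rep(c("beta", "acinar", "silent"),
                 c(n_beta, n_acinar, n_silent))
  t_end <- max(windows$end) + 30
  time <- seq(0, t_end, by = dt)
  respond_to <- list(beta = c("G16.7", "KCl"), acinar = "carbachol",
                     silent = character(0))
  withr::with_seed(seed, {
    traces <- vapply(seq_along(classes), function(j) {
      f <- rep(f0, length(time))
      for (i in seq_len(nrow(windows))) {
        if (windows$label[i] %in% respond_to[[classes[j]]]) {
          in_w <- time >= windows$start[i] & time <= windows$end[i]
          f[in_w] <- f[in_w] + f0 * amplitude / 100
        }
      }
      pmax(f + stats::rnorm(length(time), 0, noise_sd), 0)
    }, numeric(length(time)))
  })
  colnames(traces) <- paste0("cell", seq_along(classes))
  snr <- if (noise_sd > 0) amplitude / (100 * noise_sd / f0) else Inf
  list(time = time, traces = traces, windows = windows,
       baseline_window = c(0, 58),
       truth = list(generator = "synth_calcium_set", seed = seed,
                    classes = classes,
                    expected_class = ifelse(classes == "silent",
                                            "unclassified", classes),
                    amplitude = amplitude,
                    noise_sd = noise_sd, snr = snr))
}

#' Synthetic lineage-tracing timelapse
#'
#' Emulates a longitudinal red/green reporter experiment: the whole tissue
#' disk expresses the red (dsRED) reporter; islets are labelled green by
#' day 1 (pre-existing beta cells); in treated series, Poisson-distributed
#' conversion events per day create new green clusters whose red signal
#' decays exponentially with the stated half-life, producing a transient
#' yellow (red + green) stage. Green is therefore cumulative while yellow
#' is not; in control series (conversion rate 0) green stays flat after
#' islet labelling.
#'
#' Ground truth per day is the exact area fraction of pixels whose red
#' intensity is at least half its full value (one half-life), plus the
#' cumulative green and transient yellow fractions.
#'
#' @param size Image side, px.
#' @param pixel_size Pixel size, um/px.
#' @param tissue_radius Tissue disk radius, px.
#' @param n_islets Number of islet disks.
#' @param islet_radius Islet radius, px.
#' @param conversion_rate Expected conversion events per day (0 for
#'   control series).
#' @param event_radius Radius of each converted cluster, px.
#' @param dsred_halflife_days Half-life of dsRED after conversion, days.
#' @param noise_sd Gaussian noise SD on channel intensities.
#' @param days Day indices imaged (day 0 = transduction).
#' @param seed Integer seed.
#' @return List with `series` (a slice image series usable by
#'   [longitudinal_report()]) and `truth` (per-day tibble of exact
#'   fractions plus generator parameters).
#' @export
synth_timelapse <- function(size = 256, pixel_size = 10,
                            tissue_radius = round(size * 0.4),
                            n_islets = 4, islet_radius = round(size / 32),
                            conversion_rate = 3,
                            event_radius = round(size / 42),
                            dsred_halflife_days = 1.5, noise_sd = 0.02,
                            days = 0:7, seed = 1) {
  if (2 * tissue_radius > size) stop("tissue does not fit the frame")
  cx <- size / 2
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  tissue <- (xg - cx)^2 + (yg - cx)^2 <= tissue_radius^2

  full_red <- 0.8
  withr::with_seed(seed, {
    # conversion_day per pixel: NA = never converts; islets convert at day 1
    conv_day <- matrix(NA_real_, size, size)
    for (k in seq_len(n_islets)) {
      repeat {
        ic <- cx + stats::runif(2, -1, 1) * (tissue_radius - islet_radius - 2)
        if ((ic[1] - cx)^2 + (ic[2] - cx)^2 <=
            (tissue_radius - islet_radius - 1)^2) break
      }
      disk <- (xg - ic[1])^2 + (yg - ic[2])^2 <= islet_radius^2
      conv_day[disk & tissue] <- 1
    }
    event_schedule <- list()
    if (conversion_rate > 0) {
      for (d in setdiff(days, 0)) {
        n_ev <- stats::rpois(1, conversion_rate)
        for (e in seq_len(n_ev)) {
          repeat {
            ec <- cx + stats::runif(2, -1, 1) * (tissue_radius - event_radius - 2)
            if ((ec[1] - cx)^2 + (ec[2] - cx)^2 <=
                (tissue_radius - event_radius - 1)^2) break
          }
          disk <- (xg - ec[1])^2 + (yg - ec[2])^2 <= event_radius^2
          sel <- disk & tissue & is.na(conv_day)
          conv_day[sel] <- d
          event_schedule[[length(event_schedule) + 1L]] <-
            c(day = d, x = ec[1], y = ec[2])
        }
      }
    }

    images <- list(); truth_rows <- list()
    for (d in days) {
      age <- d - conv_day
      red_int <- matrix(0, size, size)
      red_int[tissue] <- full_red
      decayed <- !is.na(age) & age >= 0
      red_int[decayed] <- full_red * 0.5^(age[decayed] / dsred_halflife_days)
      green_int <- matrix(0, size, size)
      green_int[!is.na(age) & age >= 0] <- full_red

      red_on <- tissue & red_int >= full_red / 2
      green_on <- green_int > 0
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        day = d,
        red_pct = 100 * sum(red_on) / sum(tissue),
        green_pct = 100 * sum(green_on) / sum(tissue),
        yellow_pct = 100 * sum(red_on & green_on) / sum(tissue)
      )
      noisy <- function(m) {
        pmin(pmax(m + matrix(stats::rnorm(size^2, 0, noise_sd), size), 0), 1)
      }
      bf <- matrix(0.1, size, size); bf[tissue] <- 0.7
      images[[length(images) + 1L]] <- list(
        brightfield = noisy(bf), red = noisy(red_int), green = noisy(green_int)
      )
    }
  })
  list(
    series = list(days = days, pixel_size = pixel_size, images = images),
    truth = list(generator = "synth_timelapse", seed = seed,
                 fractions = do.call(rbind, truth_rows),
                 tissue_area_mm2 = sum(tissue) * (pixel_size / 1000)^2,
                 conversion_rate = conversion_rate,
                 dsred_halflife_days = dsred_halflife_days,
                 events = event_schedule, mask_threshold = full_red / 2)
  )
}
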