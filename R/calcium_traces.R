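# Calcium-imaging trace quantification.
#
# Per-cell Fluo-4 fluorescence traces are converted to percentage change
# over baseline (dF/F), responses are measured as the area under the curve
# above baseline during each stimulus window, and a response is accepted
# only if (1) it was elicited at least twice by the same stimulus and
# (2) its peak is at least twice the baseline fluctuation. Cells are then
# classified as beta (respond to both high glucose and KCl) or acinar
# (respond to carbachol/CCK8 without KCl depolarisation).

#' Percentage fluorescence change over baseline (dF/F)
#'
#' @param time Frame times, s.
#' @param f Raw fluorescence trace, a.u., >= 0.
#' @param baseline_window Two-element window (s) whose mean defines F0.
#' @return dF/F trace in percent: `100 * (F - F0) / F0`.
#' @export
delta_f_over_f <- function(time, f, baseline_window) {
  in_base <- time >= baseline_window[1] & time <= baseline_window[2]
  if (!any(in_base)) stop("baseline window contains no samples")
  f0 <- mean(f[in_base])
  if (!is.finite(f0) || f0 <= 0) stop("baseline mean F0 must be positive")
  100 * (f - f0) / f0
}

#' Response AUC above baseline
#'
#' Trapezoidal integral of the positive part of dF/F over a stimulus
#' window. Excursions below baseline contribute nothing.
#'
#' @param time Frame times, s.
#' @param dff dF/F trace, percent.
#' @param window Two-element stimulus window, s.
#' @return AUC in percent x s, always >= 0.
#' @export
response_auc <- function(time, dff, window) {
  keep <- time >= window[1] & time <= window[2]
  t_w <- time[keep]; y <- pmax(dff[keep], 0)
  if (length(t_w) < 2) stop("window contains fewer than 2 samples")
  sum(diff(t_w) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Response acceptance rule
#'
#' A stimulus response is accepted if it was elicited at least `min_elicit`
#' times by the same stimulus and the peak signal is at least
#' `peak_factor` times the baseline fluctuation. Both comparisons use
#' inclusive (>=) semantics.
#'
#' @param n_elicited Number of times the stimulus elicited a response.
#' @param peak Peak dF/F during the stimulus, percent.
#' @param baseline_fluctuation Baseline fluctuation, percent (> 0);
#'   conventionally the SD of dF/F over the baseline window.
#' @param min_elicit,peak_factor The two criterion constants (2 and 2).
#' @return Logical flag.
#' @export
accept_response <- function(n_elicited, peak, baseline_fluctuation,
                            min_elicit = 2, peak_factor = 2) {
  if (any(baseline_fluctuation <= 0))
    stop("baseline_fluctuation must be > 0")
  n_elicited >= min_elicit & peak >= peak_factor * baseline_fluctuation
}

#' Classify a cell from its accepted responses
#'
#' Beta cells respond to both KCl depolarisation and high (16.7 mM)
#' glucose; requiring both excludes alpha-like cells that respond to KCl
#' only. Acinar cells respond to carbachol or CCK8 without KCl
#' depolarisation. Anything else is unclassified.
#'
#' @param accepted Named logical vector of accepted responses; recognised
#'   names are `"KCl"`, `"G16.7"`, `"carbachol"`, `"CCK8"` (missing
#'   stimuli count as not accepted).
#' @return One of `"beta"`, `"acinar"`, `"unclassified"`.
#' @export
classify_cell <- function(accepted) {
  get <- function(nm) isTRUE(unname(accepted[nm]))
  if (get("KCl") && get("G16.7")) return("beta")
  if ((get("carbachol") || get("CCK8")) && !get("KCl")) return("acinar")
  "unclassified"
}

# Centred running mean with shrinking edge windows.
running_mean <- function(x, k) {
  if (k <= 1) return(x)
  h <- floor(k / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Quantify and classify one calcium trace
#'
#' Full per-cell pipeline: dF/F conversion, per-window peak and AUC,
#' per-stimulus elicitation counting (a window counts as elicited when its
#' peak clears `peak_factor` times the baseline SD), acceptance, and
#' classification. Repeated applications of the same stimulus label are
#' pooled for the elicitation count.
#'
#' @param time Frame times, s.
#' @param f Raw fluorescence trace.
#' @param stim_windows Data frame with `label`, `start`, `end` (s); repeated
#'   labels mark repeated applications of the same stimulus.
#' @param baseline_window Two-element baseline window, s.
#' @param fluctuation Either `"sd"` (default: SD of dF/F over the baseline
#'   window) or `"ptp"` (half the baseline peak-to-peak range).
#' @param smooth_frames Width (frames) of the running-mean filter applied
#'   before peak-picking. The baseline fluctuation is measured on the raw
#'   dF/F; only the peak estimate is denoised, so that the extreme value
#'   over a window reflects the response rather than single-frame noise.
#' @return A list with `records` (per-stimulus tibble: `stimulus`,
#'   `n_windows`, `n_elicited`, `peak`, `auc`, `accepted`), `class`, and
#'   `baseline_fluctuation`.
#' @export
analyze_calcium_trace <- function(time, f, stim_windows,
                                  baseline_window, fluctuation = c("sd", "ptp"),
                                  smooth_frames = 5) {
  fluctuation <- match.arg(fluctuation)
  dff <- delta_f_over_f(time, f, baseline_window)
  in_base <- time >= baseline_window[1] & time <= baseline_window[2]
  bf <- if (fluctuation == "sd") stats::sd(dff[in_base])
        else diff(range(dff[in_base])) / 2
  bf <- max(bf, .Machine$double.eps)
  dff_sm <- running_mean(dff, smooth_frames)

  per_window <- lapply(seq_len(nrow(stim_windows)), function(i) {
    w <- c(stim_windows$start[i], stim_windows$end[i])
    keep <- time >= w[1] & time <= w[2]
    peak <- max(dff_sm[keep])
    list(label = stim_windows$label[i], peak = peak,
         auc = response_auc(time, dff, w),
         elicited = peak >= 2 * bf)
  })
  labels <- vapply(per_window, `[[`, "", "label")
  records <- do.call(rbind, lapply(unique(labels), function(lab) {
    ws <- per_window[labels == lab]
    n_el <- sum(vapply(ws, `[[`, TRUE, "elicited"))
    peak <- max(vapply(ws, `[[`, 1, "peak"))
    tibble::tibble(
      stimulus = lab, n_windows = length(ws), n_elicited = n_el,
      peak = peak, auc = sum(vapply(ws, `[[`, 1, "auc")),
      accepted = accept_response(n_el, peak, bf)
    )
  }))
  accepted <- stats::setNames(records$accepted, records$stimulus)
  list(records = records, class = classify_cell(accepted),
       baseline_fluctuation = bf)
}

#' Analyse a set of calcium traces
#'
#' Applies [analyze_calcium_trace()] to every cell column of a time x cell
#' matrix.
#'
#' @param time Frame times, s.
#' @param traces Matrix with one column per cell (column names are cell
#'   ids).
#' @param stim_windows,baseline_window,fluctuation See
#'   [analyze_calcium_trace()].
#' @return A tibble with one row per cell: `cell`, `class`, plus one
#'   logical acceptance column per stimulus label.
#' @export
analyze_calcium_set <- function(time, traces, stim_windows, baseline_window,
                                fluctuation = "sd") {
  cells <- colnames(traces)
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(traces)))
  rows <- lapply(seq_len(ncol(traces)), function(j) {
    res <- analyze_calcium_trace(time, traces[, j], stim_windows,
                                 baseline_window, fluctuation)
    acc <- as.list(stats::setNames(res$records$accepted, res$records$stimulus))
    tibble::as_tibble(c(list(cell = cells[j], class = res$class), acc))
  })
  do.call(rbind, rows)
}
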