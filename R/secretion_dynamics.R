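# Perifusion trace analysis: stimulation indices and windowed AUCs.
#
# During a perifusion run, slices are exposed to a timed sequence of
# secretagogues while effluent is sampled every minute. Responses are
# summarised as a stimulation index (value over baseline mean) and as
# trapezoidal areas under the SI curve over the standard analysis windows.

#' The standard perifusion stimulus schedule
#'
#' Five contiguous segments: 16 min at 3 mM glucose, 20 min at 16.7 mM,
#' 30 min at 1 mM, 5 min of 3 mM glucose + 30 mM KCl, and 15 min at 3 mM;
#' 86 min in total.
#'
#' @return A tibble with `label`, `start_min`, `duration_min`,
#'   `composition`.
#' @export
default_schedule <- function() {
  dur <- c(16, 20, 30, 5, 15)
  tibble::tibble(
    label = c("G3", "G16.7", "G1", "G3+KCl", "G3"),
    start_min = cumsum(c(0, dur[-5])),
    duration_min = dur,
    composition = c("3 mM glucose", "16.7 mM glucose", "1 mM glucose",
                    "3 mM glucose + 30 mM KCl", "3 mM glucose")
  )
}

#' Validate a stimulus schedule
#'
#' Checks that segments are contiguous, non-overlapping and of positive
#' duration.
#'
#' @param schedule A schedule tibble as returned by [default_schedule()].
#' @return The schedule, invisibly; errors otherwise.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(all(c("label", "start_min", "duration_min") %in% names(schedule)))
  if (any(schedule$duration_min <= 0)) stop("segment durations must be > 0")
  ends <- schedule$start_min + schedule$duration_min
  if (nrow(schedule) > 1 &&
      any(abs(schedule$start_min[-1] - ends[-nrow(schedule)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping")
  invisible(schedule)
}

#' Stimulation index
#'
#' Divides each sample by the mean over the baseline window, yielding a
#' dimensionless trace with baseline at 1. The default baseline window is
#' 1-10 min (the 3 mM glucose period of the analysis clock).
#'
#' @param time Sample times, min, strictly increasing.
#' @param values Analyte values (insulin, glucagon or amylase), >= 0.
#' @param baseline_window Two-element window (min) defining the baseline.
#' @return Numeric SI trace, same length as `values`.
#' @export
stimulation_index <- function(time, values, baseline_window = c(1, 10)) {
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  in_base <- time >= baseline_window[1] & time <= baseline_window[2]
  if (sum(in_base) < 2) stop("baseline window must contain >= 2 samples")
  b <- mean(values[in_base])
  if (!is.finite(b) || b <= 0) stop("baseline mean must be positive")
  values / b
}

#' Canonical analysis windows
#'
#' The four standard windows on the analysis clock: baseline (1-10 min,
#' 3 mM glucose), high glucose (10-32 min, 16.7 mM), low glucose (32-50 min,
#' 1 mM) and depolarisation (50-60 min, KCl).
#'
#' @return Named list of two-element windows (min).
#' @export
canonical_windows <- function() {
  list(baseline = c(1, 10), high_glucose = c(10, 32),
       low_glucose = c(32, 50), kcl = c(50, 60))
}

#' Area under an SI trace over a window
#'
#' Trapezoidal integral of the stimulation index over the stated window,
#' computed over the available samples (no interpolation or imputation of
#' missing samples).
#'
#' @param time Sample times, min.
#' @param si SI trace (see [stimulation_index()]).
#' @param window Two-element window (min).
#' @return AUC in SI x min.
#' @export
window_auc <- function(time, si, window) {
  keep <- is.finite(si) & time >= window[1] & time <= window[2]
  t_w <- time[keep]; s_w <- si[keep]
  if (length(t_w) < 2) stop("window contains fewer than 2 samples")
  sum(diff(t_w) * (utils::head(s_w, -1) + utils::tail(s_w, -1)) / 2)
}

#' Windowed AUC summary of a perifusion trace
#'
#' Computes the stimulation index and its AUC over each canonical window.
#'
#' @param time Sample times, min.
#' @param values Raw analyte trace.
#' @param baseline_window Baseline window for SI normalisation.
#' @param windows Named list of analysis windows; defaults to
#'   [canonical_windows()].
#' @return A tibble with `window`, `start_min`, `end_min`, `auc`.
#' @export
secretion_summary <- function(time, values, baseline_window = c(1, 10),
                              windows = canonical_windows()) {
  si <- stimulation_index(time, values, baseline_window)
  tibble::tibble(
    window = names(windows),
    start_min = unname(vapply(windows, `[`, 1, 1)),
    end_min = unname(vapply(windows, `[`, 1, 2)),
    auc = unname(vapply(windows, function(w) window_auc(time, si, w), 1))
  )
}
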