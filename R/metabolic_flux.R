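# Evaporation-corrected metabolic flux equations.
#
# Daily medium sampling in open culture dishes concentrates analytes as
# water evaporates. The correction rescales each culture measurement by the
# blank-to-culture osmolarity ratio before differencing against the blank:
#
#   GCR = (G_blank - G_culture * Osm_blank / Osm_culture) / dTime
#   LPR = (L_culture * Osm_blank / Osm_culture - L_blank) / dTime
#
# both subsequently normalised per microgram of DNA.

#' Osmolarity-based evaporation correction
#'
#' Rescales a culture-sample concentration by the ratio of blank to culture
#' osmolarity, undoing the concentration increase caused by evaporation.
#'
#' @param conc Measured concentration in the culture sample.
#' @param osm_blank Osmolarity of the matched medium blank, mOsm.
#' @param osm_culture Osmolarity of the culture sample, mOsm.
#' @return Corrected concentration, `conc * osm_blank / osm_culture`.
#' @export
evaporation_correct <- function(conc, osm_blank, osm_culture) {
  if (any(!is.finite(osm_culture)) || any(osm_culture <= 0))
    stop("osm_culture must be > 0")
  if (any(!is.finite(osm_blank)) || any(osm_blank <= 0))
    stop("osm_blank must be > 0")
  conc * osm_blank / osm_culture
}

#' Glucose consumption rate
#'
#' Evaporation-corrected glucose consumption per hour, normalised per
#' microgram DNA. Vectorised over rows.
#'
#' @param g_blank,g_culture Glucose in the blank and culture sample (same
#'   units, e.g. ug).
#' @param osm_blank,osm_culture Matched osmolarities, mOsm.
#' @param delta_time Culture interval, h. Must be > 0.
#' @param dna_mass DNA normaliser, ug. Must be > 0.
#' @return GCR in (ug consumed / h) / ug DNA.
#' @export
gcr <- function(g_blank, g_culture, osm_blank, osm_culture,
                delta_time, dna_mass) {
  if (any(!is.finite(g_blank))) stop("missing blank measurement")
  if (any(delta_time <= 0)) stop("delta_time must be > 0")
  if (any(dna_mass <= 0)) stop("dna_mass must be > 0")
  (g_blank - evaporation_correct(g_culture, osm_blank, osm_culture)) /
    delta_time / dna_mass
}

#' Lactate production rate
#'
#' Evaporation-corrected lactate production per hour, normalised per
#' microgram DNA. Vectorised over rows.
#'
#' @inheritParams gcr
#' @param l_blank,l_culture Lactate in the blank and culture sample.
#' @return LPR in (ug produced / h) / ug DNA.
#' @export
lpr <- function(l_blank, l_culture, osm_blank, osm_culture,
                delta_time, dna_mass) {
  if (any(!is.finite(l_blank))) stop("missing blank measurement")
  if (any(delta_time <= 0)) stop("delta_time must be > 0")
  if (any(dna_mass <= 0)) stop("dna_mass must be > 0")
  (evaporation_correct(l_culture, osm_blank, osm_culture) - l_blank) /
    delta_time / dna_mass
}

#' Compute fluxes for a medium assay table
#'
#' Applies [gcr()] and [lpr()] row-wise to a table of daily medium
#' measurements. Negative computed rates are preserved (measurement noise
#' can imply them) and flagged in the `qc_negative` column rather than
#' clamped.
#'
#' @param assays A data frame with columns `day`, `group`, `replicate`,
#'   `g_blank`, `g_culture`, `l_blank`, `l_culture`, `osm_blank`,
#'   `osm_culture`, `delta_time`, `dna_mass`.
#' @return A tibble with `day`, `group`, `replicate`, `gcr`, `lpr`,
#'   `qc_negative`.
#' @export
compute_flux <- function(assays) {
  need <- c("day", "group", "replicate", "g_blank", "g_culture", "l_blank",
            "l_culture", "osm_blank", "osm_culture", "delta_time", "dna_mass")
  missing_cols <- setdiff(need, names(assays))
  if (length(missing_cols))
    stop("assay table lacks columns: ", paste(missing_cols, collapse = ", "))
  g <- gcr(assays$g_blank, assays$g_culture, assays$osm_blank,
           assays$osm_culture, assays$delta_time, assays$dna_mass)
  l <- lpr(assays$l_blank, assays$l_culture, assays$osm_blank,
           assays$osm_culture, assays$delta_time, assays$dna_mass)
  tibble::tibble(
    day = assays$day, group = assays$group, replicate = assays$replicate,
    gcr = g, lpr = l, qc_negative = g < 0 | l < 0
  )
}

#' ATP production per glucose consumed
#'
#' Efficiency index: ATP produced (pmol, protein-normalised) per microgram
#' of glucose consumed (protein-normalised). Both inputs are taken as
#' already normalised per microgram protein.
#'
#' @param atp ATP production, pmol per ug protein.
#' @param glucose_consumed Glucose consumption, ug per ug protein. Must be
#'   > 0.
#' @return pmol ATP per ug glucose.
#' @export
atp_efficiency <- function(atp, glucose_consumed) {
  if (any(glucose_consumed <= 0)) stop("glucose_consumed must be > 0")
  atp / glucose_consumed
}

#' Area under a daily rate series
#'
#' Trapezoidal integral of a per-day rate series over the day axis, the
#' summary statistic used to compare whole 10-day flux curves between
#' culture groups.
#'
#' @param rates Rate value per day.
#' @param days Day indices, strictly increasing.
#' @return Integral in rate x day units.
#' @export
daily_rate_auc <- function(rates, days) {
  if (length(days) < 2) stop("need at least 2 days")
  if (length(rates) != length(days)) stop("rates and days differ in length")
  if (is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing")
  sum(diff(days) * (utils::head(rates, -1) + utils::tail(rates, -1)) / 2)
}
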