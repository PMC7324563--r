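# Readers, writers and run manifests tying the stages into a reproducible
# pipeline. Tables travel as tidy CSV, image stacks as TIFF (one file per
# day with named channel suffixes), run provenance as a JSON manifest.

#' Write a tidy table as CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a medium assay table from CSV
#'
#' Validates the declared header schema used by [compute_flux()].
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_assay_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "group", "replicate", "g_blank", "g_culture", "l_blank",
            "l_culture", "osm_blank", "osm_culture", "delta_time", "dna_mass")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("assay CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  tibble::as_tibble(x)
}

#' Write an image series to TIFF files
#'
#' One single-channel float TIFF per day and channel, named
#' `day<D>_<channel>.tif`. Channel roles are carried in the returned
#' channel map, never inferred from file order.
#'
#' @param series A slice image series (see [longitudinal_report()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a data frame mapping `day`, `channel`, `file`.
#' @export
write_series_tiff <- function(series, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF requires the 'tiff' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(series$days)) {
    for (ch in names(series$images[[i]])) {
      f <- file.path(dir, sprintf("day%s_%s.tif", series$days[i], ch))
      tiff::writeTIFF(series$images[[i]][[ch]], f, bits.per.sample = 32L)
      rows[[length(rows) + 1L]] <- data.frame(
        day = series$days[i], channel = ch, file = f)
    }
  }
  invisible(do.call(rbind, rows))
}

#' Read an image series from TIFF files
#'
#' @param channel_map Data frame with `day`, `channel`, `file` columns (as
#'   produced by [write_series_tiff()]).
#' @param pixel_size Pixel size, um/px.
#' @return A slice image series.
#' @export
read_series_tiff <- function(channel_map, pixel_size) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF requires the 'tiff' package")
  need <- c("day", "channel", "file")
  missing_cols <- setdiff(need, names(channel_map))
  if (length(missing_cols))
    stop("channel map lacks columns: ", paste(missing_cols, collapse = ", "))
  days <- sort(unique(channel_map$day))
  images <- lapply(days, function(d) {
    sub <- channel_map[channel_map$day == d, ]
    stats::setNames(lapply(sub$file, function(f) {
      m <- tiff::readTIFF(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    }), sub$channel)
  })
  list(days = days, pixel_size = pixel_size, images = images)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version alongside a run's
#' outputs so that identical config + seed reproduces the outputs
#' byte-identically.
#'
#' @param config Named list of run parameters.
#' @param seed Integer seed used for the run.
#' @param dir Output directory of the run.
#' @param file Manifest file name.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, seed, dir, file = "manifest.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, file)
  jsonlite::write_json(
    list(package = "pancslice",
         version = as.character(utils::packageVersion("pancslice")),
         seed = seed, config = config,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
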