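#' Write a B-scan as 8-bit TIFF with a JSON sidecar
#'
#' Pixels are rounded to 8-bit grayscale (the format OCT instruments
#' export); calibration, acquisition metadata and the phantom ground-truth
#' block travel in `<prefix>.json`. The in-memory representation keeps
#' continuous values, so writing is lossy by at most half a grayscale unit
#' per pixel.
#'
#' @param bscan A `bscan` object.
#' @param prefix Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_bscan <- function(bscan, prefix) {
  stopifnot(inherits(bscan, "bscan"))
  tif <- paste0(prefix, ".tif"); js <- paste0(prefix, ".json")
  tiff::writeTIFF(round(bscan$pixels) / 255, tif, bits.per.sample = 8,
                  compression = "none")
  meta <- bscan[setdiff(names(bscan), "pixels")]
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tif, js))
}

#' Read a B-scan written by [write_bscan()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `bscan` object (pixels quantized to integers).
#' @export
read_bscan <- function(prefix) {
  px <- tiff::readTIFF(paste0(prefix, ".tif")) * 255
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new_bscan(round(px), meta$axial_um_per_px, meta$lateral_um_per_px,
            onh_center_px = meta$onh_center_px %||% NA,
            state = meta$state %||% NA_character_,
            subject_id = meta$subject_id %||% NA_character_,
            group = meta$group %||% NA_character_,
            drug = meta$drug %||% NA_character_,
            dose = meta$dose %||% NA_real_,
            truth = meta$truth)
}

#' Write / read a measurement table as CSV
#'
#' Thin readr wrappers fixing the conventions used by every pipeline stage
#' (UTF-8, full precision, header row).
#'
#' @param data A data frame.
#' @param path CSV path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   returns a tibble.
#' @export
write_table_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
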