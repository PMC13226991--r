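#' Build a validated plate table
#'
#' A plate table is the unit of HPTLC calibration: one silica plate carrying
#' standard tracks (known concentration, measured peak area) and sample tracks
#' (unknown concentration, measured peak area and Rf). `plate_table()`
#' validates a long-format data frame, one row per track, and returns it as a
#' tibble of class `"plate_table"`. All concentrations are in µg/mL.
#'
#' @param data Data frame with columns `plate_id`, `kind` (`"standard"` or
#'   `"sample"`), `id` (standard level label or sample id), `concentration`
#'   (µg/mL; `NA` for samples), `peak_area` (AU), `rf` (retardation factor in
#'   \[0, 1\]; `NA` allowed for standards), and optionally `replicate`
#'   (ordinal track index within a sample; defaults to 1, 2, ... per sample).
#'
#' @return A tibble with class `"plate_table"`.
#'
#' @details Each plate must carry at least three distinct standard
#'   concentrations so that a second-order calibration curve is identifiable.
#'   Standard concentrations must be positive and peak areas finite and
#'   non-negative.
#'
#' @examples
#' pt <- plate_table(data.frame(
#'   plate_id = "P1",
#'   kind = c(rep("standard", 3), "sample"),
#'   id = c("L1", "L2", "L3", "GW001-S"),
#'   concentration = c(125, 250, 500, NA),
#'   peak_area = c(0.0026, 0.0051, 0.0099, 0.0060),
#'   rf = c(NA, NA, NA, 0.58)
#' ))
#' dplyr::count(pt, kind)
#' @export
plate_table <- function(data) {
  required <- c("plate_id", "kind", "id", "concentration", "peak_area", "rf")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    pc_schema_abort(sprintf(
      "plate table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(data)
  out$plate_id <- as.character(out$plate_id)
  out$kind <- as.character(out$kind)
  out$id <- as.character(out$id)

  bad_kind <- !out$kind %in% c("standard", "sample")
  if (any(bad_kind)) {
    pc_schema_abort(sprintf(
      "`kind` must be 'standard' or 'sample' (offending row %d: '%s')",
      which(bad_kind)[1], out$kind[which(bad_kind)[1]]
    ))
  }
  for (col in c("concentration", "peak_area", "rf")) {
    if (is.logical(out[[col]]) && all(is.na(out[[col]]))) {
      out[[col]] <- as.numeric(out[[col]]) # an all-empty CSV column
    }
    if (!is.numeric(out[[col]])) {
      pc_schema_abort(sprintf("column `%s` must be numeric", col))
    }
  }
  if (!"replicate" %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data$plate_id, .data$kind, .data$id) |>
      dplyr::mutate(replicate = dplyr::row_number()) |>
      dplyr::ungroup()
  }

  std <- out[out$kind == "standard", ]
  if (any(!is.finite(std$concentration) | std$concentration <= 0)) {
    bad <- which(out$kind == "standard" &
      (!is.finite(out$concentration) | out$concentration <= 0))[1]
    pc_schema_abort(sprintf(
      "standard concentrations must be positive and finite (offending row %d, id '%s')",
      bad, out$id[bad]
    ))
  }
  if (any(!is.finite(out$peak_area) | out$peak_area < 0)) {
    bad <- which(!is.finite(out$peak_area) | out$peak_area < 0)[1]
    pc_schema_abort(sprintf(
      "peak areas must be finite and >= 0 (offending row %d, id '%s')",
      bad, out$id[bad]
    ))
  }
  rf_bad <- out$kind == "sample" & !is.na(out$rf) & (out$rf < 0 | out$rf > 1)
  if (any(rf_bad)) {
    bad <- which(rf_bad)[1]
    pc_schema_abort(sprintf(
      "Rf values must lie in [0, 1] (offending row %d, id '%s')",
      bad, out$id[bad]
    ))
  }

  n_levels <- std |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$concentration), .groups = "drop")
  plates_in <- unique(out$plate_id)
  too_few <- setdiff(plates_in, n_levels$plate_id[n_levels$n >= 3])
  if (length(too_few) > 0) {
    pc_schema_abort(sprintf(
      "insufficient calibration levels on plate(s) %s: at least 3 distinct standard concentrations are required",
      paste(too_few, collapse = ", ")
    ))
  }

  class(out) <- c("plate_table", class(tibble::tibble()))
  out
}

#' Read a plate table from CSV
#'
#' Reads a long-format plate CSV (one row per track) and returns a validated
#' [plate_table()]. The documented schema is
#' `plate_id, kind, level_or_sample_id (or id), concentration, unit,
#' peak_area, rf` with an optional `replicate` column. Concentrations given in
#' mg/mL (via the `unit` column) are converted to the canonical µg/mL at this
#' boundary, so downstream code never sees mixed units.
#'
#' @param path Path to a CSV file.
#' @param dialect Named list of options forwarded to [readr::read_csv()]
#'   (e.g. `list(delim = ";")` is not supported — use a true CSV).
#'
#' @return A [plate_table()] tibble, concentrations in µg/mL.
#' @export
read_plate_table <- function(path, dialect = list()) {
  if (!file.exists(path)) {
    pc_schema_abort(sprintf("file not found: %s", path))
  }
  raw <- rlang::exec(
    readr::read_csv, path,
    show_col_types = FALSE, progress = FALSE, !!!dialect
  )
  nm <- names(raw)
  if ("level_or_sample_id" %in% nm && !"id" %in% nm) {
    raw <- dplyr::rename(raw, id = "level_or_sample_id")
  }
  required <- c("plate_id", "kind", "id", "concentration", "peak_area", "rf")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    pc_schema_abort(sprintf(
      "plate CSV '%s' is missing column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("concentration", "peak_area", "rf")) {
    if (is.character(raw[[col]])) {
      converted <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(converted))
      if (length(bad) > 0) {
        pc_schema_abort(sprintf(
          "non-numeric value '%s' in column `%s`, row %d of %s",
          raw[[col]][bad[1]], col, bad[1], path
        ))
      }
      raw[[col]] <- converted
    }
  }
  if ("unit" %in% names(raw)) {
    unit <- tolower(trimws(as.character(raw$unit)))
    unit[is.na(unit) | unit == ""] <- "ug/ml"
    unit <- gsub("µ", "u", unit)
    known <- unit %in% c("ug/ml", "mg/ml")
    if (any(!known)) {
      pc_schema_abort(sprintf(
        "unknown concentration unit '%s' in row %d of %s (use ug/mL or mg/mL)",
        raw$unit[which(!known)[1]], which(!known)[1], path
      ))
    }
    raw$concentration <- ifelse(unit == "mg/ml",
      raw$concentration * 1000, raw$concentration
    )
    raw$unit <- NULL
  }
  plate_table(raw)
}

#' Write a plate table to CSV
#'
#' Writes the canonical long format with an explicit `unit` column (always
#' `ug/mL`), so that [read_plate_table()] round-trips the values.
#'
#' @param data A [plate_table()] (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(data, path) {
  data <- plate_table(data)
  out <- data |>
    dplyr::mutate(unit = "ug/mL") |>
    dplyr::select(
      "plate_id", "kind", "id", "concentration", "unit",
      "peak_area", "rf", "replicate"
    )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a sample metadata table from CSV
#'
#' Metadata links sample ids to plant part, province, plate assignment and the
#' extraction gravimetry (dry mass in mg, extraction volume in mL) needed to
#' turn solution concentrations into dry-weight contents.
#'
#' @param path CSV with columns `sample_id`, `part` (stem/root/leaf),
#'   `province`, `plate_id`, `mass_mg`, `volume_mL`.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    pc_schema_abort(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sample_metadata(raw)
}

#' Validate a sample metadata table
#'
#' @param data Data frame with columns `sample_id`, `part`, and optionally
#'   `province`, `plate_id`, `mass_mg` (default 100), `volume_mL` (default 1).
#'   The defaults reflect the standard extraction of 100 mg dried powder in
#'   1 mL ethanol–water (7:3).
#' @return A tibble with all columns present and checked.
#' @export
sample_metadata <- function(data) {
  if (!"sample_id" %in% names(data)) {
    pc_schema_abort("metadata must have a `sample_id` column")
  }
  out <- tibble::as_tibble(data)
  out$sample_id <- as.character(out$sample_id)
  if (!"part" %in% names(out)) {
    out$part <- part_from_suffix(out$sample_id)
  }
  out$part <- tolower(as.character(out$part))
  bad <- !out$part %in% c("stem", "root", "leaf")
  if (any(bad)) {
    pc_schema_abort(sprintf(
      "unknown part '%s' for sample %s", out$part[which(bad)[1]],
      out$sample_id[which(bad)[1]]
    ))
  }
  # -S/-R/-L suffix convention must agree with the declared part
  sfx <- part_from_suffix(out$sample_id)
  clash <- !is.na(sfx) & sfx != out$part
  if (any(clash)) {
    pc_schema_abort(sprintf(
      "sample id suffix of %s contradicts declared part '%s'",
      out$sample_id[which(clash)[1]], out$part[which(clash)[1]]
    ))
  }
  if (!"province" %in% names(out)) out$province <- NA_character_
  if (!"plate_id" %in% names(out)) out$plate_id <- NA_character_
  if (!"mass_mg" %in% names(out)) out$mass_mg <- 100
  if (!"volume_mL" %in% names(out)) out$volume_mL <- 1
  check_number(out$mass_mg, "mass_mg", positive = TRUE)
  check_number(out$volume_mL, "volume_mL", positive = TRUE)
  out
}

# stem/root/leaf from the -S/-R/-L sample-id suffix; NA when absent.
part_from_suffix <- function(sample_id) {
  sfx <- toupper(sub(".*-([SRL])$", "\\1", sample_id))
  out <- rep(NA_character_, length(sample_id))
  out[sfx == "S"] <- "stem"
  out[sfx == "R"] <- "root"
  out[sfx == "L"] <- "leaf"
  out
}

#' Build a UV spectrum
#'
#' @param wavelengths Strictly increasing wavelength grid in nm (200–400 nm is
#'   the usual densitometer scan range).
#' @param absorbances Absorbance vector (AU), same length.
#' @return A tibble with columns `wavelength`, `absorbance`, class
#'   `"uv_spectrum"`.
#' @export
uv_spectrum <- function(wavelengths, absorbances) {
  check_number(wavelengths, "wavelengths")
  check_number(absorbances, "absorbances")
  if (length(wavelengths) != length(absorbances)) {
    pc_schema_abort("wavelengths and absorbances must have equal length")
  }
  if (any(diff(wavelengths) <= 0)) {
    pc_schema_abort("wavelengths must be strictly increasing")
  }
  out <- tibble::tibble(wavelength = wavelengths, absorbance = absorbances)
  class(out) <- c("uv_spectrum", class(tibble::tibble()))
  out
}

#' Read a two-column spectrum CSV
#'
#' @param path CSV with columns `wavelength` (nm) and `absorbance` (AU).
#' @return A [uv_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) {
    pc_schema_abort(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("wavelength", "absorbance") %in% names(raw))) {
    pc_schema_abort("spectrum CSV needs columns `wavelength` and `absorbance`")
  }
  uv_spectrum(raw$wavelength, raw$absorbance)
}
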