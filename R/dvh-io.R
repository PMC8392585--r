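#' DVH CSV dialects
#'
#' Planning systems export DVH tables with varying units and conventions.
#' A dialect declares how to interpret a CSV: which columns hold dose and
#' volume, whether dose is in Gy or cGy, whether volume is absolute (cc) or
#' relative (percent), and whether the curve is cumulative or differential.
#' Relative-volume input requires `total_volume_cc` so the DVH can be
#' normalised to absolute volume.
#'
#' @param units_dose `"Gy"` or `"cGy"`.
#' @param units_volume `"cc"` or `"percent"`.
#' @param form `"cumulative"` or `"differential"`.
#' @param total_volume_cc Total organ volume in cc (required for percent).
#' @param dose_col,volume_col Column names in the CSV.
#' @param organ Organ label attached to the parsed DVH.
#' @return A list of class `dvh_dialect`.
#' @export
dvh_dialect <- function(units_dose = c("Gy", "cGy"),
                        units_volume = c("cc", "percent"),
                        form = c("cumulative", "differential"),
                        total_volume_cc = NULL,
                        dose_col = "dose", volume_col = "volume",
                        organ = "organ") {
  units_dose <- match.arg(units_dose)
  units_volume <- match.arg(units_volume)
  form <- match.arg(form)
  if (units_volume == "percent" && is.null(total_volume_cc)) {
    abort_ntcp("Relative (percent) volume input requires `total_volume_cc` in the dialect.",
               "ntcpxero_io_error")
  }
  structure(
    list(units_dose = units_dose, units_volume = units_volume, form = form,
         total_volume_cc = total_volume_cc, dose_col = dose_col,
         volume_col = volume_col, organ = organ),
    class = "dvh_dialect"
  )
}

#' Read a DVH from CSV
#'
#' Parses a dose/volume table and normalises it to Gy and absolute cc.
#' Invalid curves (non-monotone dose, negative volumes, a cumulative curve
#' that rises with dose) are rejected with the offending row index.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @param dialect A [dvh_dialect()] describing units and form.
#' @return A `dvh`.
#' @export
read_dvh <- function(path, dialect = dvh_dialect()) {
  if (!inherits(dialect, "dvh_dialect")) {
    abort_ntcp("`dialect` must be created with dvh_dialect().", "ntcpxero_io_error")
  }
  tab <- if (is.data.frame(path)) path else utils::read.csv(path, check.names = FALSE)
  for (col in c(dialect$dose_col, dialect$volume_col)) {
    if (!col %in% names(tab)) {
      abort_ntcp(sprintf("Column `%s` not found in DVH table.", col),
                 "ntcpxero_io_error")
    }
  }
  dose <- as.numeric(tab[[dialect$dose_col]])
  vol <- as.numeric(tab[[dialect$volume_col]])
  if (dialect$units_dose == "cGy") dose <- dose / 100
  if (dialect$units_volume == "percent") {
    vol <- vol / 100 * dialect$total_volume_cc
  }
  dvh(dose, vol, organ = dialect$organ, form = dialect$form,
      total_volume = if (dialect$units_volume == "percent") dialect$total_volume_cc else NULL)
}

#' Write a DVH to CSV
#'
#' Writes the curve in Gy / absolute cc; cumulative form writes one row per
#' dose edge, differential form one row per bin lower edge plus the final
#' upper edge with volume 0.
#'
#' @param dvh A `dvh`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  check_dvh(dvh)
  cum <- as_cumulative(dvh)
  utils::write.csv(
    data.frame(dose = cum$dose_edges, volume = cum$volume),
    path, row.names = FALSE
  )
  invisible(path)
}
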