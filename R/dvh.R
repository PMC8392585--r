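#' Dose-volume histogram objects
#'
#' A `dvh` stores one organ's binned dose-volume curve in Gy and absolute
#' cubic centimetres. Two forms are supported:
#'
#' * **cumulative** — one volume per dose edge, giving the volume receiving
#'   at least that dose; the curve is non-increasing and starts at the total
#'   organ volume.
#' * **differential** — one volume per half-open dose bin `(lower, upper]`
#'   (so one fewer value than edges); bin volumes are non-negative and sum
#'   to the total organ volume. The representative dose of a bin is its
#'   arithmetic centre.
#'
#' @param dose_edges Strictly increasing, non-negative dose grid in Gy.
#' @param volume Bin (differential) or edge (cumulative) volumes in cc.
#' @param organ Organ label, e.g. `"cPG"` or `"OC"`.
#' @param form `"cumulative"` or `"differential"`.
#' @param total_volume Total organ volume in cc; defaults to the first
#'   cumulative value or the sum of differential bins.
#'
#' @return An object of class `dvh`.
#' @examples
#' d <- dvh(c(0, 40, 70), c(50, 50, 0), organ = "cPG", form = "cumulative")
#' summarize_dvh(d)
#' @export
dvh <- function(dose_edges, volume, organ = "organ",
                form = c("cumulative", "differential"),
                total_volume = NULL) {
  form <- match.arg(form)
  dose_edges <- as.numeric(dose_edges)
  volume <- as.numeric(volume)
  if (anyNA(dose_edges) || anyNA(volume)) {
    abort_ntcp("DVH dose edges and volumes must not contain missing values.",
               "ntcpxero_dvh_error")
  }
  if (length(dose_edges) < 2L) {
    abort_ntcp("A DVH needs at least two dose edges.", "ntcpxero_dvh_error")
  }
  if (any(dose_edges < 0)) {
    abort_ntcp("Dose edges must be non-negative.", "ntcpxero_dvh_error")
  }
  if (any(diff(dose_edges) <= 0)) {
    bad <- which(diff(dose_edges) <= 0)[1L] + 1L
    abort_ntcp(sprintf("Dose edges must be strictly increasing (violated at row %d).", bad),
               "ntcpxero_dvh_error")
  }
  if (any(volume < -1e-9)) {
    bad <- which(volume < -1e-9)[1L]
    abort_ntcp(sprintf("Volumes must be non-negative (violated at row %d).", bad),
               "ntcpxero_dvh_error")
  }
  volume <- pmax(volume, 0)
  if (form == "cumulative") {
    if (length(volume) != length(dose_edges)) {
      abort_ntcp("Cumulative DVH needs one volume per dose edge.", "ntcpxero_dvh_error")
    }
    inc <- which(diff(volume) > 1e-9)
    if (length(inc)) {
      abort_ntcp(sprintf("Cumulative volume increases with dose at row %d.", inc[1L] + 1L),
                 "ntcpxero_dvh_error")
    }
    total_volume <- total_volume %||% volume[1L]
    if (abs(volume[1L] - total_volume) > 1e-6 * max(1, total_volume)) {
      abort_ntcp("First cumulative volume must equal the total organ volume.",
                 "ntcpxero_dvh_error")
    }
  } else {
    if (length(volume) != length(dose_edges) - 1L) {
      abort_ntcp("Differential DVH needs one volume per bin (edges minus one).",
                 "ntcpxero_dvh_error")
    }
    total_volume <- total_volume %||% sum(volume)
    if (abs(sum(volume) - total_volume) > 1e-6 * max(1, total_volume)) {
      abort_ntcp("Differential bin volumes must sum to the total organ volume.",
                 "ntcpxero_dvh_error")
    }
  }
  structure(
    list(organ = organ, form = form, dose_edges = dose_edges,
         volume = volume, total_volume = total_volume),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s (%s), %.1f cc, %d dose edges [%.2f, %.2f] Gy\n",
              x$organ, x$form, x$total_volume, length(x$dose_edges),
              min(x$dose_edges), max(x$dose_edges)))
  invisible(x)
}

#' @export
as_tibble.dvh <- function(x, ...) {
  if (x$form == "cumulative") {
    tibble::tibble(organ = x$organ, dose = x$dose_edges, volume = x$volume)
  } else {
    k <- length(x$volume)
    tibble::tibble(
      organ = x$organ,
      dose_lo = x$dose_edges[-(k + 1L)],
      dose_hi = x$dose_edges[-1L],
      dose = (x$dose_edges[-(k + 1L)] + x$dose_edges[-1L]) / 2,
      volume = x$volume
    )
  }
}

is_dvh <- function(x) inherits(x, "dvh")

check_dvh <- function(x, arg = "dvh") {
  if (!is_dvh(x)) {
    abort_ntcp(sprintf("`%s` must be a <dvh> object.", arg), "ntcpxero_dvh_error")
  }
  invisible(x)
}

#' Convert a cumulative DVH to differential form
#'
#' Bin volumes are the successive differences of the cumulative curve; any
#' residual cumulative volume at the last edge is treated as mass at that
#' edge and folded into the final bin.
#'
#' @param dvh A cumulative `dvh`.
#' @return A differential `dvh` over the same dose edges.
#' @export
to_differential <- function(dvh) {
  check_dvh(dvh)
  if (dvh$form == "differential") {
    abort_ntcp("DVH is already differential.", "ntcpxero_dvh_error")
  }
  vols <- -diff(dvh$volume)
  # residual volume still present at the last edge: mass at (or above) it
  resid <- dvh$volume[length(dvh$volume)]
  if (resid > 1e-9) vols[length(vols)] <- vols[length(vols)] + resid
  dvh(dvh$dose_edges, vols, organ = dvh$organ, form = "differential",
      total_volume = dvh$total_volume)
}

#' Convert a differential DVH to cumulative form
#'
#' @param dvh A differential `dvh`.
#' @return A cumulative `dvh` over the same dose edges (the last edge gets
#'   volume 0).
#' @export
to_cumulative <- function(dvh) {
  check_dvh(dvh)
  if (dvh$form == "cumulative") {
    abort_ntcp("DVH is already cumulative.", "ntcpxero_dvh_error")
  }
  cum <- rev(cumsum(rev(c(dvh$volume, 0))))
  dvh(dvh$dose_edges, cum, organ = dvh$organ, form = "cumulative",
      total_volume = dvh$total_volume)
}

as_differential <- function(dvh) {
  if (dvh$form == "differential") dvh else to_differential(dvh)
}

as_cumulative <- function(dvh) {
  if (dvh$form == "cumulative") dvh else to_cumulative(dvh)
}

#' Single-bin DVH for a uniformly irradiated organ
#'
#' Convenience constructor placing the whole organ volume in one narrow bin
#' whose centre is exactly `dose`.
#'
#' @param dose Uniform dose in Gy.
#' @param volume Organ volume in cc.
#' @param organ Organ label.
#' @param width Bin width in Gy (default 0.1).
#' @return A differential `dvh`.
#' @export
uniform_dvh <- function(dose, volume, organ = "organ", width = 0.1) {
  lo <- max(dose - width / 2, 0)
  dvh(c(lo, dose + width / 2), volume, organ = organ, form = "differential")
}

# Re-bin a differential DVH onto new edges, distributing each source bin's
# volume over the target bins in proportion to dose-interval overlap
# (uniform density within a bin). Mass outside the target grid is an error.
rebin_dvh <- function(dvh, new_edges) {
  dvh <- as_differential(dvh)
  k <- length(dvh$volume)
  lo <- dvh$dose_edges[-(k + 1L)]
  hi <- dvh$dose_edges[-1L]
  m <- length(new_edges) - 1L
  out <- numeric(m)
  tlo <- new_edges[-(m + 1L)]
  thi <- new_edges[-1L]
  for (i in seq_len(k)) {
    if (dvh$volume[i] == 0) next
    ov <- pmax(0, pmin(hi[i], thi) - pmax(lo[i], tlo))
    tot <- sum(ov)
    if (tot <= 0) {
      abort_ntcp("Source DVH bin falls outside the target dose grid.",
                 "ntcpxero_dvh_error")
    }
    out <- out + dvh$volume[i] * ov / tot
  }
  dvh(new_edges, out, organ = dvh$organ, form = "differential",
      total_volume = dvh$total_volume)
}

#' Combine two organs' DVHs into a single organ at risk
#'
#' Sums absolute volumes on the union of the two dose grids, re-binning each
#' DVH by mass-preserving overlap assignment. Used to form the combined
#' parotid glands (cPG) from left and right glands: the combined organ's
#' total volume is the sum of the two totals and its integral dose
#' (sum of bin volume times bin dose) is conserved.
#'
#' @param left,right `dvh` objects (any form; converted to differential).
#' @param organ Label for the combined organ; defaults to the left label.
#' @return A differential `dvh` on the union dose grid.
#' @examples
#' a <- uniform_dvh(20, 30, "PG_L")
#' b <- uniform_dvh(40, 30, "PG_R")
#' summarize_dvh(combine_organs(a, b, organ = "cPG"))$mean_dose  # 30 Gy
#' @export
combine_organs <- function(left, right, organ = NULL) {
  check_dvh(left, "left"); check_dvh(right, "right")
  left <- as_differential(left)
  right <- as_differential(right)
  if (right$total_volume == 0) {
    out <- left
    out$organ <- organ %||% left$organ
    return(out)
  }
  if (left$total_volume == 0) {
    out <- right
    out$organ <- organ %||% left$organ
    return(out)
  }
  edges <- sort(unique(c(left$dose_edges, right$dose_edges)))
  a <- rebin_dvh(left, edges)
  b <- rebin_dvh(right, edges)
  dvh(edges, a$volume + b$volume, organ = organ %||% left$organ,
      form = "differential",
      total_volume = left$total_volume + right$total_volume)
}

#' Dose covering a given volume fraction (Dx%)
#'
#' The largest dose `D` such that at least `volume_fraction` of the organ
#' receives `D` or more, obtained by linear interpolation on the cumulative
#' curve. `dose_at_volume(d, 0.98)` is the near-minimum dose D98%.
#'
#' @param dvh A `dvh` (differential input is converted internally).
#' @param volume_fraction Fraction of the organ volume, in `(0, 1]`.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_fraction) {
  check_dvh(dvh)
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      is.na(volume_fraction) || volume_fraction <= 0 || volume_fraction > 1) {
    abort_ntcp("`volume_fraction` must be a single number in (0, 1].",
               "ntcpxero_input_error")
  }
  cum <- as_cumulative(dvh)
  if (cum$total_volume <= 0) {
    abort_ntcp("DVH has zero total volume.", "ntcpxero_dvh_error")
  }
  v <- cum$volume / cum$total_volume
  d <- cum$dose_edges
  eps <- 1e-12
  idx <- which(v >= volume_fraction - eps)
  if (!length(idx)) return(d[1L])
  j <- max(idx)
  if (j == length(d) || v[j] - volume_fraction <= eps) return(d[j])
  # interpolate between (d_j, v_j) and (d_{j+1}, v_{j+1})
  d[j] + (d[j + 1L] - d[j]) * (v[j] - volume_fraction) / (v[j] - v[j + 1L])
}

#' Summary dose metrics for one DVH
#'
#' @param dvh A valid `dvh` with positive total volume.
#' @return A one-row tibble with `organ`, `volume_cc`, `mean_dose`
#'   (volume-weighted bin-centre mean), `max_dose` (highest dose edge with
#'   non-zero bin volume), and `d98` (near-minimum dose from
#'   [dose_at_volume()] at 0.98).
#' @export
summarize_dvh <- function(dvh) {
  check_dvh(dvh)
  if (dvh$total_volume <= 0) {
    abort_ntcp("Cannot summarise a DVH with zero total volume.",
               "ntcpxero_dvh_error")
  }
  dd <- as_differential(dvh)
  k <- length(dd$volume)
  centers <- (dd$dose_edges[-(k + 1L)] + dd$dose_edges[-1L]) / 2
  w <- dd$volume / dd$total_volume
  nz <- which(dd$volume > 1e-12)
  tibble::tibble(
    organ = dd$organ,
    volume_cc = dd$total_volume,
    mean_dose = sum(w * centers),
    max_dose = if (length(nz)) dd$dose_edges[max(nz) + 1L] else 0,
    d98 = dose_at_volume(dd, 0.98)
  )
}
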