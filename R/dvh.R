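#' Cumulative dose-volume histogram for one ROI
#'
#' Exact voxel-counting cumulative DVH on a uniform grid: `cum_volume[i]` is
#' the fraction of ROI voxels receiving at least `dose_bins[i]` Gy. The
#' first bin is 0 Gy, so the curve starts at 1 and is non-increasing.
#'
#' @param dose dose `volume_grid` (Gy).
#' @param mask ROI mask `volume_grid`; must be non-empty.
#' @param bin_width histogram bin width in Gy (default 0.1).
#' @param roi ROI name used in error messages.
#' @return object of class `dvh_curve` with `dose_bins` and `cum_volume`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1, roi = "ROI") {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  stop_if_grid_mismatch(dose, mask, "dose and mask")
  d <- dose$values[mask$values > 0]
  if (length(d) == 0)
    stop(sprintf("ROI '%s' has an empty mask; cannot compute a DVH", roi),
         call. = FALSE)
  bins <- seq(0, max(d) + bin_width, by = bin_width)
  cum <- vapply(bins, function(b) mean(d >= b), numeric(1))
  structure(list(dose_bins = bins, cum_volume = cum, roi = roi),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d bins, 0 to %.1f Gy\n",
              x$roi, length(x$dose_bins), max(x$dose_bins)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ...) {
  plot(x$dose_bins, 100 * x$cum_volume, type = "l", xlab = "Dose (Gy)",
       ylab = "Volume (%)", main = x$roi, ...)
  invisible(x)
}

# metric grammar: Dmax | Dmean | D{p}% | V{d} | V{p}% | HI | CI
parse_metric <- function(name) {
  if (name == "Dmax") return(list(kind = "Dmax"))
  if (name == "Dmean") return(list(kind = "Dmean"))
  if (name == "HI") return(list(kind = "HI"))
  if (name == "CI") return(list(kind = "CI"))
  m <- regmatches(name, regexec("^D([0-9]*\\.?[0-9]+)%$", name))[[1]]
  if (length(m) == 2) return(list(kind = "Dpct", p = as.numeric(m[2])))
  m <- regmatches(name, regexec("^V([0-9]*\\.?[0-9]+)%$", name))[[1]]
  if (length(m) == 2) return(list(kind = "Vpct", p = as.numeric(m[2])))
  m <- regmatches(name, regexec("^V([0-9]*\\.?[0-9]+)$", name))[[1]]
  if (length(m) == 2) return(list(kind = "Vdose", d = as.numeric(m[2])))
  stop("cannot parse DVH metric '", name, "'", call. = FALSE)
}

metric_units <- function(name) {
  k <- parse_metric(name)$kind
  switch(k, Dmax = , Dmean = , Dpct = "Gy", Vdose = , Vpct = "%", "")
}

#' Evaluate one DVH endpoint
#'
#' Implements the standard endpoint grammar: `Dmax` and `Dmean` are the
#' hottest / mean ROI voxel dose; `D{p}%` is the dose received by the
#' hottest p% of the ROI volume (linear interpolation between order
#' statistics); `V{d}` and `V{p}%` are the percent of ROI volume receiving
#' at least d Gy / at least p% of the prescription;
#' `HI = (D2% - D98%) / D50%`; `CI` is the Paddick conformity index at the
#' prescription isodose, `TV_PIV^2 / (TV * PIV)` (the RTOG ratio `PIV/TV`
#' is available via `ci_type = "rtog"`).
#'
#' @param dose dose `volume_grid`.
#' @param mask ROI mask `volume_grid`.
#' @param metric metric name string.
#' @param prescription prescription dose in Gy; required for `V{p}%` and `CI`.
#' @param ci_type `"paddick"` (default) or `"rtog"`.
#' @param roi ROI name for error messages.
#' @return numeric scalar (Gy for D-type, percent for V-type, unitless
#'   otherwise).
#' @export
endpoint <- function(dose, mask, metric, prescription = NULL,
                     ci_type = c("paddick", "rtog"), roi = "ROI") {
  ci_type <- match.arg(ci_type)
  pm <- parse_metric(metric)
  d <- dose$values[mask$values > 0]
  if (length(d) == 0)
    stop(sprintf("ROI '%s' has an empty mask", roi), call. = FALSE)
  need_rx <- pm$kind %in% c("Vpct", "CI")
  if (need_rx && is.null(prescription))
    stop("metric '", metric, "' needs a prescription dose", call. = FALSE)
  dpct <- function(p) unname(stats::quantile(d, 1 - p / 100, type = 7))
  switch(pm$kind,
    Dmax = max(d),
    Dmean = mean(d),
    Dpct = dpct(pm$p),
    Vdose = 100 * mean(d >= pm$d),
    Vpct = 100 * mean(d >= pm$p / 100 * prescription),
    HI = (dpct(2) - dpct(98)) / dpct(50),
    CI = {
      piv <- sum(dose$values >= prescription)
      tv <- length(d)
      tv_piv <- sum(d >= prescription)
      if (piv == 0 || tv == 0) 0
      else if (ci_type == "paddick") tv_piv^2 / (tv * piv)
      else piv / tv
    })
}

#' Named endpoint specifications
#'
#' `spec_openkbp()` is the compact dose-score companion set (target D2%,
#' D98%, Dmean; every OAR Dmean and Dmax). `spec_protocol()` mirrors a
#' pelvic VMAT protocol report: full target coverage/conformity metrics and
#' organ-specific V/D endpoints.
#'
#' @return named list mapping ROI to a character vector of metric names.
#' @export
spec_openkbp <- function() {
  oars <- c("Bladder", "Rectum", "SmallIntestine", "SpinalCord", "Marrow",
            "FemoralHeadL", "FemoralHeadR")
  c(list(PTV = c("D2%", "D98%", "Dmean")),
    stats::setNames(rep(list(c("Dmean", "Dmax")), length(oars)), oars))
}

#' @rdname spec_openkbp
#' @export
spec_protocol <- function() {
  list(PTV = c("Dmax", "Dmean", "V95%", "V100%", "D98%", "D2%", "CI", "HI"),
       Bladder = c("Dmean", "V30", "V40", "V45"),
       Rectum = c("Dmean", "V30", "V40", "V45"),
       SmallIntestine = c("Dmax", "Dmean", "V30"),
       SpinalCord = c("Dmax", "Dmean"),
       Marrow = c("Dmean", "V30"),
       FemoralHeadL = c("Dmean", "V30", "V40"),
       FemoralHeadR = c("Dmean", "V30", "V40"))
}

#' Tabulate DVH endpoints for a dose and structure set
#'
#' @param dose dose `volume_grid`.
#' @param structures a [structure_set()].
#' @param spec named list ROI -> metric names (see [spec_openkbp()]).
#' @param prescription prescription dose (Gy).
#' @param ci_type conformity index flavour, see [endpoint()].
#' @return data.frame with columns `roi`, `metric`, `value`, `units`
#'   (an endpoint table).
#' @export
endpoint_table <- function(dose, structures, spec = spec_protocol(),
                           prescription = 45, ci_type = "paddick") {
  missing <- setdiff(names(spec), names(structures))
  if (length(missing))
    stop("structure set lacks ROI(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (roi in names(spec)) {
    for (m in spec[[roi]]) {
      v <- endpoint(dose, roi_mask(structures, roi), m, prescription,
                    ci_type = ci_type, roi = roi)
      rows[[length(rows) + 1L]] <-
        data.frame(roi = roi, metric = m, value = v, units = metric_units(m),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read/write endpoint tables as CSV
#' @param x endpoint table data.frame.
#' @param path file path.
#' @export
write_endpoints <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endpoints
#' @export
read_endpoints <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plan-quality scores between a predicted and a reference dose
#'
#' `dose_score` is the mean absolute voxel difference inside the body (Gy).
#' `dvh_score` is the mean absolute endpoint difference over an endpoint
#' spec (Gy for the default all-dose spec). `sn_dvh_score` divides each
#' endpoint difference by a per-metric scale and sums over the spec's
#' (roi, metric) pairs, making dose (Gy) and volume (%) endpoints
#' commensurate in one dimensionless number per case; default scales are
#' the prescription for D-type metrics, 100 percentage points for V-type,
#' and 1 for the unitless HI/CI.
#'
#' @param pred,ref dose `volume_grid`s on one grid.
#' @param body Body mask `volume_grid`.
#' @return `dose_score`: Gy.
#' @export
dose_score <- function(pred, ref, body) {
  stop_if_grid_mismatch(pred, ref, "pred and ref")
  stop_if_grid_mismatch(pred, body, "dose and body")
  b <- body$values > 0
  if (!any(b)) stop("empty body mask", call. = FALSE)
  mean(abs(pred$values[b] - ref$values[b]))
}

#' @param structures a [structure_set()].
#' @param spec endpoint spec (ROI -> metrics).
#' @param prescription prescription dose (Gy).
#' @rdname dose_score
#' @export
dvh_score <- function(pred, ref, structures, spec = spec_openkbp(),
                      prescription = 45) {
  if (length(spec) == 0) stop("endpoint spec is empty", call. = FALSE)
  tp <- endpoint_table(pred, structures, spec, prescription)
  tr <- endpoint_table(ref, structures, spec, prescription)
  mean(abs(tp$value - tr$value))
}

#' @param scales optional named numeric vector of per-kind scales with names
#'   `D`, `V`, `other`; defaults `c(D = prescription, V = 100, other = 1)`.
#' @rdname dose_score
#' @export
sn_dvh_score <- function(pred, ref, structures, spec = spec_protocol(),
                         prescription = 45, scales = NULL) {
  if (is.null(scales)) scales <- c(D = prescription, V = 100, other = 1)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  tp <- endpoint_table(pred, structures, spec, prescription)
  tr <- endpoint_table(ref, structures, spec, prescription)
  sc <- vapply(tp$metric, function(m) {
    k <- parse_metric(m)$kind
    if (k %in% c("Dmax", "Dmean", "Dpct")) scales[["D"]]
    else if (k %in% c("Vdose", "Vpct")) scales[["V"]]
    else scales[["other"]]
  }, numeric(1))
  sum(abs(tp$value - tr$value) / sc)
}

#' Global gamma analysis
#'
#' Global-normalisation gamma with the dose-difference criterion expressed
#' as a percentage of the reference maximum. Each reference voxel at or
#' above `low_dose_threshold * max(ref)` is evaluated;
#' `gamma = min over displacements r (|r| <= 3 * dta) of
#' sqrt((dose difference / dd)^2 + (|r| / dta)^2)` with the evaluated dose
#' trilinearly interpolated on a 3x refined displacement grid. A voxel
#' passes when gamma <= 1. Normalisation uses the *reference* maximum, so
#' swapping the two doses changes the result slightly; the reference is
#' always the first argument.
#'
#' @param ref reference dose `volume_grid`.
#' @param eval evaluated dose `volume_grid` (same grid).
#' @param dd_percent dose-difference criterion, % of reference max.
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param low_dose_threshold fraction of reference max below which voxels
#'   are excluded (default 0.1).
#' @return `gamma_pass_rate`: percent of evaluated voxels with gamma <= 1.
#'   `gamma_index`: a `volume_grid` of per-voxel gamma (NA where excluded).
#' @export
gamma_pass_rate <- function(ref, eval, dd_percent = 3, dta_mm = 3,
                            low_dose_threshold = 0.1) {
  g <- gamma_index(ref, eval, dd_percent, dta_mm, low_dose_threshold)
  vals <- g$values[!is.na(g$values)]
  100 * mean(vals <= 1)
}

#' @rdname gamma_pass_rate
#' @export
gamma_index <- function(ref, eval, dd_percent = 3, dta_mm = 3,
                        low_dose_threshold = 0.1) {
  stop_if_grid_mismatch(ref, eval, "ref and eval")
  if (dd_percent <= 0 || dta_mm <= 0)
    stop("dd and dta criteria must be > 0", call. = FALSE)
  rmax <- max(ref$values)
  if (rmax <= 0)
    stop("reference dose is identically zero; no voxels above the low-dose threshold",
         call. = FALSE)
  thresh <- low_dose_threshold * rmax
  if (!any(ref$values >= thresh))
    stop("no reference voxels above the low-dose threshold", call. = FALSE)
  g <- cpp_gamma(as.numeric(ref$values), as.numeric(eval$values),
                 dim(ref$values), ref$spacing,
                 dd_percent / 100 * rmax, dta_mm, thresh)
  volume_grid(array(ifelse(is.na(g), NA_real_, g), dim = dim(ref$values)),
              spacing = ref$spacing, origin = ref$origin, kind = "scalar")
}

#' Full score report between predicted and reference dose
#'
#' @inheritParams dose_score
#' @param dvh_spec,sn_spec endpoint specs for the DVH and snDVH scores.
#' @param gamma logical; include the 3%/3 mm gamma pass rate.
#' @return a `score_report` list.
#' @export
score_report <- function(pred, ref, structures, prescription = 45,
                         dvh_spec = spec_openkbp(), sn_spec = spec_protocol(),
                         gamma = FALSE) {
  body <- roi_mask(structures, "Body")
  rep <- list(
    dose_score = dose_score(pred, ref, body),
    dvh_score = dvh_score(pred, ref, structures, dvh_spec, prescription),
    sndvh_score = sn_dvh_score(pred, ref, structures, sn_spec, prescription))
  if (gamma) rep$gamma_pass_3_3 <- gamma_pass_rate(ref, pred)
  tp <- endpoint_table(pred, structures, sn_spec, prescription)
  tr <- endpoint_table(ref, structures, sn_spec, prescription)
  rep$endpoints <- data.frame(roi = tp$roi, metric = tp$metric,
                              pred = tp$value, ref = tr$value,
                              units = tp$units, stringsAsFactors = FALSE)
  class(rep) <- "score_report"
  rep
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("Dose score : %.3f Gy\nDVH score  : %.3f Gy\nsnDVH score: %.4f\n",
              x$dose_score, x$dvh_score, x$sndvh_score))
  if (!is.null(x$gamma_pass_3_3))
    cat(sprintf("Gamma 3%%/3mm pass rate: %.1f%%\n", x$gamma_pass_3_3))
  invisible(x)
}
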