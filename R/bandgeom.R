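#' Directional beam-band mask for one axial slice
#'
#' A beam band at angle `theta` is the corridor between the two lines
#' parallel to the beam direction that are tangent to the target on that
#' slice. A pixel belongs to the band when the projection of its centre onto
#' the unit normal of the beam direction lies within the closed interval
#' spanned by the target pixel-centre projections. An empty target slice
#' yields an empty band.
#'
#' @param ptv_slice 2D binary matrix (target on this slice).
#' @param angle beam angle in degrees, in `[0, 180)`; measured in the axial
#'   plane from the row (anterior-posterior) axis. A band at `theta` equals
#'   the band at `theta + 180`.
#' @param spacing in-plane pixel spacing (dy, dx) in mm.
#' @return binary matrix of the same shape.
#' @export
band_mask_slice <- function(ptv_slice, angle, spacing = c(1, 1)) {
  if (any(spacing[1:2] <= 0)) stop("spacing must be positive", call. = FALSE)
  angle <- angle %% 180
  d <- dim(ptv_slice)
  out <- matrix(0, d[1], d[2])
  in_ptv <- which(ptv_slice > 0, arr.ind = TRUE)
  if (nrow(in_ptv) == 0) return(out)
  ang <- angle * pi / 180
  # beam direction (cos, sin) in physical (row, col); normal (-sin, cos)
  y <- (seq_len(d[1]) - 0.5) * spacing[1]
  x <- (seq_len(d[2]) - 0.5) * spacing[2]
  U <- outer(-sin(ang) * y, cos(ang) * x, `+`)
  up <- U[cbind(in_ptv[, 1], in_ptv[, 2])]
  lo <- min(up); hi <- max(up)
  eps <- 1e-9 * max(1, abs(lo), abs(hi))
  out[U >= lo - eps & U <= hi + eps] <- 1
  out
}

#' Build the k-direction beam-band set for a target volume
#'
#' Band angles are `i * 180 / k` for `i = 0 .. k-1` (so `k = 4` gives the
#' canonical 0/45/90/135 set). Bands are built per axial slice via
#' [band_mask_slice()] and stacked; the union is their voxelwise OR.
#'
#' @param ptv target mask `volume_grid`.
#' @param k number of band directions (>= 1).
#' @param angles optional explicit angle vector (deg) overriding the uniform
#'   set; used by the nested-subset ablation harness.
#' @param clip_body optional Body mask `volume_grid`; when given, bands are
#'   intersected with the body.
#' @return object of class `band_mask_set` with fields `k`, `angles`,
#'   `bands` (list of mask `volume_grid`s) and `union`.
#' @export
make_band_set <- function(ptv, k = 4, angles = NULL, clip_body = NULL) {
  if (is.null(angles)) {
    k <- as.integer(k)
    if (is.na(k) || k < 1) stop("k must be >= 1", call. = FALSE)
    angles <- (seq_len(k) - 1) * 180 / k
  } else {
    k <- length(angles)
    if (k < 1) stop("at least one angle required", call. = FALSE)
  }
  sh <- dim(ptv$values); sp <- ptv$spacing
  bands <- vector("list", k)
  for (b in seq_len(k)) {
    arr <- array(0, dim = sh)
    for (z in seq_len(sh[3]))
      arr[, , z] <- band_mask_slice(ptv$values[, , z], angles[b], sp[1:2])
    if (!is.null(clip_body)) arr <- arr * clip_body$values
    bands[[b]] <- volume_grid(arr, spacing = sp, origin = ptv$origin, kind = "mask")
  }
  un <- Reduce(function(a, b) pmax(a, b$values), bands, accumulate = FALSE,
               init = array(0, dim = sh))
  structure(list(k = k, angles = angles, bands = bands,
                 union = volume_grid(un, spacing = sp, origin = ptv$origin,
                                     kind = "mask")),
            class = "band_mask_set")
}

#' @export
print.band_mask_set <- function(x, ...) {
  cat(sprintf("<band_mask_set> k = %d, angles = %s deg, union %d voxels\n",
              x$k, paste(round(x$angles, 1), collapse = "/"),
              sum(x$union$values)))
  invisible(x)
}

#' Fraction of thresholded dose mass covered by the band union
#'
#' With `T = {dose >= threshold_fraction * max(dose)}`, returns
#' `sum(dose over T and band union) / sum(dose over T)`; 1 when `T` is empty.
#' Used by the band-count ablation as a surrogate for how much of the
#' high-dose corridor structure the bands capture.
#'
#' @param dose dose `volume_grid`.
#' @param bands a `band_mask_set` on the same grid.
#' @param threshold_fraction in `[0, 1)`; default 0.5.
#' @return a number in `[0, 1]`.
#' @export
band_dose_coverage <- function(dose, bands, threshold_fraction = 0.5) {
  stopifnot(inherits(bands, "band_mask_set"))
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in [0, 1)", call. = FALSE)
  stop_if_grid_mismatch(dose, bands$union, "dose and bands")
  d <- dose$values
  hot <- d >= threshold_fraction * max(d)
  denom <- sum(d[hot])
  if (denom == 0) return(1.0)
  sum(d[hot & bands$union$values > 0]) / denom
}
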