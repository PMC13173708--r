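#' Surrogate parallel-ray dose engine
#'
#' Deposits dose along parallel rays at each gantry angle with exponential
#' attenuation in body tissue: the deposit at a voxel is
#' `exp(-mu * depth)` where `depth` is the body path length upstream of the
#' voxel along the beam direction. Dose is linear in the beam weights and
#' zero outside the body. This is a deliberately simple engine whose only
#' job is to give reference doses the directional corridor structure of arc
#' deliveries.
#'
#' @param structures a [structure_set()]; only the Body mask is used.
#' @param beam_weights non-negative weight per angle.
#' @param angles gantry angles in degrees (0 = beam travelling along +row,
#'   i.e. anterior to posterior; measured in the axial plane).
#' @param attenuation_mu linear attenuation coefficient per mm.
#' @param step_mm ray-marching step (mm).
#' @return dose `volume_grid` (arbitrary monitor units before scaling).
#' @export
forward_dose <- function(structures, beam_weights, angles,
                         attenuation_mu = 0.004, step_mm = NULL) {
  if (length(angles) < 1) stop("at least one angle required", call. = FALSE)
  if (length(beam_weights) != length(angles))
    stop("one weight per angle required", call. = FALSE)
  if (any(beam_weights < 0)) stop("beam weights must be >= 0", call. = FALSE)
  body <- roi_mask(structures, "Body")
  sh <- dim(body$values); sp <- body$spacing
  if (is.null(step_mm)) step_mm <- min(sp[1:2]) / 2
  dose <- array(0, dim = sh)
  bmask <- body$values > 0
  for (a in seq_along(angles)) {
    if (beam_weights[a] == 0) next
    dep <- deposit_volume(bmask, sp, angles[a], attenuation_mu, step_mm)
    dose <- dose + beam_weights[a] * dep
  }
  dose[!bmask] <- 0
  volume_grid(dose, spacing = sp, origin = body$origin, kind = "dose")
}

# per-voxel deposit exp(-mu * depth) inside body for one angle
deposit_volume <- function(bmask, spacing, angle_deg, mu, step_mm) {
  sh <- dim(bmask)
  out <- array(0, dim = sh)
  ang <- angle_deg * pi / 180
  for (k in seq_len(sh[3])) {
    b2 <- matrix(as.integer(bmask[, , k]), sh[1], sh[2])
    if (!any(b2 > 0)) next
    depth <- cpp_depth_slice(b2, spacing[1], spacing[2], ang, step_mm)
    sl <- exp(-mu * depth)
    sl[b2 == 0] <- 0
    out[, , k] <- sl
  }
  out
}

#' Beamlet influence model for the inverse optimizer
#'
#' Discretises each gantry angle into lateral beamlet strips and assembles
#' the sparse dose-influence matrix `A` (voxels x beamlets): column
#' `(angle, strip)` holds the exponential-attenuation deposit of that strip's
#' parallel rays at body voxels. `forward_dose` with per-angle weights is
#' the special case of equal weights within each angle.
#'
#' @param structures a [structure_set()].
#' @param config a [phantom_config()] supplying angles, attenuation and the
#'   number of lateral strips per angle.
#' @return list with `A` (a `dgCMatrix`), `angles`, `n_lateral`, `shape`,
#'   `spacing`.
#' @export
beam_geometry <- function(structures, config) {
  body <- roi_mask(structures, "Body")
  sh <- dim(body$values); sp <- body$spacing
  angles <- config$angles
  if (length(angles) < 1) stop("at least one angle required", call. = FALSE)
  nl <- config$n_lateral
  bmask <- body$values > 0
  nvox <- prod(sh)
  step_mm <- min(sp[1:2]) / 2
  # lateral coordinate of each in-plane pixel for a given angle
  y <- (seq_len(sh[1]) - 0.5) * sp[1]
  x <- (seq_len(sh[2]) - 0.5) * sp[2]
  Y2 <- matrix(y, sh[1], sh[2]); X2 <- matrix(x, sh[1], sh[2], byrow = TRUE)
  ii <- jj <- xx <- list(); idx <- 1L
  body_idx <- which(bmask)
  for (a in seq_along(angles)) {
    ang <- angles[a] * pi / 180
    u2 <- -sin(ang) * Y2 + cos(ang) * X2          # lateral axis
    dep <- deposit_volume(bmask, sp, angles[a], config$attenuation_mu, step_mm)
    uvox <- array(rep(u2, sh[3]), dim = sh)
    ub <- uvox[body_idx]
    rng <- range(ub)
    bin <- pmin(pmax(1L, 1L + as.integer(floor((ub - rng[1]) /
                      (diff(rng) / nl + 1e-12)))), nl)
    ii[[idx]] <- body_idx
    jj[[idx]] <- (a - 1L) * nl + bin
    xx[[idx]] <- dep[body_idx]
    idx <- idx + 1L
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nvox, length(angles) * nl))
  list(A = A, angles = angles, n_lateral = nl, shape = sh, spacing = sp)
}
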