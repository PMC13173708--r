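#' Configuration for the pelvic phantom generator
#'
#' The generator emulates a female pelvic geometry at desk scale: an
#' elliptical body per slice, an ellipsoidal central target (PTV), bladder
#' anterior and rectum posterior to it, a midline posterior spinal-cord
#' column, lateral femoral heads, a bony shell standing in for pelvic
#' marrow, and scattered superior/anterior small-intestine blobs.
#'
#' @param shape integer length-3 grid shape (rows, cols, slices); every axis
#'   must be at least 16.
#' @param spacing voxel spacing in mm; default (2.5, 2.5, 5) honours 5-mm
#'   slices at a CPU-friendly in-plane resolution.
#' @param seed integer; fixes all randomness of one case.
#' @param jitter_pos_mm half-width of the uniform positional jitter applied
#'   to organ centres (mm).
#' @param jitter_scale half-width of the uniform relative jitter applied to
#'   organ semi-axes (fraction).
#' @param prescription prescription dose in Gy (45 Gy in 25 fractions).
#' @param hu_noise_sd additive Gaussian CT noise inside the body (HU).
#' @param angles gantry angles (deg) of the discretised arc used by the
#'   reference dose engine.
#' @param attenuation_mu effective linear attenuation per mm of body tissue.
#' @param n_lateral number of lateral beamlet bins per angle.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 32), spacing = c(2.5, 2.5, 5),
                           seed = 1L, jitter_pos_mm = 6, jitter_scale = 0.08,
                           prescription = 45, hu_noise_sd = 20,
                           angles = seq(0, 315, by = 45),
                           attenuation_mu = 0.004, n_lateral = 16) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("grid shape must have 3 axes, each >= 16", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (prescription <= 0) stop("prescription must be > 0", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 seed = as.integer(seed),
                 jitter_pos_mm = jitter_pos_mm, jitter_scale = jitter_scale,
                 prescription = prescription, hu_noise_sd = hu_noise_sd,
                 angles = as.numeric(angles),
                 attenuation_mu = attenuation_mu,
                 n_lateral = as.integer(n_lateral)),
            class = "phantom_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# physical coordinate arrays (mm, voxel centres) for a config grid
coord_arrays <- function(shape, spacing) {
  y <- (seq_len(shape[1]) - 0.5) * spacing[1]
  x <- (seq_len(shape[2]) - 0.5) * spacing[2]
  z <- (seq_len(shape[3]) - 0.5) * spacing[3]
  list(Y = array(rep(y, times = shape[2] * shape[3]), dim = shape),
       X = array(rep(rep(x, each = shape[1]), times = shape[3]), dim = shape),
       Z = array(rep(z, each = shape[1] * shape[2]), dim = shape))
}

ellipsoid_mask <- function(co, centre, semi) {
  ((co$Y - centre[1]) / semi[1])^2 + ((co$X - centre[2]) / semi[2])^2 +
    ((co$Z - centre[3]) / semi[3])^2 <= 1
}

#' Generate one pelvic phantom case
#'
#' @param config a [phantom_config()].
#' @return list with elements `ct` (a `volume_grid`, HU) and `structures`
#'   (a [structure_set()]). Identical config (including seed) gives
#'   bitwise-identical output; with both jitter ranges at zero the geometry
#'   is independent of the seed.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  sh <- config$shape; sp <- config$spacing
  ext <- sh * sp
  co <- coord_arrays(sh, sp)
  with_seed(config$seed, {
    jp <- function(n = 3) stats::runif(n, -config$jitter_pos_mm, config$jitter_pos_mm)
    js <- function(n = 3) 1 + stats::runif(n, -config$jitter_scale, config$jitter_scale)
    cy <- ext[1] / 2; cx <- ext[2] / 2; cz <- ext[3] / 2
    # scale anatomy to the physical extent so small grids stay anatomical
    sy <- ext[1] / 160; sx <- ext[2] / 160; sz <- ext[3] / 160
    body_semi <- c(0.44 * ext[1], 0.47 * ext[2])
    body <- ((co$Y - cy) / body_semi[1])^2 + ((co$X - cx) / body_semi[2])^2 <= 1

    ptv_c <- c(cy + 5 * sy, cx, cz) + jp()
    ptv_semi <- c(30 * sy, 35 * sx, 45 * sz) * js()
    ptv <- ellipsoid_mask(co, ptv_c, ptv_semi) & body

    bla_c <- c(cy - 32 * sy, cx, cz - 5 * sz) + jp()
    bla_semi <- c(18 * sy, 20 * sx, 24 * sz) * js()
    bladder <- ellipsoid_mask(co, bla_c, bla_semi) & body

    rec_c <- c(cy + 40 * sy, cx, cz) + c(jp(2), 0)
    rec_r <- c(11 * sy, 11 * sx) * js(2)
    rectum <- (((co$Y - rec_c[1]) / rec_r[1])^2 +
               ((co$X - rec_c[2]) / rec_r[2])^2 <= 1) &
      co$Z > 0.2 * ext[3] & co$Z < 0.85 * ext[3] & body

    cord_c <- c(cy + 56 * sy, cx) + jp(2) * 0.3
    cord <- (((co$Y - cord_c[1]) / (5 * sy))^2 +
             ((co$X - cord_c[2]) / (5 * sx))^2 <= 1) & body

    fem_r <- 17 * js(1)[1]
    femL <- ellipsoid_mask(co, c(cy + 12 * sy, cx - 57 * sx, cz - 5 * sz) + jp(),
                           c(fem_r * sy, fem_r * sx, fem_r * sz)) & body
    fem_r2 <- 17 * js(1)[1]
    femR <- ellipsoid_mask(co, c(cy + 12 * sy, cx + 57 * sx, cz - 5 * sz) + jp(),
                           c(fem_r2 * sy, fem_r2 * sx, fem_r2 * sz)) & body

    # marrow as the posterior part of a bony shell just inside the body surface
    rr <- ((co$Y - cy) / body_semi[1])^2 + ((co$X - cx) / body_semi[2])^2
    marrow <- rr <= 0.95 & rr >= 0.72 & co$Y > cy & body

    # small intestine: a few superior / anterior blobs
    intest <- array(FALSE, dim = sh)
    for (b in 1:3) {
      cb <- c(cy - 40 * sy, cx + (b - 2) * 32 * sx, 0.82 * ext[3]) + jp()
      rb <- 12.5 * js(1)[1]
      intest <- intest | ellipsoid_mask(co, cb, c(rb * sy, rb * sx, rb * sz))
    }
    intest <- intest & body

    ct_vals <- array(-1000, dim = sh)
    ct_vals[body] <- 0
    bone <- (marrow | femL | femR) & body
    ct_vals[bone] <- 700
    noise <- array(stats::rnorm(prod(sh), 0, config$hu_noise_sd), dim = sh)
    ct_vals[body] <- ct_vals[body] + noise[body]

    as_mask <- function(m) volume_grid(array(as.numeric(m), dim = sh),
                                       spacing = sp, kind = "mask")
    structures <- structure_set(list(
      PTV = as_mask(ptv), Bladder = as_mask(bladder), Rectum = as_mask(rectum),
      SmallIntestine = as_mask(intest), SpinalCord = as_mask(cord),
      Marrow = as_mask(marrow), FemoralHeadL = as_mask(femL),
      FemoralHeadR = as_mask(femR), Body = as_mask(body)))
    list(ct = volume_grid(ct_vals, spacing = sp, kind = "scalar"),
         structures = structures)
  })
}

#' Generate a reference plan dose for a phantom case
#'
#' Runs the surrogate inverse optimizer with default clinical-style
#' objectives (target coverage and uniformity, organ-at-risk mean/max
#' limits) over the beamlet model, then rescales so the PTV mean dose equals
#' the prescription. The beamlet weights used are attached as attribute
#' `"weights"`; if the optimizer flags non-convergence the result carries
#' attribute `"converged" = FALSE` rather than failing silently.
#'
#' @param ct CT `volume_grid` (unused by the surrogate engine; accepted for
#'   interface symmetry).
#' @param structures a [structure_set()].
#' @param config the case's [phantom_config()].
#' @return dose `volume_grid` in Gy, zero outside the body.
#' @export
generate_reference_plan <- function(ct, structures, config) {
  rx <- config$prescription
  objectives <- default_plan_objectives(rx)
  geom <- beam_geometry(structures, config)
  fit <- optimize_beamlets(objectives, structures, geom,
                           prescription = rx, seed = config$seed)
  w <- fit$weights
  dvec <- as.numeric(geom$A %*% w)
  ptv <- roi_mask(structures, "PTV")$values > 0
  m <- mean(dvec[ptv])
  if (m <= 0) stop("reference optimization produced zero target dose", call. = FALSE)
  dvec <- dvec * (rx / m)
  dose <- volume_grid(array(dvec, dim = config$shape), spacing = config$spacing,
                      kind = "dose")
  attr(dose, "weights") <- w * (rx / m)
  attr(dose, "converged") <- fit$converged
  dose
}

# clinical-style default objectives used to build reference plans
default_plan_objectives <- function(rx) {
  list(
    objective("PTV", "target_min_dvh", "D98%", 0.97 * rx, weight = 60),
    objective("PTV", "target_uniformity", "Dmax", 1.04 * rx, weight = 40),
    objective("Bladder", "oar_mean", "Dmean", 0.62 * rx, weight = 2),
    objective("Rectum", "oar_mean", "Dmean", 0.60 * rx, weight = 2),
    objective("SmallIntestine", "oar_mean", "Dmean", 0.45 * rx, weight = 2),
    objective("SpinalCord", "oar_max", "Dmax", 0.80 * rx, weight = 4),
    objective("FemoralHeadL", "oar_mean", "Dmean", 0.55 * rx, weight = 1),
    objective("FemoralHeadR", "oar_mean", "Dmean", 0.55 * rx, weight = 1),
    objective("Marrow", "oar_mean", "Dmean", 0.80 * rx, weight = 0.5)
  )
}

#' Generate a cohort of phantom cases on disk
#'
#' Writes `n` cases (CT, nine structure masks, reference dose, each as
#' `.nii.gz`) plus a JSON manifest assigning a deterministic
#' train/validation/test split at an 8:1:1 ratio (each split gets at least
#' one case).
#'
#' @param n number of cases (>= 3).
#' @param config base [phantom_config()]; case `i` uses seed
#'   `config$seed + i`.
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest list.
#' @export
generate_cohort <- function(n, config, dir) {
  if (n < 3) stop("a cohort needs n >= 3 so each split is non-empty", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create cohort directory: ", dir, call. = FALSE)
  n_val <- max(1L, as.integer(round(n / 10)))
  n_test <- max(1L, as.integer(round(n / 10)))
  n_train <- n - n_val - n_test
  split <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  cases <- list()
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    ph <- generate_phantom(cfg_i)
    dose <- generate_reference_plan(ph$ct, ph$structures, cfg_i)
    id <- sprintf("case%03d", i)
    cdir <- file.path(dir, id)
    dir.create(cdir, showWarnings = FALSE)
    write_volume(ph$ct, file.path(cdir, "ct.nii.gz"))
    write_volume(dose, file.path(cdir, "dose.nii.gz"))
    for (nm in names(ph$structures))
      write_volume(ph$structures$masks[[nm]],
                   file.path(cdir, paste0("mask_", nm, ".nii.gz")))
    cases[[i]] <- list(id = id, split = split[i], seed = cfg_i$seed,
                       converged = isTRUE(attr(dose, "converged")))
  }
  manifest <- list(n = n, seed = config$seed, shape = config$shape,
                   spacing = config$spacing, prescription = config$prescription,
                   angles = config$angles, attenuation_mu = config$attenuation_mu,
                   n_lateral = config$n_lateral, cases = cases)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(read_manifest(dir))
}

#' Read a cohort manifest or one case back from disk
#'
#' @param dir cohort directory written by [generate_cohort()].
#' @return `read_manifest`: the manifest list; `read_case`: a list with
#'   `ct`, `structures`, `dose`.
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}

#' @param id case identifier, e.g. `"case001"`.
#' @rdname read_manifest
#' @export
read_case <- function(dir, id) {
  cdir <- file.path(dir, id)
  ct <- read_volume(file.path(cdir, "ct.nii.gz"), kind = "scalar")
  dose <- read_volume(file.path(cdir, "dose.nii.gz"), kind = "dose")
  masks <- lapply(canonical_rois(), function(nm)
    read_volume(file.path(cdir, paste0("mask_", nm, ".nii.gz")), kind = "mask"))
  names(masks) <- canonical_rois()
  list(ct = ct, structures = structure_set(masks), dose = dose)
}
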