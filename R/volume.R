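#' 3D scalar volume on a regular grid
#'
#' A `volume_grid` carries one 3D scalar field together with its voxel
#' spacing and origin. It is the common carrier for CT (HU), dose (Gy) and
#' binary masks. Axis order is fixed as (row, column, slice): the first two
#' array dimensions span the axial plane, the third indexes slices.
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (dy, dx, dz); must be
#'   strictly positive.
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @param kind one of `"scalar"`, `"dose"`, `"mask"`; dose enforces
#'   non-negativity, mask enforces values in \{0, 1\}.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(2.5, 2.5, 5), origin = c(0, 0, 0),
                        kind = c("scalar", "dose", "mask")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  storage.mode(values) <- "double"
  if (kind == "dose" && any(values < 0))
    stop("dose values must be >= 0", call. = FALSE)
  if (kind == "mask" && !all(values %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin,
                 kind = kind),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid [%s]> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Check two volumes share one grid
#'
#' @param a,b `volume_grid` objects.
#' @param tol spacing/origin tolerance in mm.
#' @keywords internal
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (shape/spacing/origin differ)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored one channel per `.nii.gz` file. Spacing is carried in
#' the NIfTI header (pixdim); the origin in the sform translation.
#'
#' @param x a `volume_grid`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   `volume_grid`.
#' @export
write_volume <- function(x, path) {
  stopifnot(is_volume_grid(x))
  img <- RNifti::asNifti(x$values)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param kind volume kind to restore (`read_volume` cannot infer it).
#' @rdname write_volume
#' @export
read_volume <- function(path, kind = "scalar") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (kind == "mask") vals <- round(vals)
  volume_grid(vals, spacing = RNifti::pixdim(img)[1:3], kind = kind)
}

#' Resample a volume to a fixed shape
#'
#' Trilinear (scalar/dose) or nearest-neighbour (mask) resampling onto a new
#' grid covering the same physical extent. Utility for standardising external
#' volumes to the model's input dimensions; phantom-generated cases never
#' need it.
#'
#' @param x a `volume_grid`.
#' @param shape integer length-3 target shape.
#' @return a `volume_grid` on the new grid.
#' @export
resample_volume <- function(x, shape) {
  stopifnot(is_volume_grid(x), length(shape) == 3L, all(shape >= 2))
  d <- dim(x$values)
  extent <- d * x$spacing
  new_sp <- extent / shape
  # target voxel centres in source fractional index space
  centre <- function(n, sp) (seq_len(n) - 0.5) * sp
  src_idx <- lapply(1:3, function(a) centre(shape[a], new_sp[a]) / x$spacing[a] + 0.5)
  nearest <- x$kind == "mask"
  out <- array(0, dim = shape)
  i1 <- src_idx[[1]]; i2 <- src_idx[[2]]; i3 <- src_idx[[3]]
  if (nearest) {
    r1 <- pmin(pmax(round(i1), 1), d[1])
    r2 <- pmin(pmax(round(i2), 1), d[2])
    r3 <- pmin(pmax(round(i3), 1), d[3])
    out <- x$values[r1, r2, r3, drop = FALSE]
    dim(out) <- shape
  } else {
    out <- trilinear_sample(x$values, i1, i2, i3)
  }
  volume_grid(out, spacing = new_sp, origin = x$origin, kind = x$kind)
}

# Separable trilinear sampling of `arr` at the index grid i1 x i2 x i3
# (1-based fractional indices, clamped to the volume).
trilinear_sample <- function(arr, i1, i2, i3) {
  d <- dim(arr)
  clamp <- function(v, n) pmin(pmax(v, 1), n)
  lo <- function(v, n) pmin(pmax(floor(v), 1), n)
  w <- function(v, l) v - l
  l1 <- lo(clamp(i1, d[1]), d[1] - 1); f1 <- w(clamp(i1, d[1]), l1)
  l2 <- lo(clamp(i2, d[2]), d[2] - 1); f2 <- w(clamp(i2, d[2]), l2)
  l3 <- lo(clamp(i3, d[3]), d[3] - 1); f3 <- w(clamp(i3, d[3]), l3)
  out <- array(0, dim = c(length(i1), length(i2), length(i3)))
  for (c3 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    w3 <- if (c3 == 0) 1 - f3 else f3
    w2 <- if (c2 == 0) 1 - f2 else f2
    w1 <- if (c1 == 0) 1 - f1 else f1
    sub <- arr[l1 + c1, l2 + c2, l3 + c3, drop = FALSE]
    ww <- outer(outer(w1, w2), w3)
    out <- out + sub * ww
  }
  out
}

canonical_rois <- function() {
  c("PTV", "Bladder", "Rectum", "SmallIntestine", "SpinalCord",
    "Marrow", "FemoralHeadL", "FemoralHeadR", "Body")
}

#' Named set of binary structure masks
#'
#' Holds the nine canonical pelvic ROIs (PTV, seven organs at risk, Body) as
#' binary [volume_grid()]s on one common grid, in a fixed canonical order.
#'
#' @param masks named list of binary `volume_grid`s; must contain exactly the
#'   canonical ROIs (any order; stored canonically).
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(masks) {
  want <- canonical_rois()
  if (!setequal(names(masks), want))
    stop("structure_set needs exactly these ROIs: ", paste(want, collapse = ", "),
         call. = FALSE)
  masks <- masks[want]
  for (nm in want) {
    m <- masks[[nm]]
    if (!is_volume_grid(m) || m$kind != "mask")
      stop("ROI '", nm, "' is not a mask volume_grid", call. = FALSE)
    stop_if_grid_mismatch(masks[[1]], m, paste0("masks (", nm, ")"))
  }
  body <- masks$Body$values
  if (sum(masks$PTV$values) == 0) stop("PTV mask is empty", call. = FALSE)
  for (nm in setdiff(want, "Body")) {
    if (any(masks[[nm]]$values > body))
      stop("ROI '", nm, "' extends outside Body", call. = FALSE)
  }
  structure(list(masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> ROIs:\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-15s %d voxels\n", nm, sum(x$masks[[nm]]$values)))
  invisible(x)
}

#' @export
names.structure_set <- function(x) names(x$masks)

roi_mask <- function(structures, roi) {
  m <- structures$masks[[roi]]
  if (is.null(m)) stop("ROI '", roi, "' not present in structure set", call. = FALSE)
  m
}
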