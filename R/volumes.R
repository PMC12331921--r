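#' Geometry-aware 3D volume container
#'
#' A `vol_grid` couples a 3D scalar field with its physical voxel spacing
#' (mm) and origin, so that every geometric operation in the package
#' (margin expansion, resampling, surface distances) can work in physical
#' millimetres rather than voxel units. Binary masks are `vol_grid`s whose
#' values are restricted to \{0, 1\}.
#'
#' @param values a 3D numeric array.
#' @param spacing per-axis voxel size in mm (length 3, strictly positive).
#' @param origin physical coordinate of the centre of voxel (1,1,1), mm.
#' @return An object of class `vol_grid`.
#' @export
vol_grid <- function(values, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel sizes in mm")
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "vol_grid"
  )
}

#' @export
dim.vol_grid <- function(x) dim(x$values)

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf(
    "<vol_grid> %s voxels @ %s mm%s\n",
    paste(dim(x$values), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    if (is_binary_values(x$values)) sprintf(" [mask, %d voxels set]", sum(x$values)) else ""
  ))
  invisible(x)
}

is_binary_values <- function(v) {
  all(v == 0 | v == 1)
}

#' Coerce to a binary mask
#'
#' Binarizes at > 0.5, keeping the grid geometry. Used both at NIfTI ingest
#' (where masks may be stored as 0/255) and to harden probability fields.
#'
#' @param v a `vol_grid` or 3D array.
#' @inheritParams vol_grid
#' @export
as_mask <- function(v, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  if (!inherits(v, "vol_grid")) v <- vol_grid(v, spacing, origin)
  v$values <- array(as.numeric(v$values > 0.5), dim(v$values))
  v
}

#' @rdname as_mask
#' @export
is_mask <- function(v) inherits(v, "vol_grid") && is_binary_values(v$values)

#' Number of set voxels / physical volume of a mask
#' @param m a binary `vol_grid`.
#' @export
n_voxels <- function(m) sum(m$values > 0.5)

#' @rdname n_voxels
#' @export
mask_volume_mm3 <- function(m) n_voxels(m) * prod(m$spacing)

same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_geometry <- function(..., .names = NULL) {
  vols <- list(...)
  if (is.null(.names)) .names <- paste0("volume", seq_along(vols))
  ref <- vols[[1]]
  for (i in seq_along(vols)[-1]) {
    if (!same_geometry(ref, vols[[i]])) {
      stop("geometry mismatch: '", .names[i], "' does not share the grid of '",
           .names[1], "'")
    }
  }
  invisible(TRUE)
}

new_like <- function(v, values) {
  vol_grid(array(values, dim(v$values)), v$spacing, v$origin)
}

# ---- mask set algebra (values stay in {0,1}) --------------------------

#' Mask set operations
#'
#' Voxelwise union, intersection, difference and complement of binary
#' masks sharing one grid.
#' @param a,b,m,within binary `vol_grid`s on the same grid.
#' @name mask-algebra
NULL

#' @rdname mask-algebra
#' @export
mask_union <- function(a, b) {
  check_geometry(a, b, .names = c("a", "b"))
  new_like(a, as.numeric(a$values > 0.5 | b$values > 0.5))
}

#' @rdname mask-algebra
#' @export
mask_intersect <- function(a, b) {
  check_geometry(a, b, .names = c("a", "b"))
  new_like(a, as.numeric(a$values > 0.5 & b$values > 0.5))
}

#' @rdname mask-algebra
#' @export
mask_subtract <- function(a, b) {
  check_geometry(a, b, .names = c("a", "b"))
  new_like(a, as.numeric(a$values > 0.5 & b$values <= 0.5))
}

#' @rdname mask-algebra
#' @export
mask_complement <- function(m, within) {
  check_geometry(m, within, .names = c("m", "within"))
  new_like(m, as.numeric(within$values > 0.5 & m$values <= 0.5))
}

# ---- NIfTI I/O --------------------------------------------------------

#' Read / write NIfTI volumes
#'
#' Thin wrappers over \pkg{RNifti} that enforce the package's container
#' contract: 3D payloads only, spacing taken from the header, masks
#' binarized at > 0.5 on read.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask binarize the payload on read?
#' @return `read_volume()` returns a `vol_grid`.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)) # drop RNifti header attributes
  if (length(dim(arr)) > 3L) {
    if (all(dim(arr)[-(1:3)] == 1L)) {
      arr <- array(arr, dim(arr)[1:3])
    } else {
      stop("non-3D payload in NIfTI file: ", path)
    }
  }
  if (length(dim(arr)) != 3L) stop("non-3D payload in NIfTI file: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  v <- vol_grid(arr, abs(sp), org)
  if (mask) v <- as_mask(v)
  v
}

#' @rdname read_volume
#' @param v a `vol_grid` to write.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "vol_grid"))
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- resampling -------------------------------------------------------

#' Resample a volume to a new voxel spacing
#'
#' Continuous channels are interpolated trilinearly; masks use
#' nearest-neighbour so values stay binary. The physical extent of the
#' field is preserved to within one voxel.
#'
#' @param v a `vol_grid`.
#' @param target_spacing new per-axis spacing in mm.
#' @param is_mask use nearest-neighbour interpolation and return a mask?
#' @export
resample_to_grid <- function(v, target_spacing, is_mask = FALSE) {
  stopifnot(inherits(v, "vol_grid"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (any(target_spacing <= 0)) stop("`target_spacing` must be positive")
  din <- dim(v$values)
  if (any(din == 0)) stop("degenerate (zero-size) input volume")
  if (all(abs(target_spacing - v$spacing) < 1e-9)) return(v)
  dout <- pmax(1L, as.integer(round(din * v$spacing / target_spacing)))
  # output voxel-centre positions in input index space (1-based)
  axpos <- lapply(1:3, function(ax) {
    ((seq_len(dout[ax]) - 0.5) * target_spacing[ax]) / v$spacing[ax] + 0.5
  })
  if (is_mask) {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(axpos[[ax]]), 1L), din[ax]))
    out <- v$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out <- array(as.numeric(out > 0.5), dout)
  } else {
    lo <- lapply(1:3, function(ax) pmin(pmax(floor(axpos[[ax]]), 1L), din[ax]))
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1L, din[ax]))
    fr <- lapply(1:3, function(ax) pmin(pmax(axpos[[ax]] - lo[[ax]], 0), 1))
    out <- array(0, dout)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      ix <- if (cx == 0) lo[[1]] else hi[[1]]
      iy <- if (cy == 0) lo[[2]] else hi[[2]]
      iz <- if (cz == 0) lo[[3]] else hi[[3]]
      w <- outer(outer(wx, wy), wz)
      out <- out + w * v$values[ix, iy, iz, drop = FALSE]
    }
  }
  vol_grid(out, target_spacing, v$origin)
}

# ---- normalization ----------------------------------------------------

#' Min-max normalize a channel within a mask
#'
#' Maps the within-mask minimum to 0 and maximum to 1; voxels outside the
#' mask are set to 0. This is the per-case normalization applied to every
#' model input channel.
#'
#' @param v a `vol_grid` channel.
#' @param within binary `vol_grid`, typically the brain mask.
#' @export
minmax_normalize <- function(v, within) {
  check_geometry(v, within, .names = c("v", "within"))
  sel <- within$values > 0.5
  if (sum(sel) < 2L) stop("normalization mask must contain at least 2 voxels")
  x <- v$values[sel]
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot min-max normalize a constant field")
  out <- array(0, dim(v$values))
  out[sel] <- (x - rng[1]) / (rng[2] - rng[1])
  new_like(v, out)
}

# ---- physical-distance morphology ------------------------------------

#' Distance map to a mask, in mm
#'
#' Euclidean distance from every voxel centre to the nearest set voxel
#' centre of `m`, computed with an anisotropy-aware distance transform.
#'
#' @param m a nonempty binary `vol_grid`.
#' @export
distance_map_mm <- function(m) {
  stopifnot(is_mask(m))
  dsq <- edt_sq_cpp(as.numeric(m$values), dim(m$values), m$spacing)
  new_like(m, sqrt(dsq))
}

#' Uniform margin expansion of a mask
#'
#' Grows `m` by `margin_mm` in every direction: the result contains every
#' voxel whose centre lies within `margin_mm` (Euclidean, physical mm) of
#' some set voxel centre of `m`, intersected with `clip`. This is the
#' margin-growing operator behind the geometric CTV definitions and the
#' 4 cm analysis band.
#'
#' @param m nonempty binary `vol_grid`.
#' @param margin_mm margin in mm, >= 0.
#' @param clip binary `vol_grid` the expansion is clipped to (brain mask
#'   for CTVs); `NULL` for no clipping.
#' @export
isotropic_expand <- function(m, margin_mm, clip = NULL) {
  stopifnot(inherits(m, "vol_grid"))
  if (n_voxels(m) == 0) stop("cannot expand an empty mask")
  if (margin_mm < 0) stop("`margin_mm` must be >= 0")
  d <- distance_map_mm(m)
  out <- new_like(m, as.numeric(d$values <= margin_mm + 1e-9))
  if (!is.null(clip)) out <- mask_intersect(out, clip)
  out
}

#' Gaussian smoothing of a scalar field
#'
#' Separable Gaussian filter with sigma given in voxels per axis; used by
#' the synthetic generator for lesion blobs and correlated noise.
#' @param v a `vol_grid`.
#' @param sigma_vox scalar or length-3 sigma in voxels.
#' @export
smooth_field <- function(v, sigma_vox) {
  stopifnot(inherits(v, "vol_grid"))
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3)
  new_like(v, gauss_smooth_cpp(as.numeric(v$values), dim(v$values),
                               as.numeric(sigma_vox)))
}

#' Connected components of a mask
#'
#' @param m binary `vol_grid`.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return A `vol_grid` of integer labels, 0 = background.
#' @export
label_mask_components <- function(m, connectivity = 26) {
  stopifnot(is_mask(m), connectivity %in% c(6, 26))
  new_like(m, label_components_cpp(as.numeric(m$values), dim(m$values),
                                   as.integer(connectivity)))
}

#' Fill internal holes of a mask
#'
#' Background components (6-connectivity) that do not touch the array
#' boundary are folded into the mask.
#' @param m binary `vol_grid`.
#' @export
fill_holes <- function(m) {
  stopifnot(is_mask(m))
  bg <- new_like(m, as.numeric(m$values <= 0.5))
  lab <- label_components_cpp(bg$values, dim(bg$values), 6L)
  d <- dim(lab)
  border <- unique(c(
    lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
    lab[, , 1], lab[, , d[3]]
  ))
  hole <- lab != 0 & !(lab %in% border)
  new_like(m, as.numeric(m$values > 0.5 | hole))
}

#' Surface voxels of a mask (6-connectivity)
#'
#' A set voxel belongs to the surface when at least one of its six face
#' neighbours is background or lies outside the array.
#' @param m binary `vol_grid`.
#' @export
surface_voxels <- function(m) {
  stopifnot(is_mask(m))
  v <- m$values > 0.5
  d <- dim(v)
  inside <- array(TRUE, d)
  shift_ok <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    else { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      v[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1)) inside <- inside & shift_ok(ax, by)
  new_like(m, as.numeric(v & !inside))
}
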