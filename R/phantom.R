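#' Digital breast phantom specification
#'
#' Describes a two-breast digital phantom: grid geometry, two half-ellipsoid
#' breasts attached to a chest-wall slab, and a per-voxel fibroglandular
#' volume-fraction (composition) model. The phantom stands in for a scanned
#' volunteer: its per-voxel water fraction is known exactly, so the whole
#' measurement pipeline can be validated against ground truth.
#'
#' Breasts are half-ellipsoids anterior to the chest-wall coronal plane
#' (axis 2); the plane index marks the most anterior pectoral position, and
#' voxels with coronal index `< chest_wall_plane_index` are anterior to it.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing_mm numeric length-3, mm.
#' @param breast_semi_axes_mm numeric length-3: right-left, antero-posterior
#'   and supero-inferior semi-axes of each breast ellipsoid, in mm.
#' @param breast_offset_mm lateral distance from the midsagittal plane to
#'   each breast centre, in mm.
#' @param chest_wall_plane_index 1-based coronal slice index of the most
#'   anterior pectoral position; breast tissue lies strictly anterior to it.
#' @param chest_wall_thickness_mm thickness of the chest-wall slab.
#' @param composition list describing the fibroglandular fraction field:
#'   `list(type = "uniform", fraction = f)`,
#'   `list(type = "blobs", fraction = f, scale_mm = s)` (smoothed random
#'   field thresholded at the `1 - f` quantile, giving near-binary
#'   fibroglandular clusters occupying a proportion `f` of each breast), or
#'   `list(type = "field", v = <array>)` with an explicit per-voxel field.
#' @param chest_wall_fraction water fraction assigned to chest-wall voxels
#'   (muscle is mostly water).
#' @param noise_sd complex-noise standard deviation as a fraction of the mean
#'   tissue in-phase magnitude (0 = noise free).
#' @param bias_field either `"none"` or a named list of first/second-order
#'   polynomial coefficients (see [evaluate_bias_field()]).
#' @param rng_seed integer seed; phantom generation and acquisition noise are
#'   deterministic given the seed.
#' @return a `PhantomSpec` list.
#' @export
phantom_spec <- function(grid_shape = c(96L, 64L, 64L),
                         voxel_spacing_mm = c(1.3, 1.3, 1.0),
                         breast_semi_axes_mm = c(26, 45, 26),
                         breast_offset_mm = 28,
                         chest_wall_plane_index = 48L,
                         chest_wall_thickness_mm = 15,
                         composition = list(type = "blobs", fraction = 0.35,
                                            scale_mm = 8),
                         chest_wall_fraction = 0.7,
                         noise_sd = 0.02,
                         bias_field = "none",
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  stopifnot(length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0))
  if (any(breast_semi_axes_mm <= 0)) stop("breast semi-axes must be positive")
  if (chest_wall_plane_index < 2L || chest_wall_plane_index > grid_shape[2])
    stop("chest_wall_plane_index outside the grid")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = voxel_spacing_mm,
                 breast_semi_axes_mm = as.numeric(breast_semi_axes_mm),
                 breast_offset_mm = as.numeric(breast_offset_mm),
                 chest_wall_plane_index = as.integer(chest_wall_plane_index),
                 chest_wall_thickness_mm = as.numeric(chest_wall_thickness_mm),
                 composition = composition,
                 chest_wall_fraction = as.numeric(chest_wall_fraction),
                 noise_sd = as.numeric(noise_sd),
                 bias_field = bias_field,
                 rng_seed = as.integer(rng_seed)),
            class = "PhantomSpec")
}

# Label codes used throughout: 0 background, 1 left breast, 2 right breast,
# 3 chest wall. Axis 1 runs right-to-left, so low indices are the patient's
# right side.
LABEL_BACKGROUND <- 0L
LABEL_BREAST_L <- 1L
LABEL_BREAST_R <- 2L
LABEL_CHEST_WALL <- 3L

#' Generate a digital breast phantom
#'
#' Builds the label field (left/right breast, chest wall, background) and the
#' per-voxel fibroglandular volume fraction `v` in `[0, 1]` from a
#' [phantom_spec()]. `v` is zero outside tissue. Deterministic given the
#' spec's `rng_seed`.
#'
#' @param spec a `PhantomSpec`.
#' @return a `Phantom`: list with `v` (3D array), `labels` (3D integer
#'   array), `spacing_mm`, `chest_wall_plane_index`, `spec`, and
#'   `true_fgt_percent` (named vector for sides `"L"` and `"R"`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  ax <- spec$breast_semi_axes_mm
  extent <- d * sp

  cx <- .axis_centres(d[1], sp[1])
  cy <- .axis_centres(d[2], sp[2])
  cz <- .axis_centres(d[3], sp[3])
  mid_x <- extent[1] / 2
  wall_y <- (spec$chest_wall_plane_index - 1) * sp[2]  # anterior face of the cut plane
  ctr_z <- extent[3] / 2

  centres_x <- c(R = mid_x - spec$breast_offset_mm, L = mid_x + spec$breast_offset_mm)
  for (side in c("R", "L")) {
    x0 <- centres_x[[side]]
    if (x0 - ax[1] < 0 || x0 + ax[1] > extent[1] ||
        wall_y - ax[2] < 0 || ctr_z - ax[3] < 0 || ctr_z + ax[3] > extent[3])
      stop("breast ", side, " geometry exceeds the grid; shrink the semi-axes ",
           "or enlarge the grid")
  }

  X <- array(cx, dim = d)
  Y <- array(rep(cy, each = d[1]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)

  labels <- array(LABEL_BACKGROUND, dim = d)
  anterior <- Y < wall_y
  for (side in c("R", "L")) {
    x0 <- centres_x[[side]]
    inside <- ((X - x0) / ax[1])^2 + ((Y - wall_y) / ax[2])^2 +
      ((Z - ctr_z) / ax[3])^2 <= 1
    lab <- if (side == "L") LABEL_BREAST_L else LABEL_BREAST_R
    labels[inside & anterior] <- lab
  }
  wall <- Y >= wall_y & Y < wall_y + spec$chest_wall_thickness_mm
  labels[wall] <- LABEL_CHEST_WALL

  breast <- labels == LABEL_BREAST_L | labels == LABEL_BREAST_R
  v <- array(0, dim = d)
  comp <- spec$composition
  set.seed(spec$rng_seed)
  if (identical(comp$type, "uniform")) {
    f <- comp$fraction
    if (f < 0 || f > 1) stop("uniform fraction must be in [0, 1]")
    v[breast] <- f
  } else if (identical(comp$type, "blobs")) {
    f <- comp$fraction
    if (f < 0 || f > 1) stop("blob fraction must be in [0, 1]")
    field <- .smooth_random_field(d, sp, scale_mm = comp$scale_mm %||% 8)
    field <- field / stats::sd(field)
    cw <- comp$central_weight %||% 1
    # fibroglandular tissue clusters centrally (retroareolar); bias the
    # field towards each breast's centroid so low-density phantoms still
    # carry glandular tissue at the breast centre, then threshold each
    # breast at its own 1-f quantile so both sides hit the target fraction
    for (lab in c(LABEL_BREAST_L, LABEL_BREAST_R)) {
      sel <- labels == lab
      if (!any(sel)) next
      ctr <- c(mean(X[sel]), mean(Y[sel]), mean(Z[sel]))
      r2 <- ((X[sel] - ctr[1]) / ax[1])^2 + ((Y[sel] - ctr[2]) / ax[2])^2 +
        ((Z[sel] - ctr[3]) / ax[3])^2
      fb <- field[sel] + cw * (1 - 2 * r2)
      thr <- stats::quantile(fb, probs = 1 - f, names = FALSE)
      v[sel] <- as.numeric(fb > thr)
    }
  } else if (identical(comp$type, "field")) {
    vin <- comp$v
    if (!identical(dim(vin), as.integer(d))) stop("composition field dims must match the grid")
    if (any(vin < 0 | vin > 1)) stop("composition field must lie in [0, 1]")
    v[breast] <- vin[breast]
  } else {
    stop("unknown composition model: ", comp$type)
  }
  v[wall & !breast] <- spec$chest_wall_fraction

  ph <- structure(list(v = v, labels = labels, spacing_mm = sp,
                       chest_wall_plane_index = spec$chest_wall_plane_index,
                       spec = spec),
                  class = "Phantom")
  ph$true_fgt_percent <- c(L = true_fgt_percent(ph, "L"),
                           R = true_fgt_percent(ph, "R"))
  ph
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-smoothed white noise via FFT; periodic boundary is harmless here
# because only values inside the breast are thresholded.
.smooth_random_field <- function(d, spacing, scale_mm) {
  n <- prod(d)
  noise <- array(stats::rnorm(n), dim = d)
  kern <- lapply(1:3, function(a) {
    x <- c(0:(d[a] %/% 2), -((d[a] - d[a] %/% 2 - 1):1)) * spacing[a]
    k <- exp(-0.5 * (x / scale_mm)^2)
    k / sum(k)
  })
  K <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  dim(K) <- d
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(K), inverse = TRUE)) / n
  sm
}

#' Ground-truth percent fibroglandular tissue of one breast
#'
#' The exact %FGT implied by the phantom's composition field: 100 times the
#' mean fibroglandular volume fraction over the voxels carrying that side's
#' breast label.
#'
#' @param phantom a `Phantom`.
#' @param side `"L"` or `"R"`.
#' @return percent FGT (scalar).
#' @export
true_fgt_percent <- function(phantom, side = c("L", "R")) {
  side <- match.arg(side)
  lab <- if (side == "L") LABEL_BREAST_L else LABEL_BREAST_R
  sel <- phantom$labels == lab
  if (!any(sel)) stop("phantom has no voxels labelled breast ", side)
  100 * mean(phantom$v[sel])
}

#' @export
print.Phantom <- function(x, ...) {
  cat("<Phantom> ", paste(dim(x$v), collapse = " x "), " voxels @ ",
      paste(signif(x$spacing_mm, 4), collapse = " x "), " mm\n",
      "  true %FGT: L = ", round(x$true_fgt_percent[["L"]], 2),
      ", R = ", round(x$true_fgt_percent[["R"]], 2), "\n", sep = "")
  invisible(x)
}

#' Save a phantom's ground truth to disk
#'
#' Writes the fraction field and label field as NIfTI and a JSON sidecar
#' with the spec, seed and true per-breast %FGT.
#'
#' @param phantom a `Phantom`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisible character vector of the files written.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fv <- file.path(dir, paste0(stem, "_v.nii.gz"))
  fl <- file.path(dir, paste0(stem, "_labels.nii.gz"))
  fj <- file.path(dir, paste0(stem, ".json"))
  write_volume(volume_image(phantom$v, phantom$spacing_mm), fv)
  write_volume(volume_image(phantom$labels + 0.0, phantom$spacing_mm), fl)
  side <- list(spec = unclass(phantom$spec[setdiff(names(phantom$spec), "composition")]),
               composition_type = phantom$spec$composition$type,
               rng_seed = phantom$spec$rng_seed,
               true_fgt_percent = as.list(phantom$true_fgt_percent))
  jsonlite::write_json(side, fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fv, fl, fj))
}
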