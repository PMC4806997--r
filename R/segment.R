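#' Segmentation masks
#'
#' A `SegmentationMask` is a logical 3D grid plus its voxel spacing, the
#' laterality it covers, the posterior coronal cut index (voxels with
#' coronal index `< posterior_cut_index` are kept; `NA` if no cut applied)
#' and the provenance of the thresholding.
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel spacing, mm.
#' @param laterality `"L"`, `"R"` or `"both"`.
#' @param posterior_cut_index 1-based coronal cut index or `NA`.
#' @param provenance list (threshold used, erosion iterations, ...).
#' @return a `SegmentationMask`.
#' @export
segmentation_mask <- function(mask, spacing_mm, laterality = "both",
                              posterior_cut_index = NA_integer_,
                              provenance = list()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  structure(list(mask = mask, spacing_mm = as.numeric(spacing_mm),
                 laterality = laterality,
                 posterior_cut_index = posterior_cut_index,
                 provenance = provenance),
            class = "SegmentationMask")
}

#' Mask volume in cm^3
#' @param mask a `SegmentationMask`.
#' @return voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$mask) * voxel_volume_mm3(mask$spacing_mm) / 1000
}

# --- 3D binary morphology, 6-connected cross structuring element ----------

.shift3d <- function(x, axis, by, fill) {
  d <- dim(x)
  out <- array(fill, dim = d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
  else if (by < 0) { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  do.call(`[<-`, c(list(out), idx_dst,
                   list(do.call(`[`, c(list(x), idx_src, list(drop = FALSE))))))
}

#' 6-connected binary erosion / dilation
#'
#' One iteration erodes (dilates) with the 3D cross structuring element:
#' a voxel survives erosion if it and its six face neighbours are all true
#' (out-of-grid neighbours count as false).
#'
#' @param x logical 3D array.
#' @param iterations non-negative integer.
#' @return logical 3D array.
#' @export
binary_erode <- function(x, iterations = 1L) {
  for (i in seq_len(iterations)) {
    acc <- x
    for (axis in 1:3) for (by in c(-1L, 1L))
      acc <- acc & .shift3d(x, axis, by, FALSE)
    x <- acc
  }
  x
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(x, iterations = 1L) {
  for (i in seq_len(iterations)) {
    acc <- x
    for (axis in 1:3) for (by in c(-1L, 1L))
      acc <- acc | .shift3d(x, axis, by, FALSE)
    x <- acc
  }
  x
}

#' Largest 6-connected component of a binary volume
#'
#' Components are found on the face-adjacency graph of the true voxels
#' (via igraph); returns the mask restricted to the largest one.
#'
#' @param x logical 3D array with at least one true voxel.
#' @return logical 3D array.
#' @export
largest_component <- function(x) {
  comp <- .component_labels(x)
  sizes <- tabulate(comp[comp > 0L], nbins = max(comp))
  array(comp == which.max(sizes), dim = dim(x))
}

# Integer component-id array (0 = background) for a logical 3D mask, on the
# 6-neighbour face-adjacency graph of its true voxels.
.component_labels <- function(x) {
  idx <- which(x)
  if (length(idx) == 0L) stop("empty mask has no components")
  d <- dim(x)
  lin <- array(0L, dim = d)
  lin[idx] <- seq_along(idx)
  edges <- integer(0)
  for (axis in 1:3) {
    nb <- .shift3d(lin, axis, 1L, 0L)   # neighbour id shifted by +1 along axis
    both <- lin > 0L & nb > 0L
    if (any(both)) edges <- c(edges, rbind(lin[both], nb[both]))
  }
  out <- array(0L, dim = d)
  if (length(edges) == 0L) {
    out[idx] <- seq_along(idx)  # all voxels isolated
    return(out)
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  cc <- igraph::components(g)
  out[idx] <- as.integer(cc$membership)
  out
}

#' Otsu threshold of an image histogram
#'
#' Maximises between-class variance over a 256-bin histogram of the finite
#' values; used as the automatic option standing in for interactive
#' signal-intensity thresholding.
#'
#' @param x numeric values.
#' @param nbins histogram bins.
#' @return threshold on the original intensity scale.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1] == r[2]) stop("cannot threshold a constant image")
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  # the criterion is flat across an empty gap between modes; centre it
  at_max <- which(bc >= max(bc) - 1e-12 * max(bc))
  mids[as.integer(round(mean(range(at_max))))]
}

#' Body mask by thresholding and despeckling
#'
#' Reproduces threshold-based external-contour delineation: voxels at or
#' above the threshold are kept, and background noise specks are removed by
#' erosion-based despeckling: `erosion_iters` iterations of 6-connected
#' erosion define the object cores, and the connected component of the
#' thresholded mask with the largest surviving core is retained with its
#' original thresholded boundary intact (so the skin layer survives).
#' Components that erode away completely - isolated noise voxels and thin
#' specks - are discarded.
#'
#' @param in_phase a `VolumeImage` (typically the in-phase magnitude).
#' @param threshold numeric intensity threshold, or `"auto"` for Otsu.
#' @param erosion_iters non-negative integer.
#' @return a `SegmentationMask` covering both breasts and chest, with the
#'   threshold and iteration count in `provenance`.
#' @export
body_mask <- function(in_phase, threshold = "auto", erosion_iters = 1L) {
  stopifnot(inherits(in_phase, "VolumeImage"))
  x <- in_phase$data
  if (is.complex(x)) x <- Mod(x)
  thr <- if (identical(threshold, "auto")) otsu_threshold(x) else as.numeric(threshold)
  m <- x >= thr
  if (!any(m))
    stop("threshold ", signif(thr, 4), " leaves an empty mask; lower it ",
         "(image maximum is ", signif(max(x), 4), ")")
  if (erosion_iters > 0L) {
    core <- binary_erode(m, erosion_iters)
    if (!any(core))
      stop("erosion removed every voxel; reduce erosion_iters")
    comp <- .component_labels(m)
    core_sizes <- tabulate(comp[core], nbins = max(comp))
    m <- array(comp == which.max(core_sizes), dim = dim(m))
  } else {
    m <- largest_component(m)
  }
  segmentation_mask(m, in_phase$spacing_mm, laterality = "both",
                    provenance = list(threshold = thr,
                                      erosion_iters = as.integer(erosion_iters)))
}

#' Pectoral coronal cut and midsagittal split
#'
#' Removes every voxel at or posterior to the straight coronal cut placed at
#' the most anterior pectoral position (this also bounds the mask superiorly
#' and inferiorly through the breast contour), then splits the remainder at
#' the midsagittal plane into right and left breast masks. Axis 1 runs
#' right-to-left: sagittal indices `<= split_index` form the right breast.
#'
#' @param mask a `SegmentationMask`.
#' @param cut_index 1-based coronal index of the cut; voxels with coronal
#'   index `< cut_index` are kept.
#' @param split_index 1-based sagittal index of the last right-side column;
#'   defaults to the grid midline.
#' @return list with elements `L` and `R`, each a `SegmentationMask`.
#' @export
pectoral_cut_and_split <- function(mask, cut_index,
                                   split_index = NULL) {
  stopifnot(inherits(mask, "SegmentationMask"))
  d <- dim(mask$mask)
  cut_index <- as.integer(cut_index)
  if (cut_index < 1L || cut_index > d[2] + 1L)
    stop("cut index outside the grid")
  split_index <- as.integer(split_index %||% (d[1] %/% 2L))
  m <- mask$mask
  if (cut_index <= d[2]) m[, cut_index:d[2], ] <- FALSE
  if (!any(m)) stop("the pectoral cut removed the whole mask")
  mr <- m; mr[(split_index + 1L):d[1], , ] <- FALSE
  ml <- m; ml[1:split_index, , ] <- FALSE
  make <- function(mm, side) {
    if (!any(mm)) stop("no voxels on side ", side, " after the midsagittal split")
    segmentation_mask(mm, mask$spacing_mm, laterality = side,
                      posterior_cut_index = cut_index,
                      provenance = c(mask$provenance,
                                     list(split_index = split_index)))
  }
  list(L = make(ml, "L"), R = make(mr, "R"))
}

# --- mutual-information rigid translation ---------------------------------

.mi_bits <- function(a, b, nbins = 32L) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) stop("degenerate (constant) image in registration")
  ia <- pmin(nbins, 1L + floor((a - ra[1]) / diff(ra) * nbins))
  ib <- pmin(nbins, 1L + floor((b - rb[1]) / diff(rb) * nbins))
  j <- tabulate((ia - 1L) * nbins + ib, nbins * nbins)
  p <- j / sum(j)
  px <- rowSums(matrix(p, nbins, nbins, byrow = TRUE))
  py <- colSums(matrix(p, nbins, nbins, byrow = TRUE))
  nz <- p > 0
  sum(p[nz] * log(p[nz])) - sum(px[px > 0] * log(px[px > 0])) -
    sum(py[py > 0] * log(py[py > 0]))
}

.overlap_mi <- function(fixed, moving, s, nbins = 32L) {
  d <- dim(fixed)
  lo <- pmax(1L, 1L + s); hi <- pmin(d, d + s)
  if (any(lo > hi)) return(-Inf)
  f <- fixed[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  m <- moving[(lo[1] - s[1]):(hi[1] - s[1]),
              (lo[2] - s[2]):(hi[2] - s[2]),
              (lo[3] - s[3]):(hi[3] - s[3])]
  .mi_bits(as.vector(f), as.vector(m), nbins)
}

#' Rigid translation by mutual-information grid search
#'
#' Finds the translation (mm) mapping `moving` into `fixed` by maximising
#' the 32-bin joint-histogram mutual information over integer voxel shifts
#' within `search_radius_mm`, followed by per-axis quadratic (parabolic)
#' sub-voxel refinement. Both volumes must share one grid spacing. Mutual
#' information is invariant to monotone intensity remapping, so volumes of
#' different contrast register correctly.
#'
#' @param fixed,moving `VolumeImage`s on grids of equal spacing and shape.
#' @param search_radius_mm scalar search radius, mm.
#' @return a `RigidShift`: numeric length-3 translation in mm (class
#'   `"RigidShift"`), with the attained mutual information in `attr(, "mi")`.
#' @export
register_translation <- function(fixed, moving, search_radius_mm = 5) {
  stopifnot(inherits(fixed, "VolumeImage"), inherits(moving, "VolumeImage"))
  if (!identical(dim(fixed$data), dim(moving$data)) ||
      max(abs(fixed$spacing_mm - moving$spacing_mm)) > 1e-9)
    stop("registration expects volumes on one grid")
  f <- fixed$data; m <- moving$data
  if (is.complex(f)) f <- Mod(f)
  if (is.complex(m)) m <- Mod(m)
  sp <- fixed$spacing_mm
  rad <- pmax(0L, as.integer(floor(search_radius_mm / sp)))
  grid <- expand.grid(x = -rad[1]:rad[1], y = -rad[2]:rad[2], z = -rad[3]:rad[3])
  mi <- vapply(seq_len(nrow(grid)), function(i)
    .overlap_mi(f, m, as.integer(grid[i, ])), numeric(1))
  best <- as.integer(grid[which.max(mi), ])
  # parabolic refinement axis by axis around the best integer shift
  refine <- numeric(3)
  for (axis in 1:3) {
    s0 <- best
    mi0 <- .overlap_mi(f, m, s0)
    sm <- s0; sm[axis] <- sm[axis] - 1L
    sp1 <- s0; sp1[axis] <- sp1[axis] + 1L
    mim <- .overlap_mi(f, m, sm); mip <- .overlap_mi(f, m, sp1)
    denom <- mim - 2 * mi0 + mip
    refine[axis] <- if (is.finite(denom) && denom < 0)
      0.5 * (mim - mip) / denom else 0
    refine[axis] <- max(-0.5, min(0.5, refine[axis]))
  }
  shift <- (best + refine) * sp
  structure(shift, class = "RigidShift", mi = max(mi))
}

#' Transfer a mask onto another grid after a rigid shift
#'
#' Nearest-neighbour resampling: a target voxel is inside the transferred
#' mask if its physical centre, moved by `shift`, falls in a true voxel of
#' the source mask. `shift` is the translation returned by
#' [register_translation()] (moving-to-fixed, mm); pass the target grid of
#' the moving image to carry a mask drawn on the fixed image onto it. The
#' posterior cut index is transformed consistently.
#'
#' @param mask a `SegmentationMask` (on the fixed grid).
#' @param shift a `RigidShift` or numeric length-3, mm.
#' @param target_dim integer length-3 target grid shape.
#' @param target_spacing_mm numeric length-3 target spacing, mm.
#' @return a `SegmentationMask` on the target grid.
#' @export
transfer_mask <- function(mask, shift, target_dim, target_spacing_mm) {
  stopifnot(inherits(mask, "SegmentationMask"))
  shift <- as.numeric(shift)
  if (length(shift) != 3L || any(!is.finite(shift))) stop("shift must be 3 finite mm values")
  d <- dim(mask$mask)
  td <- as.integer(target_dim); tsp <- as.numeric(target_spacing_mm)
  idx <- lapply(1:3, function(a) {
    pos <- .axis_centres(td[a], tsp[a]) + shift[a]
    round(pos / mask$spacing_mm[a] + 0.5)
  })
  X <- array(idx[[1]], dim = td)
  Y <- array(rep(idx[[2]], each = td[1]), dim = td)
  Z <- array(rep(idx[[3]], each = td[1] * td[2]), dim = td)
  ok <- X >= 1 & X <= d[1] & Y >= 1 & Y <= d[2] & Z >= 1 & Z <= d[3]
  out <- array(FALSE, dim = td)
  out[ok] <- mask$mask[cbind(X[ok], Y[ok], Z[ok])]
  if (!any(out)) stop("mask transfer produced an empty mask")
  cut <- mask$posterior_cut_index
  if (!is.na(cut)) {
    cut_mm <- (cut - 1) * mask$spacing_mm[2] - shift[2]
    cut <- as.integer(round(cut_mm / tsp[2] + 1))
  }
  segmentation_mask(out, tsp, laterality = mask$laterality,
                    posterior_cut_index = cut,
                    provenance = c(mask$provenance, list(shift_mm = shift)))
}
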