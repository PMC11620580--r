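#' Binary colony mask
#'
#' A strict 0/1 pixel matrix with a physical pixel size. The matrix is indexed
#' `[x, y]` with the y axis pointing up, so angles about the centroid follow
#' the mathematical convention (anticlockwise from +x). [read_mask()] and
#' [write_mask()] convert to and from the top-down row order of image files.
#'
#' @param pixels matrix of 0/1 (logical or numeric accepted).
#' @param px_size physical side length of one pixel (um), default 1.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, px_size = 1) {
  stopifnot(is.matrix(pixels), px_size > 0)
  if (is.logical(pixels)) pixels <- pixels + 0L
  vals <- unique(as.vector(pixels))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be strictly binary (0/1)")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, px_size = px_size), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px (%.3g um/px), %d occupied\n",
              nrow(x$pixels), ncol(x$pixels), x$px_size, sum(x$pixels)))
  invisible(x)
}

.as_mask_matrix <- function(img) {
  if (inherits(img, "binary_mask")) img$pixels else {
    binary_mask(img)$pixels
  }
}

#' Threshold a grayscale image to a binary mask
#'
#' Global thresholding by maximising the between-class variance of the
#' grey-level histogram (Otsu's criterion). Dark pixels are taken as occupied;
#' the polarity is auto-detected from the image border, which is presumed to be
#' background. Already-binary input is returned unchanged.
#'
#' @param gray numeric matrix of grey levels (any range).
#' @param px_size physical pixel size passed through to [binary_mask()].
#' @return A [binary_mask()]; the threshold used is stored in attribute
#'   `"threshold"`.
#' @export
binarize <- function(gray, px_size = 1) {
  stopifnot(is.matrix(gray))
  vals <- unique(as.vector(gray))
  if (all(vals %in% c(0, 1)))
    return(binary_mask(gray, px_size = px_size))
  rng <- range(gray)
  if (rng[1] == rng[2])
    stop("cannot binarize a constant image")

  nbin <- 256L
  cuts <- seq(rng[1], rng[2], length.out = nbin + 1L)
  h <- tabulate(pmin(pmax(findInterval(gray, cuts, all.inside = TRUE), 1L),
                     nbin), nbin)
  mids <- (cuts[-1] + cuts[-(nbin + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  mu0 <- cumsum(h * mids) / pmax(w0, 1)
  mu1 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w1, 1)
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(between)
  thr <- cuts[k + 1L]

  low <- gray <= thr
  border <- c(gray[1, ], gray[nrow(gray), ], gray[, 1], gray[, ncol(gray)])
  # dark = occupied unless the border (background) is predominantly dark
  occupied <- if (mean(border <= thr) > 0.5) !low else low
  out <- binary_mask(occupied + 0L, px_size = px_size)
  attr(out, "threshold") <- thr
  out
}

# occupied-pixel geometry shared by all statistics
.mask_geometry <- function(M) {
  occ <- which(M == 1L, arr.ind = TRUE)
  N <- nrow(occ)
  if (N == 0L) stop("mask has no occupied pixels")
  centroid <- colMeans(occ)
  d <- sqrt((occ[, 1] - centroid[1])^2 + (occ[, 2] - centroid[2])^2)
  r_max <- max(d)
  if (r_max == 0)
    stop("mask has a single occupied pixel; radii are undefined")
  list(occ = occ, N = N, centroid = unname(centroid), d = d, r_max = r_max,
       rho_csr = N / (pi * r_max^2))
}

#' Centroid, maximum radius and reference density of a mask
#'
#' The centroid is the mean of the occupied pixel coordinates, `r_max` the
#' maximum centroid-to-occupied-pixel distance, and `rho_csr = N / (pi r_max^2)`
#' the occupied-pixel density a colony of the same area would have if spread
#' uniformly over the disk of radius `r_max` (complete spatial randomness).
#'
#' @param img a [binary_mask()] or 0/1 matrix.
#' @return List with `centroid` (pixel coordinates), `r_max`, `rho_csr`, `N`.
#' @export
centroid_and_radii <- function(img) {
  g <- .mask_geometry(.as_mask_matrix(img))
  list(centroid = g$centroid, r_max = g$r_max, rho_csr = g$rho_csr, N = g$N)
}

# radial occupancy density in unit-pixel annuli about the centroid
.radial_profile <- function(M, g) {
  K <- max(1L, as.integer(ceiling(g$r_max)))
  bin <- function(d) pmin(pmax(ceiling(d), 1), K)
  occ_k <- tabulate(bin(g$d), K)
  dx2 <- (seq_len(nrow(M)) - g$centroid[1])^2
  dy2 <- (seq_len(ncol(M)) - g$centroid[2])^2
  dall <- sqrt(outer(dx2, dy2, "+"))
  tot_k <- tabulate(bin(dall[dall <= K]), K)
  dens <- ifelse(tot_k > 0, occ_k / tot_k, 0)
  list(mid = seq_len(K) - 0.5, dens = dens)
}

.csr_radius_impl <- function(M, g, quiet = FALSE) {
  prof <- .radial_profile(M, g)
  dens <- prof$dens
  rho <- g$rho_csr
  K <- length(dens)
  cross <- which(dens[-K] >= rho & dens[-1] < rho)
  if (length(cross) == 0L) {
    if (!any(dens >= rho) && !quiet)
      warning("radial density never reaches rho_csr; returning r_max")
    return(g$r_max)
  }
  k <- max(cross)
  r <- prof$mid[k] + (dens[k] - rho) / (dens[k] - dens[k + 1])
  min(max(r, .Machine$double.eps), g$r_max)
}

#' Complete-spatial-randomness radius
#'
#' Computes the radial occupancy density in unit-pixel-width annuli about the
#' centroid and returns the outermost radius at which the density crosses from
#' `>= rho_csr` to `< rho_csr`, linearly interpolated between annulus
#' midpoints and clamped to `(0, r_max]`. If the density never reaches
#' `rho_csr` (e.g. an ideal filled disk, whose lattice pixel count slightly
#' exceeds `pi r_max^2`), `r_max` is returned with a warning.
#'
#' @inheritParams centroid_and_radii
#' @return The radius `r_csr` in pixels.
#' @export
csr_radius <- function(img) {
  M <- .as_mask_matrix(img)
  .csr_radius_impl(M, .mask_geometry(M))
}

#' Radius ratio and filamentous area ratio
#'
#' `radius_ratio()` returns `I_R = r_csr / r_max`, the fraction of the colony
#' radius occupied by the compact, Eden-like core. `filament_area_ratio()`
#' returns `I_F`, the fraction of occupied pixels lying in the annulus
#' `[r_csr, r_max]` (pixels exactly at `r_csr` count as filament).
#'
#' @inheritParams centroid_and_radii
#' @return A scalar in `(0, 1]` for `I_R`, in `[0, 1]` for `I_F`.
#' @export
radius_ratio <- function(img) {
  M <- .as_mask_matrix(img)
  g <- .mask_geometry(M)
  .csr_radius_impl(M, g) / g$r_max
}

#' @rdname radius_ratio
#' @export
filament_area_ratio <- function(img) {
  M <- .as_mask_matrix(img)
  g <- .mask_geometry(M)
  r_csr <- .csr_radius_impl(M, g)
  sum(g$d >= r_csr) / g$N
}

#' Skeletonize a binary mask
#'
#' Iterative Zhang-Suen morphological thinning to 1-px-wide, 8-connected
#' curves. The skeleton is a subset of the input mask and thinning is
#' idempotent.
#'
#' @inheritParams centroid_and_radii
#' @return A [binary_mask()] containing the skeleton.
#' @export
skeletonize <- function(img) {
  px <- if (inherits(img, "binary_mask")) img$px_size else 1
  binary_mask(cpp_thin(.as_mask_matrix(img)), px_size = px)
}

# count of 8-neighbours that are skeleton pixels, for every pixel
.neighbour_count <- function(M) {
  nx <- nrow(M); ny <- ncol(M)
  P <- matrix(0L, nx + 2L, ny + 2L)
  P[2:(nx + 1L), 2:(ny + 1L)] <- M
  cnt <- matrix(0L, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    cnt <- cnt + P[(2:(nx + 1L)) + di, (2:(ny + 1L)) + dj]
  }
  cnt
}

# count skeleton branch segments: delete branch points (>= 3 skeleton
# neighbours), label 8-connected components, keep those >= min_px pixels
.count_segments <- function(skel, min_px = 3L) {
  if (sum(skel) == 0L) return(0L)
  keep <- skel == 1L & .neighbour_count(skel) < 3L
  lab <- cpp_label8(keep + 0L)
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0L]) >= min_px)
}

#' Sub-branch count of the filamentous region
#'
#' Removes the compact core (occupied pixels closer than `r_csr` to the
#' centroid), skeletonizes the remaining filamentous region by morphological
#' thinning, restricts the skeleton to the quadrant with radius in
#' `[r_csr, r_max]` and angle in `[pi/2, pi]` (anticlockwise from +x, y up),
#' deletes branch-point pixels (>= 3 skeleton neighbours within the quadrant),
#' and counts the remaining 8-connected segments of at least `min_px` pixels.
#' Only one quadrant is counted, mirroring how experimental colony branch
#' counts are taken.
#'
#' @inheritParams centroid_and_radii
#' @param min_px minimum segment length in pixels (default 3); shorter
#'   segments are thinning artefacts and are discarded.
#' @return Integer branch count `I_B >= 0`.
#' @export
sub_branch_count <- function(img, min_px = 3L) {
  M <- .as_mask_matrix(img)
  g <- .mask_geometry(M)
  r_csr <- .csr_radius_impl(M, g)
  .sub_branch_impl(M, g, r_csr, min_px)
}

.sub_branch_impl <- function(M, g, r_csr, min_px = 3L) {
  dx2 <- (seq_len(nrow(M)) - g$centroid[1])^2
  dy2 <- (seq_len(ncol(M)) - g$centroid[2])^2
  dall <- sqrt(outer(dx2, dy2, "+"))
  fil <- M
  fil[dall < r_csr] <- 0L
  if (sum(fil) == 0L) return(0L)
  skel <- cpp_thin(fil)
  ang <- atan2(outer(rep(1, nrow(M)), seq_len(ncol(M)) - g$centroid[2]),
               outer(seq_len(nrow(M)) - g$centroid[1], rep(1, ncol(M))))
  quad <- skel == 1L & dall >= r_csr & dall <= g$r_max &
    ang >= pi / 2 & ang <= pi
  .count_segments(quad + 0L, min_px = min_px)
}

#' Summary statistics of a colony mask
#'
#' Computes the three morphology statistics in one pass: the sub-branch count
#' `I_B`, the filamentous area ratio `I_F` and the radius ratio `I_R`, along
#' with the underlying centroid, radii and pixel count. Deterministic for a
#' fixed mask.
#'
#' @inheritParams sub_branch_count
#' @return An object of class `colony_stats`: a list with elements `I_B`,
#'   `I_F`, `I_R`, `r_csr`, `r_max`, `rho_csr`, `centroid` and `N`.
#' @export
#' @examples
#' m <- make_fixture("disk", radius = 60)
#' summarise_mask(m)
summarise_mask <- function(img, min_px = 3L) {
  M <- .as_mask_matrix(img)
  g <- .mask_geometry(M)
  r_csr <- .csr_radius_impl(M, g, quiet = TRUE)
  structure(list(I_B = .sub_branch_impl(M, g, r_csr, min_px),
                 I_F = sum(g$d >= r_csr) / g$N,
                 I_R = r_csr / g$r_max,
                 r_csr = r_csr, r_max = g$r_max, rho_csr = g$rho_csr,
                 centroid = g$centroid, N = g$N),
            class = "colony_stats")
}

#' @export
print.colony_stats <- function(x, ...) {
  cat(sprintf("<colony_stats> I_B = %d, I_F = %.4f, I_R = %.4f (r_csr = %.1f, r_max = %.1f px, N = %d)\n",
              x$I_B, x$I_F, x$I_R, x$r_csr, x$r_max, x$N))
  invisible(x)
}

#' @export
as.double.colony_stats <- function(x, ...) {
  c(I_B = x$I_B, I_F = x$I_F, I_R = x$I_R)
}
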