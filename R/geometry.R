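#' Cell-type parameters
#'
#' Defines the ellipse dimensions and budding angle of one of the two yeast
#' cell types. Sated cells are short (aspect ratio ~1.4) and bud near-laterally
#' (large `beta`); pseudohyphal cells are elongated (aspect ratio ~3.5) and bud
#' near their poles (small `beta`), which drives filament formation.
#'
#' @param label `"sated"` or `"pseudohyphal"`.
#' @param half_length ellipse radius along the cell axis (major radius), in um.
#' @param half_width ellipse radius perpendicular to the axis (minor radius), um.
#' @param beta budding angle in radians, measured from the cell axis; must lie
#'   strictly between 0 and pi/2.
#' @return An object of class `cell_type`.
#' @seealso [default_cell_types()] for the standard dimensions.
#' @export
#' @examples
#' cell_type("sated", 4.2, 3, 7 * pi / 16)
cell_type <- function(label = c("sated", "pseudohyphal"),
                      half_length, half_width, beta) {
  label <- match.arg(label)
  stopifnot(is.numeric(half_length), half_length > 0,
            is.numeric(half_width), half_width > 0)
  if (!(beta > 0 && beta < pi / 2))
    stop("budding angle beta must lie strictly in (0, pi/2)")
  if (half_length < half_width)
    stop("aspect ratio half_length/half_width must be >= 1")
  structure(list(label = label, half_length = half_length,
                 half_width = half_width, beta = beta),
            class = "cell_type")
}

#' Standard cell dimensions for sated and pseudohyphal cells
#'
#' Half-length x half-width of 4.2 x 3 um for sated cells and 6.7 x 1.9 um for
#' pseudohyphal cells, with budding angles 7pi/16 and pi/16 respectively. The
#' two types have areas that differ by about 1%, so cell count is a good proxy
#' for colony area regardless of composition.
#'
#' @return A list with elements `sated` and `pseudohyphal`, each a [cell_type()].
#' @export
default_cell_types <- function() {
  list(sated = cell_type("sated", 4.2, 3, 7 * pi / 16),
       pseudohyphal = cell_type("pseudohyphal", 6.7, 1.9, pi / 16))
}

#' @export
print.cell_type <- function(x, ...) {
  cat(sprintf("<cell_type %s> half_length %.2f um, half_width %.2f um, beta %.4f rad\n",
              x$label, x$half_length, x$half_width, x$beta))
  invisible(x)
}

#' Construct a single cell agent
#'
#' @param id integer cell identifier.
#' @param centre numeric length-2 centre (um).
#' @param orientation angle of the major axis, radians anticlockwise from +x.
#' @param type_params a [cell_type()].
#' @param mother_id id of the mother cell, or `NA` for the founder.
#' @return An object of class `yeast_cell` with fields `id`, `centre`,
#'   `orientation`, `type_params`, `mother_id`, `has_pseudohyphal_daughter`
#'   and `used_sites` (integer vector of occupied bud-site indices in 1..4).
#' @export
new_cell <- function(id, centre, orientation, type_params,
                     mother_id = NA_integer_) {
  stopifnot(length(centre) == 2, is.finite(orientation),
            inherits(type_params, "cell_type"))
  structure(list(id = as.integer(id), centre = as.numeric(centre),
                 orientation = as.numeric(orientation),
                 type_params = type_params,
                 mother_id = as.integer(mother_id),
                 has_pseudohyphal_daughter = FALSE,
                 used_sites = integer(0)),
            class = "yeast_cell")
}

#' Direction vector of a cell
#'
#' The vector from the centre to the distal pole: `half_length * (cos t, sin t)`.
#' @param cell a [new_cell()] object.
#' @return Numeric length-2 vector.
#' @export
cell_direction <- function(cell) {
  cell$type_params$half_length *
    c(cos(cell$orientation), sin(cell$orientation))
}

#' Point on a cell boundary
#'
#' Parameterises the ellipse boundary as
#' `x(phi) = m + (a cos(phi) cos(t) - b sin(phi) sin(t),
#'               a cos(phi) sin(t) + b sin(phi) cos(t))`,
#' where `phi = 0` maps to the distal pole. Angles are wrapped into `[0, 2pi)`.
#'
#' @param cell a [new_cell()] object.
#' @param phi boundary angle parameter(s), radians.
#' @return A length-2 point for scalar `phi`, otherwise an `n x 2` matrix.
#' @export
#' @examples
#' ct <- cell_type("sated", 2, 1, pi / 4)
#' boundary_point(new_cell(1, c(0, 0), 0, ct), 0) # distal pole (2, 0)
boundary_point <- function(cell, phi) {
  phi <- phi %% (2 * pi)
  a <- cell$type_params$half_length
  b <- cell$type_params$half_width
  th <- cell$orientation
  px <- cell$centre[1] + a * cos(phi) * cos(th) - b * sin(phi) * sin(th)
  py <- cell$centre[2] + a * cos(phi) * sin(th) + b * sin(phi) * cos(th)
  if (length(phi) == 1L) c(px, py) else cbind(x = px, y = py)
}

#' Bud-site boundary parameter for a budding angle
#'
#' A ray from the cell centre at angle `beta` to the cell axis meets the
#' boundary at parameter `phi_beta` satisfying `tan(beta) = (b/a) tan(phi_beta)`.
#' The closed form used is
#' `phi_beta = beta + atan(((a - b) tan(beta)) / (b + a tan(beta)^2))`,
#' equivalent to `atan((a/b) tan(beta))` on the same branch.
#'
#' @param type_params a [cell_type()].
#' @return `phi_beta` in `(0, pi/2)`.
#' @export
#' @examples
#' bud_angle_parameter(cell_type("sated", 2, 1, pi / 4)) # atan(2)
bud_angle_parameter <- function(type_params) {
  stopifnot(inherits(type_params, "cell_type"))
  a <- type_params$half_length
  b <- type_params$half_width
  beta <- type_params$beta
  if (!(beta > 0 && beta < pi / 2))
    stop("budding angle beta must lie strictly in (0, pi/2)")
  tb <- tan(beta)
  beta + atan(((a - b) * tb) / (b + a * tb^2))
}

# boundary parameters of the four bud sites, in site order 1..4
.site_phis <- function(phi_beta) {
  c(phi_beta, -phi_beta, pi - phi_beta, pi + phi_beta)
}

#' Bud sites of a cell
#'
#' Each cell carries four prescribed bud sites, two flanking each pole at
#' boundary parameters `+/- phi_beta` (distal pair, sites 1-2) and
#' `pi -/+ phi_beta` (proximal pair, sites 3-4). The outward angle of a site is
#' the direction of the ray from the cell centre through the site, which makes
#' angle `+/- beta` with the cell axis at the distal pole (and the reflected
#' angles at the proximal pole).
#'
#' @param cell a [new_cell()] object.
#' @return A data frame with columns `site`, `x`, `y`, `outward_angle`, `pole`.
#' @export
bud_sites <- function(cell) {
  phis <- .site_phis(bud_angle_parameter(cell$type_params))
  pts <- boundary_point(cell, phis)
  outward <- atan2(pts[, 2] - cell$centre[2], pts[, 1] - cell$centre[1])
  data.frame(site = 1:4, x = pts[, 1], y = pts[, 2],
             outward_angle = outward,
             pole = c("distal", "distal", "proximal", "proximal"))
}

#' Test whether a point lies strictly inside a cell
#'
#' Boundary contact counts as outside: partial overlap of cell boundaries is
#' permitted in the growth model, and only a centre strictly interior to an
#' existing cell vetoes an insertion.
#'
#' @param cell a [new_cell()] object.
#' @param p numeric length-2 point.
#' @return `TRUE` iff `p` is strictly inside the ellipse.
#' @export
contains_point <- function(cell, p) {
  dx <- p[1] - cell$centre[1]
  dy <- p[2] - cell$centre[2]
  cth <- cos(cell$orientation)
  sth <- sin(cell$orientation)
  u <- dx * cth + dy * sth
  v <- -dx * sth + dy * cth
  (u / cell$type_params$half_length)^2 +
    (v / cell$type_params$half_width)^2 < 1
}

#' Place a daughter cell at a bud site
#'
#' The daughter is oriented along the outward ray from the mother's centre
#' through the bud site, pointing away from the mother, and positioned so that
#' its proximal pole coincides with the bud-site point (tangential contact,
#' no initial overlap). The placement is deterministic: no angular noise is
#' added to the outward direction.
#'
#' @param mother a [new_cell()] object.
#' @param site_index bud site in 1..4 (1-2 distal, 3-4 proximal).
#' @param daughter_type a [cell_type()] for the daughter.
#' @param next_id id to assign to the daughter.
#' @return A `yeast_cell` with `mother_id` set, empty `used_sites`, and
#'   `has_pseudohyphal_daughter = FALSE`.
#' @export
place_daughter <- function(mother, site_index, daughter_type, next_id) {
  stopifnot(site_index %in% 1:4)
  if (site_index %in% mother$used_sites)
    stop("bud site ", site_index, " is already occupied; re-propose the event")
  site <- bud_sites(mother)[site_index, ]
  ang <- site$outward_angle
  a_d <- daughter_type$half_length
  centre <- c(site$x + a_d * cos(ang), site$y + a_d * sin(ang))
  new_cell(next_id, centre, ang, daughter_type, mother_id = mother$id)
}
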