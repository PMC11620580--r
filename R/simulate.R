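#' Simulation parameters
#'
#' Bundles the five budding parameters, cell dimensions, stopping rule, domain
#' and seed of one colony growth simulation. The five budding parameters are:
#' `n_star`, the fraction of total colony growth below which all cells are
#' sated; `p_a`, the probability of selecting a sated mother once the
#' threshold is passed; `p_sp`, the probability that a sated mother produces a
#' pseudohyphal daughter; `p_ps`, the probability that a forking pseudohyphal
#' mother produces a sated daughter; and `gamma`, the forking control --- the
#' probability that proliferation of a pseudohyphal mother that already has a
#' pseudohyphal daughter is redirected to a fresh branch tip.
#'
#' Exactly one stopping rule must be active: either a cell-count target
#' `n_max`, or a rasterised-area target `target_area` (in pixels at
#' `px_per_um` resolution) with relative tolerance `area_tol`.
#'
#' @param n_star threshold fraction in (0, 1]; `n_star = 1` never permits
#'   pseudohyphal growth.
#' @param p_a,p_sp,p_ps,gamma probabilities in `[0, 1]`.
#' @param n_max target cell count (count mode).
#' @param target_area target occupied-pixel count (area mode).
#' @param area_tol relative tolerance of the area target (default 0.05).
#' @param domain domain side lengths `c(Lx, Ly)` in um; colonies must fit inside.
#' @param seed integer RNG seed, or `NULL` to grow from the current RNG state.
#' @param px_per_um raster resolution used in area mode and by default in
#'   [colony_to_mask()].
#' @param max_consecutive_aborts stall guard: the simulation stops with a
#'   warning after this many consecutive aborted proliferation events.
#' @param cell_types list with `sated` and `pseudohyphal` [cell_type()]s.
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' sim_params(0.67, 0.14, 0.25, 0.58, 0.12, n_max = 200, seed = 1)
sim_params <- function(n_star, p_a, p_sp, p_ps, gamma,
                       n_max = NULL, target_area = NULL, area_tol = 0.05,
                       domain = c(4000, 4000), seed = NULL, px_per_um = 1,
                       max_consecutive_aborts = 1e5,
                       cell_types = default_cell_types()) {
  probs <- c(n_star = n_star, p_a = p_a, p_sp = p_sp, p_ps = p_ps,
             gamma = gamma)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all five budding parameters must lie in [0, 1]")
  if (is.null(n_max) == is.null(target_area))
    stop("exactly one stopping rule must be set: n_max or target_area")
  if (!is.null(n_max) && n_max < 1) stop("n_max must be >= 1")
  if (!is.null(target_area) && target_area < 1) stop("target_area must be >= 1")
  stopifnot(length(domain) == 2, all(domain > 0), px_per_um > 0,
            area_tol > 0, max_consecutive_aborts >= 1)
  structure(list(n_star = n_star, p_a = p_a, p_sp = p_sp, p_ps = p_ps,
                 gamma = gamma, n_max = if (is.null(n_max)) NULL else as.integer(n_max),
                 target_area = target_area, area_tol = area_tol,
                 domain = as.numeric(domain), seed = seed,
                 px_per_um = px_per_um,
                 max_consecutive_aborts = max_consecutive_aborts,
                 cell_types = cell_types),
            class = "sim_params")
}

#' Budding parameter vector of a `sim_params` object
#' @param params a [sim_params()] object.
#' @return Named numeric vector `(n_star, p_a, p_sp, p_ps, gamma)`.
#' @export
sim_theta <- function(params) {
  c(n_star = params$n_star, p_a = params$p_a, p_sp = params$p_sp,
    p_ps = params$p_ps, gamma = params$gamma)
}

# 2 x 3 matrix of (half_length, half_width, phi_beta) per type (sated, pseudo)
.type_matrix <- function(params) {
  ct <- params$cell_types
  rbind(c(ct$sated$half_length, ct$sated$half_width,
          bud_angle_parameter(ct$sated)),
        c(ct$pseudohyphal$half_length, ct$pseudohyphal$half_width,
          bud_angle_parameter(ct$pseudohyphal)))
}

# effective cell budget used by the decision-tree threshold
.n_max_effective <- function(params) {
  if (!is.null(params$n_max)) return(params$n_max)
  ct <- params$cell_types
  area_um2 <- mean(c(pi * ct$sated$half_length * ct$sated$half_width,
                     pi * ct$pseudohyphal$half_length * ct$pseudohyphal$half_width))
  max(1L, as.integer(round(params$target_area /
                             (area_um2 * params$px_per_um^2))))
}

#' Initialise a colony
#'
#' Creates a colony consisting of a single sated cell at the origin with
#' orientation 0, and seeds the RNG from `params$seed` (if non-`NULL`).
#'
#' @param params a [sim_params()] object.
#' @return An object of class `colony`.
#' @export
init_colony <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  ct <- params$cell_types$sated
  if (params$domain[1] / 2 < ct$half_length ||
      params$domain[2] / 2 < ct$half_width)
    stop("domain is smaller than a single cell")
  if (!is.null(params$seed)) set.seed(params$seed)
  structure(list(x = 0, y = 0, theta = 0, type = 0L, mother = 0L,
                 has_pd = FALSE, used = 0L, n = 1L,
                 params = params, aborts = 0, stalled = FALSE),
            class = "colony")
}

#' @export
print.colony <- function(x, ...) {
  cat(sprintf("<colony> %d cells (%d sated, %d pseudohyphal), %s aborted events%s\n",
              x$n, sum(x$type == 0L), sum(x$type == 1L),
              format(x$aborts), if (x$stalled) " [STALLED]" else ""))
  invisible(x)
}

#' @export
as.data.frame.colony <- function(x, ...) {
  data.frame(id = seq_len(x$n), x = x$x, y = x$y, theta = x$theta,
             type = c("sated", "pseudohyphal")[x$type + 1L],
             mother_id = ifelse(x$mother == 0L, NA_integer_, x$mother),
             has_pseudohyphal_daughter = x$has_pd)
}

#' Extract one cell of a colony as a `yeast_cell`
#' @param colony a [init_colony()]/[run_simulation()] colony.
#' @param i cell index.
#' @return A [new_cell()] object with lineage flags and used sites filled in.
#' @export
colony_cell <- function(colony, i) {
  stopifnot(i >= 1, i <= colony$n)
  tp <- if (colony$type[i] == 0L) colony$params$cell_types$sated
        else colony$params$cell_types$pseudohyphal
  cell <- new_cell(i, c(colony$x[i], colony$y[i]), colony$theta[i], tp,
                   mother_id = if (colony$mother[i] == 0L) NA_integer_
                               else colony$mother[i])
  cell$has_pseudohyphal_daughter <- colony$has_pd[i]
  cell$used_sites <- which(bitwAnd(colony$used[i], bitwShiftL(1L, 0:3)) != 0L)
  cell
}

# 1-based index from a uniform draw (same convention as the C++ engine)
.pick <- function(u, k) 1L + min(as.integer(u * k), k - 1L)

.free_sites <- function(used, distal_only = FALSE) {
  sites <- if (distal_only) 1:2 else 1:4
  sites[bitwAnd(used, bitwShiftL(1L, sites - 1L)) == 0L]
}

#' Propose the next proliferation event
#'
#' Implements the budding decision tree, consuming draws from R's RNG in a
#' fixed order. While `n / n_max <= n_star` the mother is uniform over all
#' cells and the daughter sated. Afterwards, a sated mother is chosen with
#' probability `p_a` (forced if no pseudohyphal cell exists) and produces a
#' pseudohyphal daughter with probability `p_sp`; a pseudohyphal mother
#' without a pseudohyphal daughter extends its filament (pseudohyphal
#' daughter, distal site); one that already has a pseudohyphal daughter is,
#' with probability `gamma`, abandoned in favour of a uniformly chosen
#' pseudohyphal cell without a pseudohyphal daughter, and otherwise produces
#' a sated daughter with probability `p_ps` (else pseudohyphal) at a distal
#' site. Site choices are uniform over the mother's free sites.
#'
#' @param colony a colony object.
#' @return A list with `abort` (logical), and when `abort` is `FALSE`:
#'   `mother` (cell index), `daughter_type` (0 sated, 1 pseudohyphal) and
#'   `site` (1..4). When `abort` is `TRUE` a `reason` string is included and
#'   the caller must restart the event from the top.
#' @export
propose_event <- function(colony) {
  p <- colony$params
  n <- colony$n
  n_max <- .n_max_effective(p)
  pseudo <- which(colony$type == 1L)

  if (n / n_max <= p$n_star) {
    mother <- .pick(runif(1), n)
    dtype <- 0L
    distal <- FALSE
  } else {
    ut <- runif(1)
    sated_mother <- length(pseudo) == 0L || ut < p$p_a
    if (sated_mother) {
      sated <- which(colony$type == 0L)
      mother <- sated[.pick(runif(1), length(sated))]
      dtype <- if (runif(1) < p$p_sp) 1L else 0L
      distal <- FALSE
    } else {
      mother <- pseudo[.pick(runif(1), length(pseudo))]
      if (!colony$has_pd[mother]) {
        dtype <- 1L
        distal <- TRUE
      } else if (runif(1) < p$gamma) {
        eligible <- pseudo[!colony$has_pd[pseudo]]
        if (length(eligible) == 0L)
          return(list(abort = TRUE, reason = "no eligible pseudohyphal mother for redirect"))
        mother <- eligible[.pick(runif(1), length(eligible))]
        dtype <- 1L
        distal <- TRUE
      } else {
        dtype <- if (runif(1) < p$p_ps) 0L else 1L
        distal <- TRUE
      }
    }
  }

  free <- .free_sites(colony$used[mother], distal_only = distal)
  if (length(free) == 0L)
    return(list(abort = TRUE, reason = "no free bud site on selected mother"))
  site <- free[.pick(runif(1), length(free))]
  list(abort = FALSE, mother = mother, daughter_type = dtype, site = site)
}

# daughter pose (cx, cy, angle) for a proposal, mirroring the C++ engine
.daughter_pose <- function(colony, mother, site, dtype, tm) {
  mt <- colony$type[mother] + 1L
  phi <- .site_phis(tm[mt, 3])[site]
  th <- colony$theta[mother]
  cp <- tm[mt, 1] * cos(phi)
  sp <- tm[mt, 2] * sin(phi)
  px <- colony$x[mother] + cp * cos(th) - sp * sin(th)
  py <- colony$y[mother] + cp * sin(th) + sp * cos(th)
  ang <- atan2(py - colony$y[mother], px - colony$x[mother])
  c(px + tm[dtype + 1L, 1] * cos(ang), py + tm[dtype + 1L, 1] * sin(ang), ang)
}

#' Attempt to insert a proposed daughter cell
#'
#' Builds the daughter via the tangential placement rule and inserts it unless
#' its centre lies strictly inside an existing cell (partial volume exclusion)
#' or its boundary leaves the domain. On success the daughter is appended, the
#' mother's bud site is marked used, and the mother's
#' `has_pseudohyphal_daughter` flag is set if the daughter is pseudohyphal.
#'
#' @param colony a colony object.
#' @param proposal a non-aborted result of [propose_event()].
#' @return A list with `accepted` (logical) and `colony` (updated on success,
#'   unchanged on failure).
#' @export
attempt_insertion <- function(colony, proposal) {
  stopifnot(!isTRUE(proposal$abort))
  p <- colony$params
  tm <- .type_matrix(p)
  pose <- .daughter_pose(colony, proposal$mother, proposal$site,
                         proposal$daughter_type, tm)
  cx <- pose[1]; cy <- pose[2]; ang <- pose[3]
  ad <- tm[proposal$daughter_type + 1L, 1]
  bd <- tm[proposal$daughter_type + 1L, 2]

  ex <- sqrt(ad^2 * cos(ang)^2 + bd^2 * sin(ang)^2)
  ey <- sqrt(ad^2 * sin(ang)^2 + bd^2 * cos(ang)^2)
  ok <- cx - ex >= -p$domain[1] / 2 && cx + ex <= p$domain[1] / 2 &&
        cy - ey >= -p$domain[2] / 2 && cy + ey <= p$domain[2] / 2

  if (ok) {
    a <- tm[colony$type + 1L, 1]
    b <- tm[colony$type + 1L, 2]
    dx <- cx - colony$x
    dy <- cy - colony$y
    near <- dx^2 + dy^2 < a^2
    if (any(near)) {
      cth <- cos(colony$theta[near]); sth <- sin(colony$theta[near])
      u <- dx[near] * cth + dy[near] * sth
      v <- -dx[near] * sth + dy[near] * cth
      if (any((u / a[near])^2 + (v / b[near])^2 < 1)) ok <- FALSE
    }
  }

  if (!ok) return(list(accepted = FALSE, colony = colony))

  i <- colony$n + 1L
  colony$x[i] <- cx; colony$y[i] <- cy; colony$theta[i] <- ang
  colony$type[i] <- proposal$daughter_type
  colony$mother[i] <- proposal$mother
  colony$has_pd[i] <- FALSE
  colony$used[i] <- 0L
  colony$used[proposal$mother] <- bitwOr(colony$used[proposal$mother],
                                         bitwShiftL(1L, proposal$site - 1L))
  if (proposal$daughter_type == 1L) colony$has_pd[proposal$mother] <- TRUE
  colony$n <- i
  list(accepted = TRUE, colony = colony)
}

# grow a colony to n_target cells with the compiled engine
.grow_cpp <- function(colony, n_target) {
  p <- colony$params
  tm <- .type_matrix(p)
  state <- cbind(colony$x, colony$y, colony$theta, as.numeric(colony$type),
                 as.numeric(colony$mother), as.numeric(colony$has_pd),
                 as.numeric(colony$used))
  res <- cpp_grow_colony(state, as.integer(n_target),
                         as.integer(.n_max_effective(p)),
                         p$n_star, p$p_a, p$p_sp, p$p_ps, p$gamma, tm,
                         p$domain[1], p$domain[2], p$max_consecutive_aborts)
  m <- res$cells
  colony$x <- m[, 1]; colony$y <- m[, 2]; colony$theta <- m[, 3]
  colony$type <- as.integer(m[, 4]); colony$mother <- as.integer(m[, 5])
  colony$has_pd <- m[, 6] != 0; colony$used <- as.integer(m[, 7])
  colony$n <- nrow(m)
  colony$aborts <- colony$aborts + res$aborts
  colony$stalled <- res$stalled
  colony
}

# grow with the pure-R engine (reference implementation; same RNG draw order)
.grow_r <- function(colony, n_target) {
  consec <- 0
  while (colony$n < n_target) {
    if (consec >= colony$params$max_consecutive_aborts) {
      colony$stalled <- TRUE
      break
    }
    prop <- propose_event(colony)
    if (!prop$abort) {
      res <- attempt_insertion(colony, prop)
      colony <- res$colony
      if (res$accepted) { consec <- 0; next }
    }
    consec <- consec + 1
    colony$aborts <- colony$aborts + 1
  }
  colony
}

#' Grow a colony
#'
#' Repeats propose/insert cycles until the stopping rule is met: the colony
#' reaches `n_max` cells (count mode), or its rasterised occupied-pixel area is
#' within `area_tol` of `target_area` (area mode, checked by periodic
#' rasterisation at `px_per_um`). Any aborted event restarts the decision tree
#' from the top with fresh random draws; after `max_consecutive_aborts`
#' consecutive failures the simulation stops with a warning and the partial
#' colony is returned with `stalled = TRUE`.
#'
#' @param params a [sim_params()] object.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation). Both consume R's RNG stream in the same order and
#'   produce bit-identical colonies for equal seeds.
#' @return A `colony` object.
#' @export
#' @examples
#' col <- run_simulation(sim_params(0.6, 0.2, 0.3, 0.5, 0.1,
#'                                  n_max = 100, seed = 1))
#' table(as.data.frame(col)$type)
run_simulation <- function(params, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  colony <- init_colony(params)
  grow <- if (engine == "cpp") .grow_cpp else .grow_r

  if (!is.null(params$n_max)) {
    colony <- grow(colony, params$n_max)
  } else {
    target <- params$target_area
    tol <- params$area_tol
    ct <- params$cell_types
    cell_px <- mean(c(pi * ct$sated$half_length * ct$sated$half_width,
                      pi * ct$pseudohyphal$half_length *
                        ct$pseudohyphal$half_width)) * params$px_per_um^2
    repeat {
      area <- sum(colony_to_mask(colony, params$px_per_um)$pixels)
      if (area >= target * (1 - tol) || colony$stalled) break
      chunk <- max(5L, as.integer(ceiling((target * (1 - tol) - area) /
                                            cell_px * 0.7)))
      colony <- grow(colony, colony$n + chunk)
    }
    if (area > target * (1 + tol))
      warning(sprintf("colony area %d overshot target %g by more than %g%%",
                      area, target, 100 * tol))
  }
  if (colony$stalled)
    warning(sprintf("colony stalled at %d cells after %d consecutive aborted events",
                    colony$n, as.integer(colony$params$max_consecutive_aborts)))
  colony
}

#' Rasterise a colony to a binary mask
#'
#' Pixels cover the colony bounding box plus a margin; a pixel is occupied iff
#' its centre lies inside or on the boundary of any cell.
#'
#' @param colony a colony object.
#' @param px_per_um raster resolution, pixels per um (default from the
#'   simulation parameters). The three morphology statistics are ratio-based
#'   and robust to this choice.
#' @param margin margin around the bounding box, um.
#' @return A [binary_mask()] with `px_size = 1/px_per_um`.
#' @export
colony_to_mask <- function(colony, px_per_um = NULL, margin = 3) {
  px_per_um <- px_per_um %||% colony$params$px_per_um %||% 1
  stopifnot(px_per_um > 0)
  if (colony$n == 0L)
    return(binary_mask(matrix(0L, 1, 1), px_size = 1 / px_per_um))
  tm <- .type_matrix(colony$params)
  a <- tm[colony$type + 1L, 1]
  b <- tm[colony$type + 1L, 2]
  ex <- sqrt(a^2 * cos(colony$theta)^2 + b^2 * sin(colony$theta)^2)
  ey <- sqrt(a^2 * sin(colony$theta)^2 + b^2 * cos(colony$theta)^2)
  xmin <- min(colony$x - ex) - margin
  xmax <- max(colony$x + ex) + margin
  ymin <- min(colony$y - ey) - margin
  ymax <- max(colony$y + ey) + margin
  px <- 1 / px_per_um
  nx <- as.integer(ceiling((xmax - xmin) / px))
  ny <- as.integer(ceiling((ymax - ymin) / px))
  cells <- cbind(colony$x, colony$y, colony$theta, as.numeric(colony$type))
  M <- cpp_rasterize(cells, tm, xmin, ymin, px, nx, ny)
  binary_mask(M, px_size = px)
}
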