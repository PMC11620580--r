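#' Fixture mask specification
#'
#' Describes a deterministic synthetic mask with known morphology, used to
#' validate the morphometry statistics against constructions whose radii,
#' filament content and branch counts are known by design.
#'
#' @param kind one of `"disk"`, `"disk_spikes"`, `"y_filament"`,
#'   `"random_blob"`.
#' @param radius disk radius in pixels.
#' @param n_spikes number of radial spikes (for `disk_spikes`); evenly spaced
#'   in angle starting at `angle_offset`, so the number falling in any quadrant
#'   is predictable.
#' @param spike_length,spike_width spike dimensions in pixels.
#' @param angle_offset angle of the first spike, radians. The default
#'   `pi/16` places exactly 2 of 8 spikes in the counting quadrant
#'   `[pi/2, pi]`.
#' @param canvas_half optional half-width of the canvas in pixels; defaults to
#'   what the shape needs. Spikes longer than the canvas are an error.
#' @param n_blobs,seed blob count and RNG seed for `random_blob`.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("disk", "disk_spikes", "y_filament",
                                  "random_blob"),
                         radius = 100, n_spikes = 8, spike_length = radius,
                         spike_width = 5, angle_offset = pi / 16,
                         canvas_half = NULL, n_blobs = 25, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, n_spikes >= 0)
  if (kind == "disk_spikes" && n_spikes > 0 &&
      (spike_length <= 0 || spike_width <= 0))
    stop("spike dimensions must be positive when n_spikes > 0")
  structure(list(kind = kind, radius = radius, n_spikes = n_spikes,
                 spike_length = spike_length, spike_width = spike_width,
                 angle_offset = angle_offset, canvas_half = canvas_half,
                 n_blobs = n_blobs, seed = seed),
            class = "fixture_spec")
}

# draw a thick segment from p0 to p1 into logical canvas B (pixel coords
# centred at 0); returns updated canvas
.draw_segment <- function(B, xs, ys, p0, p1, width) {
  v <- p1 - p0
  len2 <- sum(v^2)
  DX <- outer(xs - p0[1], rep(1, length(ys)))
  DY <- outer(rep(1, length(xs)), ys - p0[2])
  t <- (DX * v[1] + DY * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  dist2 <- (DX - t * v[1])^2 + (DY - t * v[2])^2
  B | (dist2 <= (width / 2)^2)
}

#' Generate a fixture mask
#'
#' Deterministic for a given spec (and seed, for `random_blob`): disks, disks
#' with evenly spaced radial spikes, a Y-shaped filament on a compact core,
#' and random blob unions for fuzz testing.
#'
#' @param spec a [fixture_spec()], or a `kind` string with further arguments
#'   passed to [fixture_spec()].
#' @param ... arguments forwarded to [fixture_spec()] when `spec` is a string.
#' @return A [binary_mask()].
#' @export
#' @examples
#' sum(make_fixture("disk", radius = 50)$pixels) / (pi * 50^2) # ~1
make_fixture <- function(spec, ...) {
  if (is.character(spec)) spec <- fixture_spec(spec, ...)
  stopifnot(inherits(spec, "fixture_spec"))
  R <- spec$radius
  need_half <- switch(spec$kind,
                      disk = R + 4,
                      disk_spikes = R + spec$spike_length + 4,
                      y_filament = 2.2 * R + 4,
                      random_blob = 1.6 * R + 4)
  half <- spec$canvas_half %||% ceiling(need_half)
  if (half < need_half)
    stop("canvas_half is too small for the requested shape")
  xs <- -half:half
  ys <- xs

  B <- outer(xs^2, ys^2, "+") <= R^2

  if (spec$kind == "disk_spikes" && spec$n_spikes > 0) {
    for (k in seq_len(spec$n_spikes)) {
      ang <- spec$angle_offset + (k - 1) * 2 * pi / spec$n_spikes
      along <- outer(xs * cos(ang), ys * sin(ang), "+")
      perp <- outer(xs * (-sin(ang)), ys * cos(ang), "+")
      B <- B | (along >= R - 2 & along <= R + spec$spike_length &
                  abs(perp) <= spec$spike_width / 2)
    }
  } else if (spec$kind == "y_filament") {
    # compact core plus a Y entirely inside the quadrant [pi/2, pi]
    ang <- 3 * pi / 4
    fork <- 1.45 * R * c(cos(ang), sin(ang))
    base <- 0.9 * R * c(cos(ang), sin(ang))
    B <- .draw_segment(B, xs, ys, base, fork, 3)
    for (da in c(-0.45, 0.45)) {
      tip <- fork + 0.65 * R * c(cos(ang + da), sin(ang + da))
      B <- .draw_segment(B, xs, ys, fork, tip, 3)
    }
  } else if (spec$kind == "random_blob") {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(spec$seed)
    for (k in seq_len(spec$n_blobs)) {
      rr <- runif(1, 0, 1.2 * R)
      aa <- runif(1, 0, 2 * pi)
      rad <- runif(1, R / 10, R / 3)
      ctr <- rr * c(cos(aa), sin(aa))
      B <- B | (outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+") <= rad^2)
    }
  }

  binary_mask(B + 0L)
}

#' Simulate a replicate set of colonies at one parameter vector
#'
#' Simulates `n_rep` colonies at `theta` with distinct seeds, rasterises each,
#' computes its summary statistics and assembles the [replicate_stats()]
#' normalisation basis. If any statistic is degenerate across replicates
#' (max equals min, leaving the normalisation undefined), replicates are
#' re-drawn with fresh seeds up to `max_redraws` times.
#'
#' @param theta budding parameter 5-vector `(n_star, p_a, p_sp, p_ps, gamma)`.
#' @param n_rep number of replicates (>= 2).
#' @param n_max cells per colony.
#' @param px_per_um raster resolution.
#' @param seed base seed; replicate `i` uses `seed + 7919 * i`.
#' @param domain simulation domain, um.
#' @param max_redraws redraw budget for the degeneracy guard.
#' @return List with `masks` (list of [binary_mask()]), `stats`
#'   (a [replicate_stats()]), `theta` and the per-replicate `seeds`.
#' @export
synthetic_replicate_set <- function(theta, n_rep, n_max = 1000L,
                                    px_per_um = 1, seed = 1L,
                                    domain = c(4000, 4000),
                                    max_redraws = 5L) {
  if (n_rep < 2L) stop("at least 2 replicates are required")
  stopifnot(length(theta) == 5)

  one <- function(s) {
    params <- sim_params(theta[1], theta[2], theta[3], theta[4], theta[5],
                         n_max = n_max, domain = domain, seed = s,
                         px_per_um = px_per_um)
    mask <- colony_to_mask(run_simulation(params))
    list(mask = mask, stats = summarise_mask(mask))
  }

  seeds <- seed + 7919L * seq_len(n_rep)
  reps <- lapply(seeds, one)
  redraws <- 0L
  repeat {
    ok <- tryCatch({
      stats <- as_replicate_stats(lapply(reps, `[[`, "stats"))
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
    redraws <- redraws + 1L
    if (redraws > max_redraws)
      stop("replicate statistics degenerate after ", max_redraws, " redraws")
    i <- ((redraws - 1L) %% n_rep) + 1L
    seeds[i] <- seeds[i] + 104729L * redraws
    reps[[i]] <- one(seeds[i])
  }
  list(masks = lapply(reps, `[[`, "mask"), stats = stats,
       theta = theta, seeds = seeds)
}
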