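#' Read a colony mask from a PNG or TIFF file
#'
#' Grayscale or RGB images are averaged over channels and thresholded with
#' [binarize()] unless already binary. Image rows (top-down) are converted to
#' the package's `[x, y]`, y-up matrix convention.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param px_size physical pixel size, um.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, px_size = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                           c(1, 2), mean)
  # image row 1 is the top: x = column, y = flipped row
  m <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  vals <- unique(as.vector(m))
  if (all(vals %in% c(0, 1))) {
    # binary file: dark (0) pixels are the colony
    binary_mask((m == 0) + 0L, px_size = px_size)
  } else {
    binarize(m, px_size = px_size)
  }
}

#' Write a colony mask to a PNG or TIFF file
#'
#' Occupied pixels are written dark (0) on a light background, the convention
#' used for experimental colony photographs.
#'
#' @param mask a [binary_mask()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- 1 - mask$pixels # dark = occupied
  img <- t(m[, rev(seq_len(ncol(m))), drop = FALSE])
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Write a colony to CSV (cells) and JSON (parameters)
#'
#' @param colony a colony object.
#' @param path output CSV path; a `.json` sidecar with the simulation
#'   parameters is written next to it.
#' @return `path`, invisibly.
#' @export
write_colony <- function(colony, path) {
  write.csv(as.data.frame(colony), path, row.names = FALSE)
  p <- colony$params
  header <- list(n_star = p$n_star, p_a = p$p_a, p_sp = p$p_sp,
                 p_ps = p$p_ps, gamma = p$gamma, n_max = p$n_max,
                 target_area = p$target_area, domain = p$domain,
                 seed = p$seed, px_per_um = p$px_per_um,
                 n = colony$n, aborts = colony$aborts,
                 stalled = colony$stalled)
  jsonlite::write_json(header, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Write per-image summary statistics to CSV
#'
#' @param stats list of [summarise_mask()] results.
#' @param paths character vector of source identifiers (one per image).
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_stats_csv <- function(stats, paths, file) {
  stopifnot(length(stats) == length(paths))
  df <- do.call(rbind, lapply(seq_along(stats), function(i) {
    s <- stats[[i]]
    data.frame(path = paths[i], N = s$N, r_csr = s$r_csr, r_max = s$r_max,
               I_B = s$I_B, I_F = s$I_F, I_R = s$I_R)
  }))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read replicate statistics from a CSV of precomputed summaries
#'
#' The CSV must have columns `I_B`, `I_F` and `I_R`, one row per replicate.
#'
#' @param file CSV path.
#' @return A [replicate_stats()] object.
#' @export
read_stats_csv <- function(file) {
  df <- read.csv(file)
  stopifnot(all(c("I_B", "I_F", "I_R") %in% names(df)))
  replicate_stats(df$I_B, df$I_F, df$I_R)
}

#' Write the trace of an ABC fit to CSV
#'
#' One row per iteration per chain, with the five parameters, the proposal
#' distance, the acceptance flag and the chain id.
#'
#' @param fit an [run_abc()] result.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(fit, file) {
  df <- do.call(rbind, lapply(seq_along(fit$chains), function(j) {
    ch <- fit$chains[[j]]
    cbind(data.frame(chain = j, iteration = seq_len(nrow(ch$samples))),
          as.data.frame(ch$samples),
          data.frame(distance = ch$distances, accepted = ch$accepted))
  }))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read an ABC configuration from YAML
#'
#' Recognised keys: `epsilon`, `chain_length`, `n_chains`, `seed`, `burn_in`,
#' `init_sd`, `prefactor`, `priors` (named list of two shape values each) and
#' a `simulator` block (`n_max`, `target_area`, `area_tol`, `px_per_um`,
#' `domain`).
#'
#' @param file YAML path.
#' @return An [abc_config()].
#' @export
read_abc_config <- function(file) {
  y <- yaml::read_yaml(file)
  priors <- if (!is.null(y$priors)) {
    lapply(y$priors, as.numeric)[.theta_names]
  } else default_priors()
  abc_config(epsilon = y$epsilon %||% Inf,
             chain_length = y$chain_length %||% 1000L,
             n_chains = y$n_chains %||% 3L,
             priors = priors,
             seed = y$seed %||% 1L,
             burn_in = y$burn_in %||% 0.1,
             init_sd = y$init_sd %||% 0.02,
             prefactor = y$prefactor %||% "third",
             simulator = y$simulator %||% list())
}
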