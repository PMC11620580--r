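#' Replicate summary statistics
#'
#' Holds the three summary-statistic vectors over the replicate images of one
#' experimental condition, together with the per-statistic min, max and mean
#' used as the normalisation basis for the ABC distance. All statistics ---
#' observed and simulated --- are normalised with the same basis, so the
#' comparison is on one common scale.
#'
#' @param I_B,I_F,I_R numeric vectors of equal length (>= 2), one entry per
#'   replicate.
#' @return An object of class `replicate_stats`.
#' @export
replicate_stats <- function(I_B, I_F, I_R) {
  n <- length(I_B)
  stopifnot(length(I_F) == n, length(I_R) == n)
  if (n < 2L) stop("at least 2 replicates are required")
  m <- cbind(I_B = I_B, I_F = I_F, I_R = I_R)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  if (any(maxs == mins))
    stop("degenerate replicate statistics: max equals min for ",
         paste(colnames(m)[maxs == mins], collapse = ", "),
         "; normalisation is undefined")
  structure(list(I_B = I_B, I_F = I_F, I_R = I_R, n_rep = n,
                 min = mins, max = maxs, mean = colMeans(m)),
            class = "replicate_stats")
}

#' Build replicate statistics from a list of colony_stats
#' @param stats list of [summarise_mask()] results.
#' @return A [replicate_stats()] object.
#' @export
as_replicate_stats <- function(stats) {
  replicate_stats(I_B = vapply(stats, function(s) s$I_B, numeric(1)),
                  I_F = vapply(stats, function(s) s$I_F, numeric(1)),
                  I_R = vapply(stats, function(s) s$I_R, numeric(1)))
}

#' @export
print.replicate_stats <- function(x, ...) {
  cat(sprintf("<replicate_stats> %d replicates\n", x$n_rep))
  print(rbind(min = x$min, mean = x$mean, max = x$max))
  invisible(x)
}

#' Min-max normalise a statistic triple against a replicate basis
#'
#' Each statistic is scaled as `(x - min) / (max - min)` with the min and max
#' taken over the replicate vectors. Observed replicates map into `[0, 1]`;
#' simulated colonies may fall slightly outside.
#'
#' @param raw a [summarise_mask()] result or numeric triple `(I_B, I_F, I_R)`.
#' @param ref a [replicate_stats()] object.
#' @return Named numeric vector of the three normalised statistics.
#' @export
normalise_stats <- function(raw, ref) {
  stopifnot(inherits(ref, "replicate_stats"))
  x <- if (inherits(raw, "colony_stats")) as.numeric(raw) else {
    stopifnot(length(raw) == 3)
    as.numeric(raw)
  }
  out <- (x - ref$min) / (ref$max - ref$min)
  names(out) <- c("I_B", "I_F", "I_R")
  out
}

#' Normalised mean of the replicate statistics
#'
#' The reference vector the ABC distance compares simulations against: the
#' per-statistic replicate means, min-max normalised with the same basis as
#' [normalise_stats()].
#'
#' @param ref a [replicate_stats()] object.
#' @return Named numeric vector of the three normalised means.
#' @export
reference_stats <- function(ref) {
  stopifnot(inherits(ref, "replicate_stats"))
  out <- (ref$mean - ref$min) / (ref$max - ref$min)
  names(out) <- c("I_B", "I_F", "I_R")
  out
}

#' Normalised Euclidean distance between statistic vectors
#'
#' `rho(S_x, S_bar) = (1/3) * sqrt(sum_i ((S_x_i - S_bar_i) / (1 + S_bar_i))^2)`.
#' The prefactor multiplies the root rather than dividing the sum inside it;
#' `prefactor = "rms"` exposes the `sqrt(sum/3)` alternative for sensitivity
#' checks. The distance is not symmetric in its arguments: the second argument
#' fixes the denominators.
#'
#' @param s_x normalised statistics of one simulated image.
#' @param s_bar normalised reference statistics ([reference_stats()]).
#' @param prefactor `"third"` (default) or `"rms"`.
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' abc_distance(c(1, 1, 1), c(0, 0, 0)) # sqrt(3)/3
#' abc_distance(c(1, 1, 0), c(1, 1, 1)) # 1/6
abc_distance <- function(s_x, s_bar, prefactor = c("third", "rms")) {
  prefactor <- match.arg(prefactor)
  stopifnot(length(s_x) == 3, length(s_bar) == 3)
  ss <- sum(((s_x - s_bar) / (1 + s_bar))^2)
  if (prefactor == "third") sqrt(ss) / 3 else sqrt(ss / 3)
}

#' Default Beta priors for the five budding parameters
#'
#' Weakly informative priors for `n_star` (expected large: pseudohyphal growth
#' emerges late), `gamma` and `p_a` (expected small), and uninformative
#' `Beta(2, 2)` priors for `p_sp` and `p_ps`.
#'
#' @return Named list of `c(shape1, shape2)` pairs in parameter order
#'   `(n_star, p_a, p_sp, p_ps, gamma)`.
#' @export
default_priors <- function() {
  list(n_star = c(5, 2), p_a = c(2, 5), p_sp = c(2, 2),
       p_ps = c(2, 2), gamma = c(2, 5))
}

.theta_names <- c("n_star", "p_a", "p_sp", "p_ps", "gamma")

#' Prior mean vector
#' @param priors prior list as from [default_priors()].
#' @return Named numeric vector of Beta means `shape1 / (shape1 + shape2)`.
#' @export
prior_mean <- function(priors = default_priors()) {
  vapply(priors, function(p) p[1] / (p[1] + p[2]), numeric(1))
}

#' Log prior density of a parameter vector
#'
#' Sum of independent Beta log densities; `-Inf` outside the open unit
#' hypercube.
#'
#' @param theta numeric 5-vector `(n_star, p_a, p_sp, p_ps, gamma)`.
#' @param priors prior list as from [default_priors()].
#' @return Scalar log density (possibly `-Inf`).
#' @export
prior_log_density <- function(theta, priors = default_priors()) {
  stopifnot(length(theta) == length(priors))
  if (any(theta <= 0) || any(theta >= 1)) return(-Inf)
  sum(mapply(function(x, p) dbeta(x, p[1], p[2], log = TRUE), theta, priors))
}

.draw_prior <- function(priors) {
  vapply(priors, function(p) stats::rbeta(1, p[1], p[2]), numeric(1))
}

#' ABC-MCMC configuration
#'
#' @param epsilon ABC tolerance; `Inf` short-circuits the simulator and the
#'   chain samples the prior (useful as a diagnostic).
#' @param chain_length iterations per chain.
#' @param n_chains number of independent chains (concatenated after burn-in).
#' @param priors prior list, see [default_priors()].
#' @param proposal_cov 5x5 symmetric positive-definite Gaussian proposal
#'   covariance; usually filled in by [tune_abc()].
#' @param seed base seed; chain `j` is seeded with `seed + j - 1`.
#' @param burn_in fraction of each chain discarded before concatenation.
#' @param init_sd standard deviation of the Gaussian perturbation of the prior
#'   mean used as the initial point.
#' @param prefactor distance prefactor convention, see [abc_distance()].
#' @param warmup_abort abort with tuning advice if no proposal is accepted in
#'   the first `warmup_abort` iterations (with finite `epsilon`); `NULL`
#'   disables the guard.
#' @param simulator list of simulator settings: `n_max` or
#'   `target_area`/`area_tol`, `px_per_um`, `domain`, `cell_types`,
#'   `max_consecutive_aborts`.
#' @return An object of class `abc_config`.
#' @export
abc_config <- function(epsilon = Inf, chain_length = 1000L, n_chains = 3L,
                       priors = default_priors(),
                       proposal_cov = diag(0.01, 5), seed = 1L,
                       burn_in = 0.1, init_sd = 0.02,
                       prefactor = c("third", "rms"), warmup_abort = 200L,
                       simulator = list()) {
  prefactor <- match.arg(prefactor)
  stopifnot(epsilon > 0, chain_length >= 1, n_chains >= 1,
            burn_in >= 0, burn_in < 1, length(priors) == 5)
  if (!isTRUE(all.equal(proposal_cov, t(proposal_cov))))
    stop("proposal_cov must be symmetric")
  ch <- tryCatch(chol(proposal_cov), error = function(e) NULL)
  if (is.null(ch)) stop("proposal_cov must be positive definite")
  if (any(vapply(priors, function(p) any(p <= 0), logical(1))))
    stop("Beta prior shapes must be positive")
  sim <- utils::modifyList(
    list(n_max = 1000L, target_area = NULL, area_tol = 0.05,
         px_per_um = 1, domain = c(4000, 4000),
         max_consecutive_aborts = 1e5, cell_types = default_cell_types()),
    simulator)
  structure(list(epsilon = epsilon, chain_length = as.integer(chain_length),
                 n_chains = as.integer(n_chains), priors = priors,
                 proposal_cov = proposal_cov, chol_cov = ch,
                 seed = as.integer(seed), burn_in = burn_in,
                 init_sd = init_sd, prefactor = prefactor,
                 warmup_abort = warmup_abort, simulator = sim),
            class = "abc_config")
}

# simulator closure: theta -> raw statistic triple (or NULL on stall),
# drawing from the ambient RNG stream
.make_sim_fn <- function(config) {
  s <- config$simulator
  function(theta) {
    params <- sim_params(theta[1], theta[2], theta[3], theta[4], theta[5],
                         n_max = s$n_max, target_area = s$target_area,
                         area_tol = s$area_tol, domain = s$domain,
                         seed = NULL, px_per_um = s$px_per_um,
                         max_consecutive_aborts = s$max_consecutive_aborts,
                         cell_types = s$cell_types)
    colony <- suppressWarnings(run_simulation(params))
    if (colony$stalled) return(NULL)
    as.numeric(summarise_mask(colony_to_mask(colony)))
  }
}

#' One ABC Metropolis-Hastings step
#'
#' Proposes `theta* ~ N(theta, proposal_cov)`. Proposals with zero prior
#' density are rejected without calling the simulator. Otherwise one colony is
#' simulated at `theta*`, its statistics normalised and compared with the
#' reference; the proposal is accepted with probability
#' `min(1, pi(theta*) / pi(theta)) * 1(rho <= epsilon)` (the symmetric Gaussian
#' proposal densities cancel). With `epsilon = Inf` the simulator is skipped
#' and the chain targets the prior. A simulator stall counts as a rejection.
#'
#' @param state list with elements `theta` (current 5-vector) and `log_prior`.
#' @param sim_fn function mapping `theta` to the raw statistic triple, or
#'   `NULL` on failure.
#' @param s_bar normalised reference statistics ([reference_stats()]).
#' @param ref the [replicate_stats()] normalisation basis.
#' @param config an [abc_config()].
#' @return Updated state list, with `accepted` (logical) and `distance`
#'   (`NA` when no simulation was run) appended.
#' @export
abc_mh_step <- function(state, sim_fn, s_bar, ref, config) {
  z <- rnorm(5)
  theta_star <- drop(state$theta + t(config$chol_cov) %*% z)
  lp_star <- prior_log_density(theta_star, config$priors)
  rho <- NA_real_

  ok <- is.finite(lp_star)
  if (ok && is.finite(config$epsilon)) {
    raw <- sim_fn(theta_star)
    if (is.null(raw)) {
      ok <- FALSE
    } else {
      rho <- abc_distance(normalise_stats(raw, ref), s_bar,
                          prefactor = config$prefactor)
      ok <- rho <= config$epsilon
    }
  }
  accepted <- FALSE
  if (ok) {
    accepted <- log(runif(1)) < (lp_star - state$log_prior)
  }
  if (accepted) {
    state$theta <- theta_star
    state$log_prior <- lp_star
  }
  state$accepted <- accepted
  state$distance <- rho
  state
}

.run_chain <- function(chain_seed, ref, config, sim_fn, s_bar) {
  set.seed(chain_seed)
  theta <- prior_mean(config$priors) + rnorm(5, 0, config$init_sd)
  theta <- pmin(pmax(theta, 1e-4), 1 - 1e-4)
  state <- list(theta = theta,
                log_prior = prior_log_density(theta, config$priors))
  m <- config$chain_length
  samples <- matrix(NA_real_, m, 5, dimnames = list(NULL, .theta_names))
  accepted <- logical(m)
  distances <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    state <- abc_mh_step(state, sim_fn, s_bar, ref, config)
    samples[i, ] <- state$theta
    accepted[i] <- state$accepted
    distances[i] <- state$distance
    if (!is.null(config$warmup_abort) && is.finite(config$epsilon) &&
        i == config$warmup_abort && !any(accepted[seq_len(i)]))
      stop("no proposals accepted in the first ", i, " iterations; ",
           "epsilon is likely unreachable -- increase it or re-run tune_abc()")
  }
  list(samples = samples, accepted = accepted, distances = distances,
       seed = chain_seed)
}

#' Run ABC-MCMC chains
#'
#' Runs `n_chains` independent chains, each started from a small Gaussian
#' perturbation of the prior mean, and concatenates the post-burn-in samples.
#'
#' @param ref a [replicate_stats()] object (the observed replicates), or a
#'   list of colony masks/[summarise_mask()] results coerced via
#'   [as_replicate_stats()].
#' @param config an [abc_config()].
#' @return An object of class `abc_fit`: list with `chains` (per-chain traces),
#'   `samples` (concatenated post-burn-in matrix), `chain_id`,
#'   `acceptance_rate`, `ess` (per-parameter, summed over chains), `s_bar`,
#'   and the `config`.
#' @export
run_abc <- function(ref, config) {
  stopifnot(inherits(config, "abc_config"))
  if (!inherits(ref, "replicate_stats")) ref <- as_replicate_stats(ref)
  s_bar <- reference_stats(ref)
  sim_fn <- .make_sim_fn(config)
  chains <- lapply(seq_len(config$n_chains), function(j) {
    .run_chain(config$seed + j - 1L, ref, config, sim_fn, s_bar)
  })
  drop_n <- floor(config$burn_in * config$chain_length)
  keep <- (drop_n + 1L):config$chain_length
  samples <- do.call(rbind, lapply(chains, function(ch) ch$samples[keep, , drop = FALSE]))
  chain_id <- rep(seq_along(chains), each = length(keep))
  ess <- Reduce(`+`, lapply(chains, function(ch)
    effective_sample_size(ch$samples[keep, , drop = FALSE])))
  structure(list(chains = chains, samples = samples, chain_id = chain_id,
                 acceptance_rate = mean(unlist(lapply(chains, `[[`, "accepted"))),
                 ess = ess, s_bar = s_bar, ref = ref, config = config),
            class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat(sprintf("<abc_fit> %d chains x %d iterations, epsilon = %.4g, acceptance %.1f%%\n",
              x$config$n_chains, x$config$chain_length, x$config$epsilon,
              100 * x$acceptance_rate))
  cat("posterior means:\n")
  print(round(colMeans(x$samples), 4))
  cat("ESS:\n")
  print(round(x$ess, 1))
  invisible(x)
}

#' Marginal credible intervals of an ABC fit
#' @param fit an [run_abc()] result.
#' @param prob central interval probability (default 0.9).
#' @return 5 x 2 matrix of lower/upper bounds.
#' @export
credible_interval <- function(fit, prob = 0.9) {
  a <- (1 - prob) / 2
  t(apply(fit$samples, 2, quantile, probs = c(a, 1 - a)))
}

#' Tune the proposal covariance and tolerance
#'
#' First runs a pilot chain at a large tolerance and sets the proposal
#' covariance from the scaled pilot sample covariance (`2.38^2/5` scaling,
#' jittered to positive definiteness; a degenerate pilot falls back to the
#' default diagonal). Then decreases the tolerance geometrically until the
#' pilot acceptance rate lies in `[0.05, 0.10]`. If the band cannot be reached
#' within the round budget, the best tolerance found is returned with a
#' warning.
#'
#' @param ref a [replicate_stats()] object.
#' @param config an [abc_config()]; its `epsilon` is used as the pilot start
#'   when finite, otherwise a start is estimated from prior-predictive
#'   distances.
#' @param pilot_budget iterations per pilot chain (>= 100).
#' @param eps_factor geometric decrease factor for the tolerance.
#' @param max_rounds maximum tuning rounds.
#' @param cov_scale scaling applied to the pilot sample covariance.
#' @return The updated `abc_config` with `epsilon` and `proposal_cov` set;
#'   the tuning trajectory is stored in attribute `"tuning"`.
#' @export
tune_abc <- function(ref, config, pilot_budget = 300L, eps_factor = 0.7,
                     max_rounds = 20L, cov_scale = 2.38^2 / 5) {
  stopifnot(pilot_budget >= 100L)
  if (!inherits(ref, "replicate_stats")) ref <- as_replicate_stats(ref)
  s_bar <- reference_stats(ref)
  sim_fn <- .make_sim_fn(config)

  # starting tolerance: prior-predictive distances if none supplied
  eps <- config$epsilon
  if (!is.finite(eps)) {
    set.seed(config$seed + 7001L)
    rho0 <- replicate(15, {
      th <- .draw_prior(config$priors)
      raw <- sim_fn(th)
      if (is.null(raw)) NA_real_
      else abc_distance(normalise_stats(raw, ref), s_bar, config$prefactor)
    })
    eps <- unname(quantile(rho0, 0.8, na.rm = TRUE))
  }

  pilot_cfg <- function(eps, cov, seed_off) {
    cfg <- config
    cfg$epsilon <- eps
    cfg$proposal_cov <- cov
    cfg$chol_cov <- chol(cov)
    cfg$chain_length <- as.integer(pilot_budget)
    cfg$warmup_abort <- NULL
    cfg$seed <- config$seed + seed_off
    cfg
  }

  # pilot at generous tolerance -> proposal covariance
  pilot <- .run_chain(config$seed + 7101L, ref,
                      pilot_cfg(eps, config$proposal_cov, 7101L),
                      sim_fn, s_bar)
  S <- cov(pilot$samples)
  cov_new <- if (any(!is.finite(S)) || any(diag(S) < 1e-10)) {
    config$proposal_cov
  } else {
    cov_scale * S + diag(1e-6, 5)
  }

  history <- data.frame(round = integer(), epsilon = numeric(),
                        acceptance = numeric())
  best <- list(eps = eps, dist = Inf)
  eps_hi <- eps
  for (r in seq_len(max_rounds)) {
    ch <- .run_chain(config$seed + 7200L + r, ref,
                     pilot_cfg(eps, cov_new, 7200L + r), sim_fn, s_bar)
    acc <- mean(ch$accepted)
    history <- rbind(history, data.frame(round = r, epsilon = eps,
                                         acceptance = acc))
    band_dist <- max(0, acc - 0.10, 0.05 - acc)
    if (band_dist < best$dist) best <- list(eps = eps, dist = band_dist)
    if (acc >= 0.05 && acc <= 0.10) break
    if (acc > 0.10) {
      eps_hi <- eps
      eps <- eps * eps_factor
    } else if (eps_hi > eps) {
      # overshot below the band: bisect back towards the last tolerance
      # that accepted too often
      eps <- sqrt(eps * eps_hi)
    } else {
      # started below the band: move up
      eps <- eps / eps_factor
      eps_hi <- eps
    }
    if (r == max_rounds)
      warning(sprintf("tuning budget exhausted; using epsilon = %.4g (closest acceptance %.3f)",
                      best$eps, acc))
  }
  out <- config
  out$epsilon <- best$eps
  out$proposal_cov <- cov_new
  out$chol_cov <- chol(cov_new)
  attr(out, "tuning") <- history
  out
}

#' Effective sample size of MCMC traces
#'
#' `ESS = M / (1 + 2 * sum_k rho_k)` with the autocorrelation sum truncated by
#' Geyer's initial positive sequence: consecutive lag pairs are summed until
#' the first non-positive pair.
#'
#' @param x numeric vector or matrix (one column per parameter) of at least 10
#'   draws.
#' @return Scalar or per-column named vector of effective sample sizes.
#' @export
effective_sample_size <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, effective_sample_size))
  M <- length(x)
  stopifnot(M >= 10)
  if (sd(x) == 0) return(1)
  rho <- drop(acf(x, lag.max = min(M - 1L, 2000L), plot = FALSE,
                  demean = TRUE)$acf)
  n_pairs <- floor(length(rho) / 2)
  tau <- NULL
  S <- 0
  for (m in seq_len(n_pairs)) {
    g <- rho[2 * m - 1] + rho[2 * m]
    if (g <= 0) break
    S <- S + g
  }
  tau <- max(2 * S - 1, 1 / M)
  min(M, M / tau)
}
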