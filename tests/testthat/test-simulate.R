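test_that("sim_params validates probabilities and stopping rules", {
  expect_error(sim_params(1.2, 0.5, 0.5, 0.5, 0.5, n_max = 10), "\\[0, 1\\]")
  expect_error(sim_params(0.5, 0.5, 0.5, 0.5, 0.5), "exactly one")
  expect_error(sim_params(0.5, 0.5, 0.5, 0.5, 0.5, n_max = 10,
                          target_area = 100), "exactly one")
  expect_error(sim_params(0.5, 0.5, 0.5, 0.5, 0.5, n_max = 0), "n_max")
  p <- sim_params(0.5, 0.5, 0.5, 0.5, 0.5, n_max = 10)
  expect_equal(unname(sim_theta(p)), rep(0.5, 5))
})

test_that("init_colony starts with one sated cell at the origin", {
  p <- sim_params(0.5, 0.5, 0.5, 0.5, 0.5, n_max = 10, seed = 1)
  col <- init_colony(p)
  expect_equal(col$n, 1L)
  expect_equal(col$type, 0L)
  expect_equal(c(col$x, col$y, col$theta), c(0, 0, 0))
  expect_error(init_colony(sim_params(0.5, 0.5, 0.5, 0.5, 0.5, n_max = 10,
                                      domain = c(5, 5))),
               "smaller than a single cell")
})

test_that("equal seeds give bit-identical colonies; the two engines agree", {
  p <- sim_params(0.67, 0.14, 0.25, 0.58, 0.12, n_max = 120, seed = 42)
  c1 <- run_simulation(p, engine = "cpp")
  c2 <- run_simulation(p, engine = "cpp")
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- run_simulation(p, engine = "r")
  expect_identical(as.data.frame(c1), as.data.frame(c3))
  expect_identical(c1$used, c3$used)
  expect_equal(c1$aborts, c3$aborts)
  # n_max = 1: founder returned untouched
  c4 <- run_simulation(sim_params(0.5, 0.5, 0.5, 0.5, 0.5, n_max = 1, seed = 3))
  expect_equal(c4$n, 1L)
})

test_that("the decision tree respects the threshold and branch probabilities", {
  # below the threshold every daughter is sated, for every seed
  for (s in 1:5) {
    col <- run_simulation(sim_params(1, 0, 1, 0, 1, n_max = 150, seed = s))
    expect_equal(sum(col$type), 0L)
  }
  # past the threshold with no pseudohyphal cells and p_sp = 1, the first
  # post-threshold daughter is pseudohyphal: the proposal for cell 22 is the
  # first with n / n_max = 21/40 > 0.5
  col <- run_simulation(sim_params(0.5, 1, 1, 0, 0, n_max = 40, seed = 9))
  expect_equal(col$type[22], 1L)
  expect_equal(sum(col$type[1:21]), 0L)

  # Monte-Carlo check of the p_sp branch against the binomial oracle:
  # all-sated colony past the threshold, forced sated mothers, p_sp = 0.25
  p <- sim_params(0.01, 1, 0.25, 0, 0, n_max = 10, seed = 1)
  col <- run_simulation(sim_params(1, 0, 0, 0, 0, n_max = 30, seed = 2))
  col$params <- p # n / n_max = 3 > n_star: post-threshold branch
  set.seed(11)
  n_draw <- 20000
  hits <- 0L
  n_ok <- 0L
  for (i in seq_len(n_draw)) {
    pr <- propose_event(col)
    if (pr$abort) next # daughter type is drawn before the site, independently
    n_ok <- n_ok + 1L
    if (pr$daughter_type == 1L) hits <- hits + 1L
  }
  se <- sqrt(0.25 * 0.75 / n_ok)
  expect_lt(abs(hits / n_ok - 0.25), 3 * se)
})

test_that("pseudohyphal mothers bud distally; lineage flags stay consistent", {
  col <- run_simulation(sim_params(0.3, 0.2, 0.3, 0.3, 0.2, n_max = 400,
                                   seed = 5))
  df <- as.data.frame(col)
  expect_gt(sum(df$type == "pseudohyphal"), 0)
  # every pseudohyphal cell's daughters used only distal sites (1, 2)
  pseudo <- which(df$type == "pseudohyphal")
  for (i in pseudo) {
    sites_used <- which(bitwAnd(col$used[i], bitwShiftL(1L, 0:3)) != 0L)
    expect_true(all(sites_used %in% 1:2))
  }
  # flag <=> exists a pseudohyphal child (lineage audit)
  has_pd_truth <- vapply(seq_len(col$n), function(i)
    any(df$mother_id == i & df$type == "pseudohyphal", na.rm = TRUE),
    logical(1))
  expect_identical(col$has_pd, has_pd_truth)
  # conservation: each cell's mother precedes it; cells never mutate type
  expect_true(all(df$mother_id[-1] < df$id[-1]))
})

test_that("attempt_insertion enforces volume exclusion and the domain", {
  p <- sim_params(1, 0, 0, 0, 0, n_max = 10, seed = 1)
  col <- init_colony(p)
  prop <- list(abort = FALSE, mother = 1L, daughter_type = 0L, site = 1L)
  # first daughter in an empty domain succeeds
  res <- attempt_insertion(col, prop)
  expect_true(res$accepted)
  expect_equal(res$colony$n, 2L)
  expect_equal(res$colony$used[1], 1L)
  # a cell already sitting at the would-be daughter centre blocks the event
  pose_centre <- c(res$colony$x[2], res$colony$y[2])
  blocked <- manual_colony(c(0, pose_centre[1]), c(0, pose_centre[2]),
                           c(0, 0), p)
  res2 <- attempt_insertion(blocked, prop)
  expect_false(res2$accepted)
  expect_equal(res2$colony$n, 2L)
  # a domain too tight for the daughter rejects the event
  p_small <- sim_params(1, 0, 0, 0, 0, n_max = 10,
                        domain = c(13, 13), seed = 1)
  res3 <- attempt_insertion(init_colony(p_small), prop)
  expect_false(res3$accepted)
})

test_that("a jammed colony stalls with a warning instead of livelocking", {
  # tiny domain: the founder fits but few daughters do
  p <- sim_params(1, 0, 0, 0, 0, n_max = 500, domain = c(26, 26),
                  seed = 4, max_consecutive_aborts = 500)
  expect_warning(col <- run_simulation(p), "stalled")
  expect_true(col$stalled)
  expect_lt(col$n, 500)
})

test_that("n_star drives filamentation: lower threshold, higher I_F", {
  i_f <- function(n_star, seeds) {
    sapply(seeds, function(s) {
      th <- fig10b_theta
      th[1] <- n_star
      col <- run_simulation(sim_params(th[1], th[2], th[3], th[4], th[5],
                                       n_max = 600, seed = s))
      filament_area_ratio(colony_to_mask(col))
    })
  }
  seeds <- 1:6
  expect_gt(mean(i_f(0.67, seeds)), mean(i_f(0.95, seeds)))
})

test_that("area-mode stopping lands within tolerance of the target", {
  p <- sim_params(0.67, 0.14, 0.25, 0.58, 0.12, target_area = 20000, seed = 5)
  col <- run_simulation(p)
  area <- sum(colony_to_mask(col)$pixels)
  expect_gte(area, 20000 * 0.95)
  expect_lte(area, 20000 * 1.05)
})

test_that("colony_to_mask matches an area oracle and scales with resolution", {
  # a single circular cell of radius 10 um
  ct <- list(sated = cell_type("sated", 10, 10, pi / 4),
             pseudohyphal = cell_type("pseudohyphal", 10, 5, pi / 16))
  p <- sim_params(1, 0, 0, 0, 0, n_max = 1, seed = 1, cell_types = ct)
  col <- init_colony(p)
  m1 <- colony_to_mask(col, px_per_um = 1)
  expect_lt(abs(sum(m1$pixels) - pi * 100) / (pi * 100), 0.02)
  m2 <- colony_to_mask(col, px_per_um = 2)
  expect_lt(abs(sum(m2$pixels) / sum(m1$pixels) - 4), 0.05)
  expect_equal(m2$px_size, 0.5)
  # rasterisation is deterministic
  expect_identical(colony_to_mask(col, px_per_um = 1)$pixels, m1$pixels)
})

test_that("insertion failures accumulate as the core gets crowded", {
  # compare abort counts of the first and second growth halves
  p <- sim_params(1, 0, 0, 0, 0, n_max = 600, seed = 8)
  col_half <- init_colony(p)
  col_half <- filacol:::.grow_cpp(col_half, 300)
  aborts_first <- col_half$aborts
  col_full <- filacol:::.grow_cpp(col_half, 600)
  aborts_second <- col_full$aborts - aborts_first
  expect_gt(aborts_second, aborts_first)
})
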