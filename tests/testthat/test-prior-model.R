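# Stage-1 prior: time bases, the 14-specification lattice, mixed-model
# fitting, prediction assembly, and hold-out model selection.

test_that("linear basis is a centered-year column", {
  B <- build_time_basis(2000:2013, "linear")
  expect_equal(ncol(B), 1L)
  expect_equal(drop(B)[which(2000:2013 == 2006)], -0.5)  # 2006 - 2006.5
  expect_equal(sum(drop(B)), 0)
  expect_error(build_time_basis(2005, "linear"), "distinct years")
})

test_that("ncs1 basis spans the textbook natural-spline space", {
  # truncated-power construction (Hastie et al.): with knots k1 < k2 < k3
  # (boundary, interior, boundary) the natural-spline space is spanned by
  # {1, x, d1(x) - d2(x)} with d_j(x) = [(x-k_j)_+^3 - (x-k_3)_+^3]/(k_3-k_j)
  years <- c(2000, 2003, 2006, 2010, 2013)
  B <- build_time_basis(years, "ncs1")
  expect_equal(ncol(B), 2L)
  grid <- seq(1998, 2015, by = 0.25)
  Bg <- eval_time_basis(grid, attr(B, "info"))
  k <- c(2000, median(years), 2013)
  dj <- function(x, kj) (pmax(x - kj, 0)^3 - pmax(x - k[3], 0)^3) /
    (k[3] - kj)
  oracle <- cbind(1, grid, dj(grid, k[1]) - dj(grid, k[2]))
  for (j in 1:2) {
    fitted <- oracle %*% qr.solve(oracle, Bg[, j])
    expect_equal(drop(fitted), Bg[, j], tolerance = 1e-8)
  }
})

test_that("ncs1 basis is linear beyond the boundary knots", {
  B <- build_time_basis(2000:2013, "ncs1")
  left <- eval_time_basis(seq(1990, 1999, by = 1), attr(B, "info"))
  right <- eval_time_basis(seq(2014, 2023, by = 1), attr(B, "info"))
  for (side in list(left, right)) {
    second_diff <- apply(side, 2, function(col) diff(diff(col)))
    expect_lt(max(abs(second_diff)), 1e-10)
  }
  expect_error(build_time_basis(c(2000, 2001), "ncs1"), "distinct years")
})

test_that("the specification lattice has exactly 14 members, deterministically", {
  specs <- enumerate_specs()
  expect_length(specs, 14L)
  ids <- vapply(specs, function(s) s$id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(ids, vapply(enumerate_specs(), function(s) s$id,
                               character(1)))
  expect_true("linear|fixed" %in% ids)                 # plain OLS member
  expect_true("ncs1|u_s+u_z+b_s+b_z" %in% ids)         # fully loaded member
  # slope-requires-intercept is enforced
  expect_error(prior_spec("linear", "b_s"), "requires")
  expect_error(prior_spec("ncs1", c("u_s", "b_z")), "requires")
})

test_that("the fixed-effects-only spec equals closed-form least squares", {
  d <- make_line_data(noise_sd = 0.3, seed = 4)
  f <- fit_prior(d, prior_spec("linear", character()))
  X <- cbind(1, d$year - mean(range(d$year)))
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(c(f$alpha, f$beta)), drop(beta_hat), tolerance = 1e-8)
})

test_that("noise-free lines and constants are recovered exactly", {
  d <- make_line_data(states = "Lagos", zones = "South West", noise_sd = 0)
  expect_warning(f <- fit_prior(d, prior_spec("linear", character())), NA)
  expect_equal(f$alpha, 2, tolerance = 1e-8)
  expect_equal(unname(f$beta), 0.1, tolerance = 1e-8)
  # prediction at observed years of the noise-free fit equals the data
  expect_equal(predict_prior(f, "Lagos", d$year), d$y, tolerance = 1e-8)

  const <- d
  const$y <- 1.3
  fc <- fit_prior(const, prior_spec("linear", character()))
  expect_equal(fc$alpha, 1.3, tolerance = 1e-10)
  expect_equal(unname(fc$beta), 0, tolerance = 1e-10)
})

test_that("prediction equals manual assembly of the stored components", {
  cfg <- sim_config(basis = "ncs1")
  sim <- simulate_truth(cfg, seed = 21)
  est <- simulate_surveys(sim$truth, cfg, seed = 22)
  lg <- to_logit(est$p, est$var_p)
  d <- tibble::tibble(state = est$state, zone = est$zone, year = est$year,
                      y = lg$y)
  f <- suppressWarnings(
    fit_prior(d, prior_spec("ncs1", c("u_s", "u_z", "b_s", "b_z"))))
  years <- 2000:2013
  B <- eval_time_basis(years, f$basis_info)
  for (s in c("Lagos", "Zamfara", "FCT")) {
    z <- unname(f$state_zone[s])
    manual <- f$alpha + drop(B %*% (f$beta + f$b_s[s, ] + f$b_z[z, ])) +
      f$u_s[[s]] + f$u_z[[z]]
    expect_equal(predict_prior(f, s, years), manual, tolerance = 1e-12)
  }
  expect_error(predict_prior(f, "Atlantis", years), "unknown state")
})

test_that("zone terms are dropped with a warning on single-zone data", {
  d <- make_line_data(states = c("Lagos", "Ogun"),
                      zones = c("South West", "South West"),
                      noise_sd = 0.2, seed = 9)
  expect_warning(f <- fit_prior(d, prior_spec("linear", c("u_s", "u_z"))),
                 "zone terms")
  expect_true(all(f$u_z == 0))
})

test_that("random effects never worsen in-sample fit for nested specs", {
  cfg <- sim_config()
  sim <- simulate_truth(cfg, seed = 31)
  est <- simulate_surveys(sim$truth, cfg, seed = 32)
  lg <- to_logit(est$p, est$var_p)
  d <- tibble::tibble(state = est$state, zone = est$zone, year = est$year,
                      y = lg$y)
  pairs <- list(
    c("linear|fixed", "linear|u_s"),
    c("linear|u_s", "linear|u_s+u_z"),
    c("linear|u_s+u_z", "linear|u_s+u_z+b_s+b_z")
  )
  specs <- enumerate_specs()
  ids <- vapply(specs, function(s) s$id, character(1))
  insample <- function(id) {
    f <- suppressWarnings(fit_prior(d, specs[[which(ids == id)]]))
    rmse(d$y - predict_prior_rows(f, d$state, d$zone, d$year))
  }
  # REML shrinkage of the random effects can nudge in-sample RMSE up by a
  # hair, so the comparison carries a small absolute slack
  for (pr in pairs) {
    expect_lte(insample(pr[2]), insample(pr[1]) + 1e-3)
  }
})

test_that("hold-out RMSE arithmetic and determinism", {
  expect_equal(rmse(c(0, 0, 0)), 0)
  expect_equal(rmse(c(3, 4)), sqrt((9 + 16) / 2))

  d <- make_line_data(states = c("Lagos", "Kano", "Enugu"),
                      zones = c("South West", "North West", "South East"),
                      noise_sd = 0.2, seed = 5)
  specs <- enumerate_specs()[c(1, 2)]
  cv1 <- suppressMessages(cv_select(d, specs, reps = 5, seed = 99))
  cv2 <- suppressMessages(cv_select(d, specs, reps = 5, seed = 99))
  expect_identical(cv1$rmse, cv2$rmse)
  expect_identical(cv1$selected$id, cv2$selected$id)
  expect_true(cv1$table$selected[cv1$table$id == cv1$selected$id])
  expect_equal(cv1$table$mean_rmse[cv1$table$selected],
               min(cv1$table$mean_rmse))
})

test_that("cross-validation prefers the spline family under strong curvature", {
  cfg <- sim_config(basis = "ncs1", beta = c(2.4, 1.4),
                    sd_u_s = 0.3, sd_u_z = 0.2)
  picks <- vapply(1:8, function(r) {
    sim <- simulate_truth(cfg, seed = 400 + r)
    est <- simulate_surveys(sim$truth, cfg, seed = 500 + r)
    lg <- to_logit(est$p, est$var_p)
    d <- tibble::tibble(state = est$state, zone = est$zone,
                        year = est$year, y = lg$y)
    cv <- suppressMessages(cv_select(d, reps = 8, seed = 600 + r))
    cv$selected$basis
  }, character(1))
  expect_gte(mean(picks == "ncs1"), 0.8)
})

test_that("fixed effects are recovered without bias on simulated data", {
  # moderate-size version of the recovery property (the acceptance suite
  # runs the full 200-replicate check)
  cfg <- sim_config(basis = "ncs1")
  ests <- t(vapply(1:40, function(r) {
    sim <- simulate_truth(cfg, seed = 700 + r)
    est <- simulate_surveys(sim$truth, cfg, seed = 800 + r)
    lg <- to_logit(est$p, est$var_p)
    d <- tibble::tibble(state = est$state, zone = est$zone,
                        year = est$year, y = lg$y)
    # basis knots must match the generator's (built on the full grid) for
    # the coefficients to be comparable
    f <- suppressWarnings(fit_prior(d, prior_spec("ncs1", c("u_s", "u_z")),
                                    ref_years = cfg$years))
    c(f$alpha, f$beta)
  }, numeric(3)))
  truth <- c(cfg$alpha, cfg$beta)
  for (j in 1:3) {
    mc_se <- sd(ests[, j]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, j]) - truth[j]), 2 * mc_se + 1e-8)
  }
})
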