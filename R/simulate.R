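# Synthetic-data generator: logit-scale truths with zone/state random
# intercepts and slopes (the generative twin of the stage-1 model), sparse
# irregular binomial survey estimates with design effects, piecewise-constant
# hazard birth histories, and a population/births table. Every stage of the
# pipeline is testable against a known truth without any external data.

#' Simulation configuration
#'
#' Defaults mirror the real application's conditions: 37 states in 6 zones,
#' annual grid 2000-2013, a rising logit-scale coverage trend with moderate
#' between-zone and between-state heterogeneity, and a sparse survey plan of
#' 6 irregular survey years with DHS-scale state samples (n = 400 per state)
#' and a design effect of 1.5.
#'
#' @param states tibble of `state`, `zone` (default [nigeria_states()]).
#' @param years annual grid (default 2000:2013).
#' @param basis truth trend family, `"linear"` or `"ncs1"`.
#' @param alpha logit-scale intercept at the grid midpoint.
#' @param beta time coefficient(s): length 1 for linear, 2 for ncs1.
#' @param sd_u_s,sd_u_z SDs of state / zone random intercepts (logit scale).
#' @param sd_b_s,sd_b_z SDs of state / zone random slopes.
#' @param sigma_eps residual SD of survey-level deviations (used by the
#'   stage-1 recovery tests; sampling noise is added separately by
#'   [simulate_surveys()]).
#' @param survey_years survey years (default irregular: 2003, 2007, 2008,
#'   2010, 2011, 2013).
#' @param n_per_state respondents per state per survey (default 400).
#' @param deff design effect (variance inflation, >= 1; default 1.5).
#' @param hazard monthly death hazards per age segment of
#'   [u5m_age_segments()] (default: a schedule with 5q0 of about 0.17).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(states = nigeria_states(), years = 2000:2013,
                       basis = c("linear", "ncs1"),
                       alpha = qlogis(0.40), beta = NULL,
                       sd_u_s = 0.5, sd_u_z = 0.3,
                       sd_b_s = 0.02, sd_b_z = 0.01,
                       sigma_eps = 0.1,
                       survey_years = c(2003, 2007, 2008, 2010, 2011, 2013),
                       n_per_state = 400, deff = 1.5,
                       hazard = c(0.030, 0.0065, 0.0040, 0.0018, 0.0012,
                                  0.0008, 0.0006)) {
  basis <- match.arg(basis)
  if (is.null(beta)) {
    beta <- if (basis == "linear") 0.045 else c(0.9, 0.6)
  }
  if (any(c(sd_u_s, sd_u_z, sd_b_s, sd_b_z) < 0)) stop("SDs must be >= 0")
  if (deff < 1) stop("design effect must be >= 1")
  structure(list(states = states, years = years, basis = basis,
                 alpha = alpha, beta = beta,
                 sd_u_s = sd_u_s, sd_u_z = sd_u_z,
                 sd_b_s = sd_b_s, sd_b_z = sd_b_z,
                 sigma_eps = sigma_eps,
                 survey_years = survey_years, n_per_state = n_per_state,
                 deff = deff, hazard = hazard),
            class = "sim_config")
}

#' Simulate true state-year proportions
#'
#' Draws zone and state random intercepts/slopes from mean-zero normals with
#' the configured SDs and assembles
#' `truth = invlogit(alpha + T(beta + b_s + b_z) + u_s + u_z)`. The realized
#' effects are returned so recovery tests can compare against them.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return list with `truth` (tibble `state`, `zone`, `year`, `p`, `y`),
#'   `effects` (realized random effects), and `config`.
#' @export
simulate_truth <- function(config = sim_config(), seed = 1) {
  withr::with_seed(seed, {
    st <- config$states
    zones <- unique(st$zone)
    k <- length(config$beta)
    u_s <- setNames(rnorm(nrow(st), 0, config$sd_u_s), st$state)
    u_z <- setNames(rnorm(length(zones), 0, config$sd_u_z), zones)
    b_s <- matrix(rnorm(nrow(st) * k, 0, config$sd_b_s), ncol = k,
                  dimnames = list(st$state, NULL))
    b_z <- matrix(rnorm(length(zones) * k, 0, config$sd_b_z), ncol = k,
                  dimnames = list(zones, NULL))
    B <- build_time_basis(config$years, config$basis,
                          ref_years = config$years)
    truth <- dplyr::bind_rows(lapply(seq_len(nrow(st)), function(i) {
      s <- st$state[i]; z <- st$zone[i]
      y <- config$alpha + drop(B %*% (config$beta + b_s[s, ] + b_z[z, ])) +
        u_s[s] + u_z[z]
      tibble::tibble(state = s, zone = z, year = config$years,
                     y = y, p = plogis(y))
    }))
    list(truth = truth,
         effects = list(u_s = u_s, u_z = u_z, b_s = b_s, b_z = b_z),
         config = config)
  })
}

#' Simulate survey estimates around a truth
#'
#' Per survey year and state, successes are binomial with the effective
#' sample size `n / deff`, giving `p_hat` and the binomial sampling variance
#' `p_hat (1 - p_hat) / n_eff`; proportions are clamped into the standard
#' band before storage.
#'
#' @param truth truth tibble from [simulate_truth()]`$truth`.
#' @param config a `sim_config` (supplies the survey plan).
#' @param seed integer seed.
#' @return estimates tibble in the [weighted_tabulate()] layout.
#' @export
simulate_surveys <- function(truth, config = sim_config(), seed = 1) {
  withr::with_seed(seed, {
    n_eff <- round(config$n_per_state / config$deff)
    rows <- truth[truth$year %in% config$survey_years, ]
    p_hat <- rbinom(nrow(rows), n_eff, rows$p) / n_eff
    p <- clamp_proportion(p_hat)
    tibble::tibble(
      indicator = "simulated", state = rows$state, zone = rows$zone,
      year = rows$year, p = p,
      var_p = pmax(p * (1 - p) / n_eff, 1e-8),
      source_id = paste0("survey_", rows$year),
      flags = ""
    )
  })
}

#' Simulate complete birth histories under piecewise-constant hazards
#'
#' Children are born uniformly over the cohort years (uniform month);
#' survival is simulated segment by segment with exponential waiting times at
#' the configured monthly hazards; censoring occurs at the survey date.
#'
#' @param n_children number of children.
#' @param config a `sim_config` (supplies the hazard schedule).
#' @param cohort_years years over which births occur.
#' @param survey_year interview year (censoring time; interviews mid-year).
#' @param state,survey_id labels attached to the records.
#' @param seed integer seed.
#' @return birth-history tibble for [cbh_5q0()].
#' @export
simulate_birth_histories <- function(n_children, config = sim_config(),
                                     cohort_years = 2000:2012,
                                     survey_year = 2013,
                                     state = "StateA",
                                     survey_id = "sim_survey", seed = 1) {
  withr::with_seed(seed, {
    seg <- u5m_age_segments()
    haz <- config$hazard
    stopifnot(length(haz) == nrow(seg))
    birth_year <- sample(cohort_years, n_children, replace = TRUE)
    birth_month <- sample.int(12, n_children, replace = TRUE)
    # age at death: exponential within each constant-hazard segment
    age_death <- rep(NA_real_, n_children)
    alive <- rep(TRUE, n_children)
    for (k in seq_len(nrow(seg))) {
      width <- seg$a1[k] - seg$a0[k]
      t_k <- if (haz[k] > 0) rexp(n_children, rate = haz[k]) else
        rep(Inf, n_children)
      dies <- alive & t_k < width
      age_death[dies] <- seg$a0[k] + t_k[dies]
      alive <- alive & !dies
    }
    censor <- 12 * survey_year + 6 - (12 * birth_year + (birth_month - 1))
    died <- !is.na(age_death) & age_death < censor
    tibble::tibble(
      survey_id = survey_id, state = state,
      weight = 1,
      birth_year = birth_year, birth_month = birth_month,
      died = died,
      age_death_months = ifelse(died, age_death, NA_real_),
      censor_age_months = censor
    )
  })
}

#' Simulate a population and live-births table
#'
#' Log-normal state sizes (configurable skew) growing at a constant annual
#' rate; live births are a fixed fraction of population.
#'
#' @param config a `sim_config`.
#' @param skew SD of log state size (default 0.5).
#' @param growth annual growth rate (default 0.025).
#' @param birth_rate births per person-year (default 0.04).
#' @param seed integer seed.
#' @return tibble `state`, `year`, `population`, `live_births`.
#' @export
simulate_population <- function(config = sim_config(), skew = 0.5,
                                growth = 0.025, birth_rate = 0.04,
                                seed = 1) {
  withr::with_seed(seed, {
    st <- config$states
    base <- exp(rnorm(nrow(st), log(3e6), skew))
    dplyr::bind_rows(lapply(seq_len(nrow(st)), function(i) {
      pop <- base[i] * (1 + growth)^(config$years - min(config$years))
      tibble::tibble(state = st$state[i], year = config$years,
                     population = pop, live_births = birth_rate * pop)
    }))
  })
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits the CSV inputs the pipeline consumes: survey estimates, population
#' table, birth histories, and the underlying truth.
#'
#' @param dir output directory (created if needed).
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return invisibly, the paths written.
#' @export
write_simulation_bundle <- function(dir, config = sim_config(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_truth(config, seed = seed)
  est <- simulate_surveys(sim$truth, config, seed = seed + 1)
  pop <- simulate_population(config, seed = seed + 2)
  bh <- simulate_birth_histories(5000, config, seed = seed + 3)
  paths <- file.path(dir, c("estimates.csv", "population.csv",
                            "birth_histories.csv", "truth.csv"))
  utils::write.csv(est, paths[1], row.names = FALSE)
  utils::write.csv(pop, paths[2], row.names = FALSE)
  utils::write.csv(bh, paths[3], row.names = FALSE)
  utils::write.csv(sim$truth, paths[4], row.names = FALSE)
  invisible(paths)
}
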