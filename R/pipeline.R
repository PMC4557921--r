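# End-to-end wrapper: harmonized state-year estimates in, per-state posterior
# draws and summaries out.

#' Estimate state-level annual trends for one indicator
#'
#' Runs the two-stage model: (1) logit-transform the non-excluded estimates
#' and fit the stage-1 mixed-effects prior (selected by hold-out
#' cross-validation unless a specification is supplied); (2) per state,
#' condition a Matern Gaussian process on the state's observations around the
#' stage-1 mean and draw from the posterior. The GP amplitude defaults to the
#' robust stage-1 residual scale.
#'
#' @param estimates estimates tibble (columns `state`, `zone`, `year`, `p`,
#'   `var_p`, `flags`, ...).
#' @param years annual estimation grid (default 2000:2013).
#' @param spec a `prior_spec` to use directly, or `NULL` to select one by
#'   [cv_select()].
#' @param cv_reps hold-out replicates when selecting (default 100).
#' @param nu,length_scale Matern hyperparameters (defaults 3/2 and 5 years).
#' @param amplitude GP prior SD; `NULL` (default) uses [gp_amplitude()] of
#'   the stage-1 residuals.
#' @param n_draws posterior draws per state (default 1000).
#' @param seed integer seed controlling CV splits and posterior draws.
#' @return list of class `mch_trends`: `summary` (tibble `state`, `year`,
#'   `median`, `lower`, `upper`), `draws` (named list of `posterior_draws`),
#'   `prior_fit`, `cv` (or `NULL`), `config`.
#' @export
estimate_trends <- function(estimates, years = 2000:2013, spec = NULL,
                            cv_reps = 100, nu = 3 / 2, length_scale = 5,
                            amplitude = NULL, n_draws = 1000, seed = 1) {
  est <- drop_excluded(estimates)
  if (nrow(est) == 0) stop("no usable estimates after exclusions")
  lg <- to_logit(est$p, est$var_p)
  data <- tibble::tibble(state = est$state, zone = est$zone,
                         year = est$year, y = lg$y, var_y = lg$var_y)

  cv <- NULL
  if (is.null(spec)) {
    cv <- cv_select(data, reps = cv_reps, seed = seed)
    spec <- cv$selected
  }
  fit <- suppressWarnings(fit_prior(data, spec))

  if (is.null(amplitude)) {
    fitted_vals <- predict_prior_rows(fit, data$state, data$zone, data$year)
    amplitude <- gp_amplitude(data$y - fitted_vals)
    if (amplitude <= 0) amplitude <- fit$sigma_eps
  }

  states <- sort(unique(data$state))
  draws <- list()
  for (i in seq_along(states)) {
    s <- states[i]
    cfg <- gp_config(nu = nu, length_scale = length_scale,
                     amplitude = amplitude, n_draws = n_draws,
                     seed = seed + i)
    obs <- data[data$state == s, c("year", "y", "var_y")]
    draws[[s]] <- gp_smooth_state(fit, s, obs, years = years, config = cfg)
  }
  summary <- dplyr::bind_rows(lapply(draws, summarize_draws,
                                     rule = if (n_draws == 1000) "canonical"
                                            else "quantile"))
  structure(list(summary = summary, draws = draws, prior_fit = fit, cv = cv,
                 config = list(nu = nu, length_scale = length_scale,
                               amplitude = amplitude, n_draws = n_draws,
                               years = years, seed = seed)),
            class = "mch_trends")
}

#' @export
print.mch_trends <- function(x, ...) {
  cat("<mch_trends>", length(x$draws), "states,",
      length(x$config$years), "years,", x$config$n_draws, "draws\n")
  cat("  prior:", x$prior_fit$spec$id,
      " amplitude:", format(x$config$amplitude, digits = 3), "\n")
  invisible(x)
}

#' Read tabulated estimates, population tables, and birth histories
#'
#' Thin readers for the pipeline's delimited interfaces.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
read_estimates <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  req <- c("indicator", "state", "zone", "year", "p", "var_p", "source_id")
  miss <- setdiff(req, names(out))
  if (length(miss)) stop("estimates file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"flags" %in% names(out)) out$flags <- ""
  out$flags[is.na(out$flags)] <- ""
  out
}

#' @rdname pipeline-io
#' @export
read_population <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  miss <- setdiff(c("state", "year"), names(out))
  if (length(miss)) stop("population file missing column(s): ",
                         paste(miss, collapse = ", "))
  out
}

#' @rdname pipeline-io
#' @export
read_birth_histories <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  if ("birth_ym" %in% names(out) && !"birth_year" %in% names(out)) {
    parts <- strsplit(as.character(out$birth_ym), "-", fixed = TRUE)
    out$birth_year <- as.integer(vapply(parts, `[`, "", 1))
    out$birth_month <- as.integer(vapply(parts, `[`, "", 2))
  }
  req <- c("weight", "birth_year", "birth_month", "died",
           "age_death_months", "censor_age_months")
  miss <- setdiff(req, names(out))
  if (length(miss)) stop("birth-history file missing column(s): ",
                         paste(miss, collapse = ", "))
  out
}

#' Population weights for aggregation
#'
#' Selects the weighting basis: total population for coverage indicators,
#' live births for the birth-cohort mortality series.
#'
#' @param pops tibble from [read_population()] or [simulate_population()].
#' @param basis `"population"` or `"live_births"`.
#' @return tibble `state`, `year`, `value`.
#' @export
population_weights <- function(pops, basis = c("population", "live_births")) {
  basis <- match.arg(basis)
  if (!basis %in% names(pops)) stop("population table has no '", basis,
                                    "' column")
  tibble::tibble(state = pops$state, year = pops$year,
                 value = pops[[basis]])
}
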