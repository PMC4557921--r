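# Under-5 mortality stage: period 5q0 from complete birth histories by the
# synthetic-cohort life-table method, a one-knot natural-spline mixed model
# with state and survey random intercepts for smoothing, and year-specific
# scaling of the state series to a reference national series.

#' Standard under-5 age segments (months)
#'
#' The canonical complete-birth-history segments: 0, 1-5, 6-11, 12-23,
#' 24-35, 36-47, 48-59 months, expressed as half-open intervals `[a0, a1)`.
#'
#' @return tibble with columns `a0`, `a1`.
#' @export
u5m_age_segments <- function() {
  tibble::tibble(
    a0 = c(0, 1, 6, 12, 24, 36, 48),
    a1 = c(1, 6, 12, 24, 36, 48, 60)
  )
}

#' Period 5q0 from complete birth histories (synthetic cohort)
#'
#' Within one calendar-year period, each age segment's death probability is
#' estimated as weighted deaths over weighted potential exposure: a child
#' contributes the fraction of the segment it would spend inside the period
#' if it survived (deaths do not truncate their own segment's denominator,
#' the actuarial convention that keeps each q in \[0,1\]); a death is counted
#' when it falls inside the child's exposed age window. The synthetic-cohort
#' probability is `q5 = 1 - prod(1 - q_a)`. The variance combines per-segment
#' binomial approximations (with Kish effective sample sizes) on the
#' log-survival scale.
#'
#' @param histories tibble with columns `weight`, `birth_year`,
#'   `birth_month` (1-12), `died` (logical or 0/1), `age_death_months`
#'   (NA when alive), `censor_age_months`, and optionally `state`,
#'   `survey_id`.
#' @param period calendar year.
#' @param segments age-segment table (default [u5m_age_segments()]).
#' @return one-row tibble `state`, `year`, `q5`, `var_q5`, `source_id`, or
#'   `NULL` when no segment has exposure in the period.
#' @export
cbh_5q0 <- function(histories, period, segments = u5m_age_segments()) {
  if (nrow(histories) == 0) return(NULL)
  if (any(histories$weight <= 0)) stop("weights must be positive")
  died <- as.logical(histories$died)
  d_age <- histories$age_death_months
  if (any(died & (is.na(d_age) | d_age > histories$censor_age_months))) {
    stop("deaths must have an age at death within the censoring age")
  }
  bm <- 12 * histories$birth_year + (histories$birth_month - 1)
  ps_age <- 12 * period - bm        # age (months) at period start
  pe_age <- ps_age + 12             # age at period end
  w <- histories$weight

  q <- var_q <- numeric(nrow(segments))
  any_exposure <- FALSE
  for (k in seq_len(nrow(segments))) {
    a0 <- segments$a0[k]; a1 <- segments$a1[k]
    lo <- pmax(a0, ps_age)
    hi <- pmin(a1, pe_age)
    # potential exposure if the child survived the segment, censored for
    # children still alive at interview
    end_alive <- pmin(hi, histories$censor_age_months)
    f <- ifelse(died,
                ifelse(d_age >= lo, pmax(0, hi - lo), 0),
                pmax(0, end_alive - lo)) / (a1 - a0)
    death_here <- died & d_age >= lo & d_age < hi
    wf <- w * f
    N <- sum(wf)
    if (N <= 0) next
    any_exposure <- TRUE
    D <- sum(w[death_here])
    q[k] <- min(D / N, 0.999)
    n_eff <- N^2 / sum(wf^2)
    var_q[k] <- q[k] * (1 - q[k]) / n_eff
  }
  if (!any_exposure) return(NULL)

  q5 <- min(1 - prod(1 - q), 0.999)
  var_log_s <- sum(var_q / (1 - q)^2)
  var_q5 <- max((1 - q5)^2 * var_log_s, 1e-8)
  tibble::tibble(
    state = if ("state" %in% names(histories)) {
      as.character(histories$state[1])
    } else NA_character_,
    year = as.integer(period),
    q5 = q5,
    var_q5 = var_q5,
    source_id = if ("survey_id" %in% names(histories)) {
      as.character(histories$survey_id[1])
    } else NA_character_
  )
}

#' Smooth state 5q0 series with a one-knot spline mixed model
#'
#' Logit-transforms the source-year 5q0 estimates and fits a natural cubic
#' spline in year (one interior knot) with IID random intercepts for state
#' and for survey source; the survey intercepts absorb systematic
#' source-level offsets and are marginalized out of the state predictions.
#' Uncertainty is carried by parametric-bootstrap draws: fixed effects
#' sampled from their estimated sampling distribution, state intercepts from
#' their conditional (posterior) distribution.
#'
#' @param estimates tibble with columns `state`, `year`, `q5`, `source_id`.
#' @param year_grid annual estimation grid (default 2000:2013).
#' @param n_draws number of bootstrap draws (default 1000).
#' @param seed integer seed.
#' @return list with `trends` (tibble `state`, `year`, `q5`, `lower`,
#'   `upper`), `draws` (named list of year x draw matrices on the q5 scale),
#'   `model`, and `years`.
#' @export
fit_u5m_trend <- function(estimates, year_grid = 2000:2013, n_draws = 1000,
                          seed = NULL) {
  if (length(unique(estimates$source_id)) < 2 &&
      length(unique(estimates$year)) < 2) {
    stop("need at least two sources or two years to fit a trend")
  }
  y <- qlogis(clamp_proportion(estimates$q5))
  uy <- sort(unique(estimates$year))
  basis_type <- if (length(uy) >= 3) "ncs1" else "linear"
  B <- build_time_basis(estimates$year, basis_type, ref_years = uy)
  info <- attr(B, "info")
  bnames <- colnames(B)
  df <- data.frame(y = y, B, state = factor(estimates$state),
                   source = factor(estimates$source_id))

  re_terms <- c(
    if (nlevels(df$state) > 1) "(1 | state)",
    if (nlevels(df$source) > 1) "(1 | source)"
  )
  fixed <- paste("y ~ 1 +", paste(bnames, collapse = " + "))
  if (length(re_terms) == 0) {
    model <- lm(as.formula(fixed), data = df)
    fe <- coef(model); vb <- vcov(model)
    u_s <- setNames(rep(0, nlevels(df$state)), levels(df$state))
    pv <- setNames(rep(0, nlevels(df$state)), levels(df$state))
  } else {
    fml <- as.formula(paste(c(fixed, re_terms), collapse = " + "))
    model <- lme4::lmer(fml, data = df, REML = TRUE,
                        control = lme4::lmerControl(
                          calc.derivs = FALSE,
                          check.conv.singular = "ignore"))
    fe <- lme4::fixef(model); vb <- as.matrix(vcov(model))
    re <- lme4::ranef(model, condVar = TRUE)
    if (!is.null(re$state)) {
      u_s <- setNames(re$state[["(Intercept)"]], rownames(re$state))
      pv <- setNames(drop(attr(re$state, "postVar")), rownames(re$state))
    } else {
      u_s <- setNames(rep(0, nlevels(df$state)), levels(df$state))
      pv <- u_s
    }
  }

  Bg <- eval_time_basis(year_grid, info)
  X <- cbind(1, Bg)
  states <- levels(df$state)

  sim <- function() {
    Lb <- chol(vb + diag(1e-12, nrow(vb)))
    beta_d <- fe + t(Lb) %*% matrix(rnorm(length(fe) * n_draws),
                                    nrow = length(fe))
    draws <- list()
    for (s in states) {
      us_d <- rnorm(n_draws, mean = u_s[s], sd = sqrt(pv[s]))
      eta <- X %*% beta_d + matrix(us_d, nrow = nrow(X), ncol = n_draws,
                                   byrow = TRUE)
      draws[[s]] <- plogis(eta)
    }
    draws
  }
  draws <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())

  trends <- dplyr::bind_rows(lapply(states, function(s) {
    point <- plogis(drop(X %*% fe) + u_s[s])
    qs <- apply(draws[[s]], 1, quantile, probs = c(0.025, 0.975),
                names = FALSE)
    tibble::tibble(state = s, year = year_grid, q5 = point,
                   lower = qs[1, ], upper = qs[2, ])
  }))
  list(trends = trends, draws = draws, model = model, years = year_grid)
}

#' Scale state mortality series to a reference national series
#'
#' Per year, the scaling factor is `reference_t` divided by the
#' births-weighted national aggregate of the state estimates; every state's
#' estimate (and each draw) is multiplied by it, so the re-aggregated
#' national series reproduces the reference exactly. Between-state ratios
#' within each year are preserved.
#'
#' @param trends tibble `state`, `year`, `q5` (and optionally
#'   `lower`/`upper`, scaled alongside).
#' @param pops tibble `state`, `year`, `value` with live births.
#' @param reference tibble `year`, `q5` covering the trend years.
#' @param draws optional named list of year x draw q5-scale matrices (year
#'   order must match `sort(unique(trends$year))`).
#' @return list with scaled `trends`, `factors` (tibble `year`, `factor`),
#'   and scaled `draws` (if supplied).
#' @export
scale_to_reference <- function(trends, pops, reference, draws = NULL) {
  years <- sort(unique(trends$year))
  if (!all(years %in% reference$year)) {
    stop("reference series must cover every trend year")
  }
  factors <- vapply(years, function(t) {
    sub <- trends[trends$year == t, ]
    w <- vapply(sub$state, function(s) {
      v <- pops$value[pops$state == s & pops$year == t]
      if (length(v) != 1L) stop("missing births for ", s, " in ", t)
      v
    }, numeric(1))
    agg <- sum(w / sum(w) * sub$q5)
    if (agg <= 0) stop("zero national aggregate in ", t)
    reference$q5[reference$year == t] / agg
  }, numeric(1))
  fmap <- setNames(factors, years)

  out <- trends
  r <- unname(fmap[as.character(out$year)])
  for (col in intersect(c("q5", "lower", "upper"), names(out))) {
    out[[col]] <- out[[col]] * r
  }
  if (!is.null(draws)) {
    draws <- lapply(draws, function(m) m * factors)
  }
  list(trends = out, factors = tibble::tibble(year = years, factor = factors),
       draws = draws)
}
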