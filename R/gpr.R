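# Stage 2: Gaussian process regression of each state's logit-scale residual
# trend around the stage-1 prior mean, with a Matern covariance in time.
# Conditioning is exact (dense) on the annual grid; uncertainty is carried
# forward as 1,000 posterior draws per state, and every downstream summary is
# computed from ordered draws.

#' Gaussian process configuration
#'
#' @param nu Matern smoothness, one of 1/2, 3/2 (default), 5/2. 3/2 gives
#'   once-differentiable sample trends, a sensible default for annual health
#'   series.
#' @param length_scale correlation length in years (default 5).
#' @param amplitude prior SD on the logit scale. The pipeline default sets it
#'   per indicator to 1.4826 x the median absolute stage-1 residual (a robust
#'   residual-scale estimate, see [gp_amplitude()]).
#' @param n_draws number of posterior draws (default 1000; the canonical
#'   interval rule uses the 25th and 975th ordered draws).
#' @param seed integer seed for the draws.
#' @return an object of class `gp_config`.
#' @export
gp_config <- function(nu = 3 / 2, length_scale = 5, amplitude = 1,
                      n_draws = 1000, seed = NULL) {
  if (!nu %in% c(1 / 2, 3 / 2, 5 / 2)) {
    stop("`nu` must be one of 1/2, 3/2, 5/2")
  }
  if (length_scale <= 0) stop("`length_scale` must be positive")
  if (amplitude < 0) stop("`amplitude` must be non-negative")
  if (n_draws < 2) stop("`n_draws` must be at least 2")
  structure(list(nu = nu, length_scale = length_scale,
                 amplitude = amplitude, n_draws = as.integer(n_draws),
                 seed = seed),
            class = "gp_config")
}

#' Robust amplitude from stage-1 residuals
#'
#' The scaled median absolute deviation `1.4826 * median(|r|)` of the prior
#' model's residuals, a robust estimate of how far the data stray from the
#' prior mean on the logit scale.
#'
#' @param residuals numeric vector of stage-1 residuals.
#' @return non-negative scalar.
#' @export
gp_amplitude <- function(residuals) {
  1.4826 * median(abs(residuals))
}

#' Matern covariance between time points
#'
#' For distance `d = |t1 - t2|`, length-scale `l` and amplitude `sigma`:
#' nu = 1/2: `sigma^2 exp(-d/l)`;
#' nu = 3/2: `sigma^2 (1 + sqrt(3) d/l) exp(-sqrt(3) d/l)`;
#' nu = 5/2: `sigma^2 (1 + sqrt(5) d/l + 5 d^2/(3 l^2)) exp(-sqrt(5) d/l)`.
#'
#' @param t1,t2 numeric vectors of time points; the full cross-covariance
#'   matrix `length(t1) x length(t2)` is returned.
#' @param config a `gp_config`.
#' @return covariance matrix.
#' @export
matern_cov <- function(t1, t2, config) {
  stopifnot(inherits(config, "gp_config"))
  d <- abs(outer(t1, t2, "-")) / config$length_scale
  s2 <- config$amplitude^2
  k <- switch(as.character(config$nu),
    "0.5" = exp(-d),
    "1.5" = (1 + sqrt(3) * d) * exp(-sqrt(3) * d),
    "2.5" = (1 + sqrt(5) * d + 5 * d^2 / 3) * exp(-sqrt(5) * d),
    stop("unsupported nu")
  )
  s2 * k
}

# Cholesky with escalating diagonal jitter, declared so results are
# bit-reproducible: start at 1e-10 * scale, escalate x10 up to 1e-6 * scale.
chol_jitter <- function(mat, scale = max(diag(mat), 1)) {
  for (jit in c(0, scale * 10^seq(-10, -6))) {
    ch <- tryCatch(chol(mat + diag(jit, nrow(mat))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("covariance matrix not positive definite after maximum jitter")
}

#' Condition the Gaussian process on observed state-year estimates
#'
#' Standard Gaussian conditioning of the zero-mean residual process
#' `y - prior_mean` on the observations, each carrying its own independent
#' Gaussian noise variance (the delta-method logit sampling variance):
#' posterior mean `= m + K*' (K + diag(var_y))^{-1} (y - m_obs)`.
#'
#' @param years the estimation grid.
#' @param prior_mean stage-1 mean function on `years`.
#' @param obs tibble with columns `year`, `y`, `var_y`; observation years
#'   must lie within the grid range (prior mean is interpolated linearly at
#'   off-grid years).
#' @param config a `gp_config`.
#' @return list with `years`, `mean` (posterior mean) and `cov` (posterior
#'   covariance, symmetric PSD).
#' @export
gp_condition <- function(years, prior_mean, obs, config) {
  stopifnot(length(years) == length(prior_mean))
  K <- matern_cov(years, years, config)
  if (is.null(obs) || nrow(obs) == 0) {
    return(list(years = years, mean = prior_mean, cov = K))
  }
  if (any(obs$var_y <= 0)) stop("observation variances must be positive")
  if (any(obs$year < min(years) | obs$year > max(years))) {
    stop("observation years must lie within the grid")
  }
  m_obs <- stats::approx(years, prior_mean, xout = obs$year)$y
  Koo <- matern_cov(obs$year, obs$year, config) + diag(obs$var_y,
                                                       nrow(obs))
  Kgo <- matern_cov(years, obs$year, config)
  ch <- tryCatch(
    chol_jitter(Koo, scale = max(config$amplitude^2, 1e-12)),
    error = function(e) stop("GP conditioning system is singular: ",
                             conditionMessage(e), call. = FALSE))
  Koo_inv_resid <- backsolve(ch, forwardsolve(t(ch), obs$y - m_obs))
  Koo_inv_Kog <- backsolve(ch, forwardsolve(t(ch), t(Kgo)))
  post_mean <- prior_mean + drop(Kgo %*% Koo_inv_resid)
  post_cov <- K - Kgo %*% Koo_inv_Kog
  post_cov <- (post_cov + t(post_cov)) / 2
  list(years = years, mean = post_mean, cov = post_cov)
}

#' Draw from the Gaussian process posterior
#'
#' @param mean posterior mean vector.
#' @param cov posterior covariance matrix (PSD; jitter-stabilized).
#' @param n_draws number of draws.
#' @param seed integer seed; identical seeds give identical draw matrices.
#' @return matrix of dimension `length(mean) x n_draws` (logit scale).
#' @export
draw_posterior <- function(mean, cov, n_draws = 1000, seed = NULL) {
  p <- length(mean)
  draw <- function() {
    if (max(abs(cov)) < 1e-14) {
      matrix(mean, nrow = p, ncol = n_draws)
    } else {
      L <- chol_jitter(cov)
      mean + t(L) %*% matrix(rnorm(p * n_draws), nrow = p)
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Posterior draws for one state
#'
#' Container tying a state's draw matrix to its year grid.
#'
#' @param state state name.
#' @param years year grid.
#' @param draws `length(years) x n_draws` matrix on the logit scale.
#' @return an object of class `posterior_draws`.
#' @export
posterior_draws <- function(state, years, draws) {
  stopifnot(nrow(draws) == length(years), all(is.finite(draws)))
  structure(list(state = state, years = years, draws = draws),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws>", x$state, ":", length(x$years), "years x",
      ncol(x$draws), "draws\n")
  invisible(x)
}

#' Summarize posterior draws into median trends and intervals
#'
#' With the canonical rule (requires exactly 1,000 draws) the per-year bounds
#' are the 25th and 975th ordered draws and the median the mean of the 500th
#' and 501st; otherwise empirical quantiles at 0.025/0.5/0.975 are used. All
#' summaries are back-transformed to the proportion scale.
#'
#' @param pd a `posterior_draws`.
#' @param rule `"canonical"` (ordered-draw rule, 1,000 draws) or
#'   `"quantile"`.
#' @return tibble with `state`, `year`, `median`, `lower`, `upper` in (0,1).
#' @export
summarize_draws <- function(pd, rule = c("canonical", "quantile")) {
  rule <- match.arg(rule)
  stopifnot(inherits(pd, "posterior_draws"))
  n <- ncol(pd$draws)
  if (rule == "canonical" && n != 1000L) {
    stop("the canonical ordered-draw rule requires exactly 1000 draws; got ",
         n)
  }
  summ <- apply(pd$draws, 1, function(v) {
    s <- sort(v)
    if (rule == "canonical") {
      c(med = (s[500] + s[501]) / 2, lo = s[25], hi = s[975])
    } else {
      q <- quantile(s, c(0.5, 0.025, 0.975), names = FALSE)
      c(med = q[1], lo = q[2], hi = q[3])
    }
  })
  tibble::tibble(
    state = pd$state, year = pd$years,
    median = plogis(unname(summ["med", ])),
    lower = plogis(unname(summ["lo", ])),
    upper = plogis(unname(summ["hi", ]))
  )
}

#' Smooth one state's estimates through the full stage-2 pipeline
#'
#' Conditions the GP on the state's logit-scale observations around the
#' stage-1 mean and returns posterior draws.
#'
#' @param fit a `prior_fit`.
#' @param state state name.
#' @param obs tibble with `year`, `y`, `var_y` for that state.
#' @param years the estimation grid (default 2000:2013).
#' @param config a `gp_config`.
#' @return a `posterior_draws`.
#' @export
gp_smooth_state <- function(fit, state, obs, years = 2000:2013, config) {
  prior_mean <- predict_prior(fit, state, years, allow_new = TRUE)
  cond <- gp_condition(years, prior_mean, obs, config)
  draws <- draw_posterior(cond$mean, cond$cov, n_draws = config$n_draws,
                          seed = config$seed)
  posterior_draws(state, years, draws)
}
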