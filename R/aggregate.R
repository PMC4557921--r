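# National aggregation at the draw level, the 11-indicator composite
# coverage index, and the benchmarking arithmetic used in reporting
# (extremal ranges, continuum-of-care gaps, relative declines).

#' Population-weight state draws into a national series
#'
#' Per year and draw index, the national value is the population-weighted
#' mean of the state values computed on the proportion scale (weighted means
#' of proportions are the estimand; averaging logits would bias), then
#' re-logit-transformed for storage so the national series composes with
#' every draw-based summary.
#'
#' @param state_draws named list of `posterior_draws`, one per state, sharing
#'   the year grid and draw count.
#' @param pops tibble with columns `state`, `year`, `value` (population or
#'   live births; positive). Must cover every (state, year) on the grid.
#' @return a `posterior_draws` with `state = "national"`.
#' @export
national_aggregate <- function(state_draws, pops) {
  stopifnot(length(state_draws) >= 1)
  states <- vapply(state_draws, function(d) d$state, character(1))
  years <- state_draws[[1]]$years
  n_draws <- ncol(state_draws[[1]]$draws)
  for (d in state_draws) {
    if (!identical(d$years, years) || ncol(d$draws) != n_draws) {
      stop("all states must share the same year grid and draw count")
    }
  }
  missing_pop <- setdiff(states, unique(pops$state))
  if (length(missing_pop)) {
    stop("population table missing state(s): ",
         paste(missing_pop, collapse = ", "))
  }
  if (any(pops$value <= 0)) stop("population values must be positive")

  nat_p <- matrix(0, nrow = length(years), ncol = n_draws)
  for (t in seq_along(years)) {
    w <- vapply(states, function(s) {
      v <- pops$value[pops$state == s & pops$year == years[t]]
      if (length(v) != 1L) {
        stop("population table missing ", s, " in ", years[t])
      }
      v
    }, numeric(1))
    w <- w / sum(w)
    for (i in seq_along(states)) {
      nat_p[t, ] <- nat_p[t, ] + w[i] * plogis(state_draws[[i]]$draws[t, ])
    }
  }
  posterior_draws("national", years, qlogis(nat_p))
}

#' Composite coverage specification
#'
#' The 11 composite members from the registry with their transforms (wasting
#' enters as its complement, "not wasted"); all members equally weighted.
#'
#' @param registry registry tibble (default [indicator_registry()]).
#' @return tibble with columns `id`, `transform` (11 rows).
#' @export
composite_spec <- function(registry = indicator_registry()) {
  members <- registry[registry$composite_member, c("id", "composite_transform")]
  names(members) <- c("id", "transform")
  if (nrow(members) != 11L) stop("composite requires exactly 11 members")
  members
}

#' Equally-weighted composite intervention coverage
#'
#' The mean of the 11 member coverages after per-member transforms. Inputs
#' may be scalars, vectors, or draw matrices of identical shape; applied per
#' draw, the composite carries forward the members' uncertainty.
#'
#' @param indicator_values named list mapping member id to its value(s) on
#'   the proportion scale, in \[0,1\].
#' @param spec composite spec tibble (default [composite_spec()]).
#' @return the composite value(s), same shape as the inputs.
#' @export
composite_coverage <- function(indicator_values, spec = composite_spec()) {
  missing_m <- setdiff(spec$id, names(indicator_values))
  if (length(missing_m)) {
    stop("missing composite member(s): ", paste(missing_m, collapse = ", "))
  }
  acc <- NULL
  for (k in seq_len(nrow(spec))) {
    v <- indicator_values[[spec$id[k]]]
    if (any(v < 0 | v > 1)) {
      stop("composite member '", spec$id[k], "' outside [0, 1]")
    }
    if (spec$transform[k] == "complement") v <- 1 - v
    acc <- if (is.null(acc)) v else acc + v
  }
  acc / nrow(spec)
}

#' Extremal range across units
#'
#' @param values named numeric vector (unit -> value on the reported scale,
#'   e.g. percent coverage or deaths per 1,000 live births).
#' @return list with `max_unit`, `min_unit`, `difference` (max - min).
#' @export
range_gap <- function(values) {
  if (length(values) < 2) stop("need at least two units")
  list(
    max_unit = names(values)[which.max(values)],
    min_unit = names(values)[which.min(values)],
    difference = max(values) - min(values)
  )
}

#' Signed paired difference (e.g. DPT3 minus OPV3, ANC1 minus ANC4)
#'
#' @param value_a,value_b two values on the same scale.
#' @return `value_a - value_b`.
#' @export
paired_gap <- function(value_a, value_b) {
  value_a - value_b
}

#' Relative decline between two time points, in percent
#'
#' `100 (v_start - v_end) / v_start`; round to the nearest integer when
#' mirroring headline text.
#'
#' @param v_start,v_end start and end values; `v_start` must be positive.
#' @return percent decline (positive when the value fell).
#' @export
relative_decline <- function(v_start, v_end) {
  if (any(v_start <= 0)) stop("`v_start` must be positive")
  100 * (v_start - v_end) / v_start
}
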