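# Cross-survey harmonization: card-only immunization crosswalk and
# near-zero pre-policy pseudo-observations for malaria interventions.

#' Estimate the card-only to total immunization crosswalk ratio
#'
#' Some surveys ascertain vaccination only from child health cards, missing
#' children whose cards were lost. Sources that record both card-based and
#' card-or-recall coverage give paired estimates from which the average
#' relationship is computed: the unweighted mean of per-survey
#' `total / card_only` ratios, pooled over states.
#'
#' @param paired_estimates tibble (or data.frame) with columns `card_only_p`
#'   and `total_p`, one row per paired survey estimate.
#' @return the pooled ratio (a scalar, usually >= 1).
#' @export
estimate_crosswalk_ratio <- function(paired_estimates) {
  if (is.null(paired_estimates) || nrow(paired_estimates) == 0) {
    stop("at least one paired estimate is required")
  }
  co <- paired_estimates$card_only_p
  tot <- paired_estimates$total_p
  if (any(co <= 0 | co >= 1)) {
    stop("card-only proportions must lie strictly inside (0, 1)")
  }
  if (any(tot <= 0 | tot >= 1)) {
    stop("total proportions must lie strictly inside (0, 1)")
  }
  mean(tot / co)
}

#' Adjust a card-only immunization estimate to the card-or-recall scale
#'
#' Multiplies the proportion by the crosswalk ratio (capped at 0.999), scales
#' the sampling variance by `ratio^2`, and flags the estimate
#' `card_only_adjusted`.
#'
#' @param estimate one-or-more-row estimates tibble of card-only estimates.
#' @param ratio crosswalk ratio from [estimate_crosswalk_ratio()].
#' @return the adjusted estimates.
#' @export
card_crosswalk <- function(estimate, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) {
    stop("`ratio` must be a positive scalar")
  }
  estimate$p <- pmin(ratio * estimate$p, 0.999)
  estimate$var_p <- estimate$var_p * ratio^2
  estimate$flags <- add_flag(estimate$flags, "card_only_adjusted")
  estimate
}

#' Pre-policy near-zero pseudo-observations for malaria interventions
#'
#' Malaria interventions did not exist before their formal adoption in
#' national policy, so years before the adoption year receive coverage
#' pseudo-observations of 0.01% (p = 1e-4). Their variance is fixed at 1e-8:
#' pre-policy coverage is treated as known-near-zero, and a tiny variance pins
#' the Gaussian process there without a numerically singular noise term.
#' A per-state `policy_table` (columns `state`, `policy_start_year`) overrides
#' the registry's national year, for phased roll-outs such as IRS.
#'
#' @param indicator one-row registry entry with a `policy_start_year`.
#' @param states character vector of states to impute for.
#' @param year_grid integer years of the estimation grid.
#' @param policy_table optional per-state adoption years.
#' @return estimates tibble of pseudo-observations flagged
#'   `imputed_pre_policy` (possibly empty).
#' @export
impute_pre_policy <- function(indicator, states, year_grid,
                              policy_table = NULL) {
  national_year <- indicator$policy_start_year
  if (is.na(national_year) && is.null(policy_table)) {
    stop("indicator '", indicator$id, "' has no policy start year")
  }
  zmap <- state_zone_map()
  rows <- lapply(states, function(s) {
    start <- national_year
    if (!is.null(policy_table) && s %in% policy_table$state) {
      start <- policy_table$policy_start_year[policy_table$state == s][1]
    }
    if (is.na(start)) stop("no policy start year for state ", s)
    years <- year_grid[year_grid < start]
    if (length(years) == 0) return(NULL)
    tibble::tibble(
      indicator = indicator$id, state = s,
      zone = unname(zmap[s]), year = as.integer(years),
      p = 1e-4, var_p = 1e-8,
      source_id = "pre_policy_imputation",
      flags = "imputed_pre_policy"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_estimates() else out
}
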