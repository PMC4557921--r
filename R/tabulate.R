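# Design-weighted tabulation of survey microdata into state-year estimates,
# plus the record-level harmonization steps that run before tabulation
# (event-year attribution, recall-window filtering) and the post-tabulation
# exclusion flags.

# flags are stored as a comma-separated string so estimates stay a plain,
# writeable rectangular table
add_flag <- function(flags, flag) {
  ifelse(flags == "" | is.na(flags), flag, paste(flags, flag, sep = ","))
}

#' Test whether estimates carry a given flag
#'
#' @param flags character vector of comma-separated flag strings.
#' @param flag single flag name.
#' @return logical vector.
#' @export
has_flag <- function(flags, flag) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ",", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Tabulate microdata into design-weighted state-year estimates
#'
#' Collapses one survey's respondent-level records to one estimate per
#' (state, event year): `p` is the weighted mean of the binary outcome and
#' `var_p` the design-weighted ratio-estimator variance
#' `sum(w^2 (o - p)^2) / (sum w)^2`. The microdata carry sampling weights but
#' not full stratum/PSU structure, so this is the variance estimator used
#' throughout. Proportions are clamped into \[0.001, 0.999\] before storage;
#' degenerate all-0/all-1 cells fall back to the binomial variance at the
#' clamped proportion with the Kish effective sample size.
#'
#' @param records tibble with columns `survey_id`, `state`, `zone`, `weight`,
#'   `outcome` (0/1), `event_year`.
#' @param indicator one-row registry entry (see [indicator_definition()]).
#' @return a tibble of estimates: `indicator`, `state`, `zone`, `year`, `p`,
#'   `var_p`, `source_id`, `flags`.
#' @export
weighted_tabulate <- function(records, indicator) {
  if (nrow(records) == 0) {
    return(empty_estimates())
  }
  if (length(unique(records$survey_id)) != 1L) {
    stop("`records` must come from a single survey")
  }
  if (any(!records$outcome %in% c(0, 1))) stop("outcomes must be 0/1")
  if (any(is.na(records$weight)) || all(records$weight == 0)) {
    stop("malformed sampling weights")
  }
  if (any(records$weight <= 0)) stop("sampling weights must be positive")

  records |>
    dplyr::group_by(.data$state, .data$zone, year = .data$event_year) |>
    dplyr::summarise(
      p_raw = sum(.data$weight * .data$outcome) / sum(.data$weight),
      n_eff = sum(.data$weight)^2 / sum(.data$weight^2),
      var_raw = sum(.data$weight^2 * (.data$outcome - .data$p_raw)^2) /
        sum(.data$weight)^2,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      indicator = indicator$id,
      p = clamp_proportion(.data$p_raw),
      var_p = ifelse(.data$var_raw > 0, .data$var_raw,
                     .data$p * (1 - .data$p) / .data$n_eff),
      source_id = unique(records$survey_id),
      flags = ""
    ) |>
    dplyr::select("indicator", "state", "zone", "year", "p", "var_p",
                  "source_id", "flags")
}

empty_estimates <- function() {
  tibble::tibble(
    indicator = character(), state = character(), zone = character(),
    year = integer(), p = numeric(), var_p = numeric(),
    source_id = character(), flags = character()
  )
}

#' Attribute each record's event year by indicator convention
#'
#' Coverage of the antenatal/delivery indicators (ANC1, ANC4, SBA, IFD) is
#' attributed to the child's birth year; all other indicators use the survey
#' year. Birth-year records with a missing birth year are dropped and the
#' drop count attached as attribute `n_dropped` (and reported via `message`).
#'
#' @param records tibble with `survey_year` and (for birth-year indicators)
#'   `birth_year` columns.
#' @param indicator one-row registry entry.
#' @return `records` with an `event_year` column set.
#' @export
attribute_event_year <- function(records, indicator) {
  if (identical(indicator$attribution, "birth-year")) {
    missing_by <- is.na(records$birth_year)
    n_dropped <- sum(missing_by)
    if (n_dropped > 0) {
      message(sprintf("dropped %d record(s) with missing birth year for %s",
                      n_dropped, indicator$id))
    }
    out <- records[!missing_by, , drop = FALSE]
    out$event_year <- out$birth_year
  } else {
    n_dropped <- 0L
    out <- records
    out$event_year <- out$survey_year
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Restrict birth-year records to each source family's recall window
#'
#' Full-birth-history sources (DHS-like) report births up to six years before
#' the survey; most-recent-birth sources (MICS-like) are representative only
#' within two years of the survey date.
#'
#' @param records tibble with `survey_year` and `birth_year`.
#' @param source_family `"full-history"` (6-year window) or
#'   `"recent-birth-only"` (2-year window).
#' @return the filtered records.
#' @export
window_filter <- function(records,
                          source_family = c("full-history",
                                            "recent-birth-only")) {
  source_family <- match.arg(source_family)
  window <- if (source_family == "full-history") 6L else 2L
  lag <- records$survey_year - records$birth_year
  records[!is.na(lag) & lag >= 0 & lag <= window, , drop = FALSE]
}

#' Flag estimates listed in an exclusion table
#'
#' Exclusions are judgement-based (documented sampling problems,
#' implausibility relative to nearby points) and therefore configuration
#' driven: an explicit (indicator, state, source) table, never auto-detected.
#' Flagged estimates are retained in the table but never enter model fitting.
#'
#' @param estimates estimates tibble (from [weighted_tabulate()]).
#' @param exclusion_list tibble with columns `indicator`, `state`,
#'   `source_id`.
#' @return `estimates` with matching rows flagged `excluded`.
#' @export
flag_exclusions <- function(estimates, exclusion_list) {
  if (is.null(exclusion_list) || nrow(exclusion_list) == 0) {
    return(estimates)
  }
  key <- function(d) paste(d$indicator, d$state, d$source_id, sep = "\r")
  hit <- key(estimates) %in% key(exclusion_list)
  estimates$flags[hit] <- add_flag(estimates$flags[hit], "excluded")
  message(sprintf("flagged %d of %d estimates (%.1f%%) as excluded",
                  sum(hit), nrow(estimates),
                  100 * sum(hit) / max(1, nrow(estimates))))
  estimates
}

#' Drop flagged-excluded estimates before model fitting
#'
#' @param estimates estimates tibble.
#' @return estimates without `excluded` rows.
#' @export
drop_excluded <- function(estimates) {
  estimates[!has_flag(estimates$flags, "excluded"), , drop = FALSE]
}
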