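# Indicator registry: the 20 maternal and child health outcomes and
# interventions tracked by the pipeline, with the metadata the harmonization
# rules consume (denominator, event-year attribution, pre-policy adoption
# years for malaria interventions, composite-index membership).

#' Indicator registry
#'
#' One row per indicator. `attribution` controls whether tabulated estimates
#' are attributed to the survey year or to the child's birth year (the latter
#' for the antenatal/delivery indicators ANC1, ANC4, SBA, IFD).
#' `policy_start_year` is set only for the malaria interventions with a
#' documented national adoption year; years before it receive near-zero
#' pseudo-observations (see [impute_pre_policy()]). Exactly 11 indicators are
#' members of the composite coverage index; wasting enters the composite as
#' its complement ("not wasted").
#'
#' @return a tibble with columns `id`, `label`, `denominator`, `attribution`,
#'   `policy_start_year`, `composite_member`, `composite_transform`.
#' @export
indicator_registry <- function() {
  reg <- tibble::tribble(
    ~id,          ~label,                                         ~denominator,      ~attribution,  ~policy_start_year, ~composite_member, ~composite_transform,
    "u5m",        "Under-5 mortality",                            "births",          "survey-year", NA_integer_,        FALSE, "identity",
    "underweight","Children under 5 underweight",                 "children-u5",     "survey-year", NA_integer_,        FALSE, "identity",
    "wasting",    "Children under 5 wasted",                      "children-u5",     "survey-year", NA_integer_,        TRUE,  "complement",
    "stunting",   "Children under 5 stunted",                     "children-u5",     "survey-year", NA_integer_,        FALSE, "identity",
    "itn_own",    "Household ITN ownership",                      "households",      "survey-year", 2000L,              FALSE, "identity",
    "itn_use",    "ITN use by children under 5",                  "children-u5",     "survey-year", NA_integer_,        FALSE, "identity",
    "itn_irs",    "Household ITN ownership or IRS",               "households",      "survey-year", 2000L,              TRUE,  "identity",
    "iptp2",      "IPTp, two doses, during pregnancy",            "women-15-49",     "survey-year", 2001L,              TRUE,  "identity",
    "act",        "ACT treatment of febrile children under 5",    "children-u5",     "survey-year", 2004L,              TRUE,  "identity",
    "bcg",        "BCG immunization",                             "children-u5",     "survey-year", NA_integer_,        TRUE,  "identity",
    "measles",    "Measles immunization",                         "children-12-59m", "survey-year", NA_integer_,        TRUE,  "identity",
    "dpt3",       "DPT immunization, three doses",                "children-12-59m", "survey-year", NA_integer_,        TRUE,  "identity",
    "opv3",       "Oral polio vaccine, three doses",              "children-12-59m", "survey-year", NA_integer_,        TRUE,  "identity",
    "anc1",       "Antenatal care, one or more visits",           "women-15-49",     "birth-year",  NA_integer_,        FALSE, "identity",
    "anc4",       "Antenatal care, four or more visits",          "women-15-49",     "birth-year",  NA_integer_,        TRUE,  "identity",
    "sba",        "Skilled birth attendance",                     "women-15-49",     "birth-year",  NA_integer_,        TRUE,  "identity",
    "ifd",        "In-facility delivery",                         "women-15-49",     "birth-year",  NA_integer_,        FALSE, "identity",
    "ebf",        "Exclusive breastfeeding",                      "children-u5",     "survey-year", NA_integer_,        TRUE,  "identity",
    "mod_contra", "Modern contraceptive use",                     "women-15-49",     "survey-year", NA_integer_,        FALSE, "identity",
    "tt2",        "Tetanus toxoid, two or more doses",            "women-15-49",     "survey-year", NA_integer_,        FALSE, "identity"
  )
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$id)) stop("indicator ids must be unique")
  if (sum(reg$composite_member) != 11L) {
    stop("exactly 11 indicators must be composite members, found ",
         sum(reg$composite_member))
  }
  bad <- reg$composite_transform[!reg$composite_transform %in%
                                   c("identity", "complement")]
  if (length(bad)) stop("unknown composite_transform: ", bad[1])
  invisible(reg)
}

#' Look up one indicator definition
#'
#' @param id indicator id, e.g. `"dpt3"`.
#' @param registry a registry tibble, by default [indicator_registry()].
#' @return the matching one-row tibble.
#' @export
indicator_definition <- function(id, registry = indicator_registry()) {
  row <- registry[registry$id == id, ]
  if (nrow(row) != 1L) stop("unknown indicator id: ", id)
  row
}

#' Read an indicator registry from a YAML or JSON configuration file
#'
#' The file must contain a list of records with the registry's fields; missing
#' `policy_start_year` entries become `NA`.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a validated registry tibble.
#' @export
read_registry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML registries requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading JSON registries requires the 'jsonlite' package")
    }
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported registry format: .", ext)
  }
  reg <- dplyr::bind_rows(lapply(raw, function(rec) {
    tibble::tibble(
      id = rec$id,
      label = rec$label %||% rec$id,
      denominator = rec$denominator,
      attribution = rec$attribution %||% "survey-year",
      policy_start_year = as.integer(rec$policy_start_year %||% NA),
      composite_member = isTRUE(rec$composite_member),
      composite_transform = rec$composite_transform %||% "identity"
    )
  }))
  validate_registry(reg)
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
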