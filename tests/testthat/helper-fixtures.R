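# Shared fixtures: tiny microdata tables and logit-scale datasets built in
# code, so every test input is generated at run time.

make_microdata <- function(outcomes, weights = rep(1, length(outcomes)),
                           state = "Lagos", zone = "South West",
                           event_year = 2010, survey_id = "svy1") {
  tibble::tibble(
    survey_id = survey_id, state = state, zone = zone,
    weight = weights, outcome = outcomes, event_year = event_year
  )
}

# logit-scale observations on a clean line for a handful of states
make_line_data <- function(states = c("Lagos", "Kano"),
                           zones = c("South West", "North West"),
                           years = 2000:2013, alpha = 2, beta = 0.1,
                           noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_along(states), function(i) {
      tibble::tibble(
        state = states[i], zone = zones[i], year = years,
        y = alpha + beta * (years - mean(range(years))) +
          rnorm(length(years), 0, noise_sd),
        var_y = 0.05
      )
    }))
  })
}

sba_def <- function() indicator_definition("sba")
itn_def <- function() indicator_definition("itn_own")
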