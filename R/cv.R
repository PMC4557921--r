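# Model selection for the stage-1 prior: predictive validity of each
# candidate specification under a 20% random hold-out repeated 100 times,
# scored by RMSE of logit-scale predictions on the held-out observations.

rmse <- function(residuals) sqrt(mean(residuals^2))

#' Select a prior specification by repeated random hold-out
#'
#' For each replicate, a random 20% of the state-year observations are held
#' out; every candidate specification is fitted on the remainder and scored
#' by the RMSE of its logit-scale predictions on the held-out set (held-out
#' states unseen in a training split predict from the fixed effects). The
#' specification with the lowest mean RMSE across replicates wins; replicates
#' in which a specification fails to converge are excluded from its mean,
#' with counts reported. Ties are broken deterministically: fewest random
#' terms first, then the linear basis before the spline.
#'
#' @param data tibble with columns `state`, `zone`, `year`, `y`.
#' @param specs list of `prior_spec`s (default: all 14).
#' @param holdout_frac fraction held out per replicate (default 0.20).
#' @param reps number of hold-out replicates (default 100).
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @return an object of class `cv_result`: per-spec table (`id`, `mean_rmse`,
#'   `n_converged`, `selected`), the replicate-level RMSE matrix, and the
#'   selected `prior_spec`.
#' @export
cv_select <- function(data, specs = enumerate_specs(), holdout_frac = 0.20,
                      reps = 100, seed = 1) {
  n <- nrow(data)
  n_test <- max(1L, round(holdout_frac * n))
  if (n - n_test < 3) stop("too few observations for hold-out validation")
  ref_years <- sort(unique(data$year))
  ids <- vapply(specs, function(s) s$id, character(1))

  rmse_mat <- withr::with_seed(seed, {
    m <- matrix(NA_real_, nrow = reps, ncol = length(specs),
                dimnames = list(NULL, ids))
    for (r in seq_len(reps)) {
      test_idx <- sample.int(n, n_test)
      train <- data[-test_idx, , drop = FALSE]
      test <- data[test_idx, , drop = FALSE]
      for (j in seq_along(specs)) {
        fit <- tryCatch(
          suppressWarnings(suppressMessages(
            fit_prior(train, specs[[j]], ref_years = ref_years))),
          error = function(e) NULL)
        if (is.null(fit)) next
        pred <- tryCatch(
          predict_prior_rows(fit, test$state, test$zone, test$year,
                             allow_new = TRUE),
          error = function(e) NULL)
        if (is.null(pred)) next
        m[r, j] <- rmse(test$y - pred)
      }
    }
    m
  })

  n_conv <- colSums(!is.na(rmse_mat))
  if (all(n_conv == 0)) stop("every specification failed in every replicate")
  mean_rmse <- colMeans(rmse_mat, na.rm = TRUE)
  mean_rmse[n_conv == 0] <- Inf
  n_re <- vapply(specs, function(s) length(s$re), integer(1))
  is_spline <- vapply(specs, function(s) s$basis == "ncs1", logical(1))
  ord <- order(mean_rmse, n_re, is_spline, ids)
  sel <- ord[1]

  table <- tibble::tibble(
    id = ids, basis = vapply(specs, function(s) s$basis, character(1)),
    n_random_terms = n_re, mean_rmse = unname(mean_rmse),
    n_converged = unname(n_conv),
    selected = seq_along(specs) == sel
  )
  failed <- sum(reps - n_conv)
  if (failed > 0) {
    message(sprintf("cv_select: %d spec-replicate fits failed to converge",
                    failed))
  }
  structure(list(table = table, rmse = rmse_mat, selected = specs[[sel]],
                 holdout_frac = holdout_frac, reps = reps, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$reps, "replicates,",
      sprintf("%.0f%%", 100 * x$holdout_frac), "hold-out\n")
  cat("  selected:", x$selected$id, "\n")
  print(x$table[order(x$table$mean_rmse), c("id", "mean_rmse", "n_converged")],
        n = 5)
  invisible(x)
}
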