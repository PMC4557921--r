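# Stage 1: the mixed-effects prior over logit-scale state-year estimates,
#
#   y_{s,t} = alpha + T (beta + b_s + b_z) + u_s + u_z + eps_{s,t}
#
# where T is time (linear, or the two bases of a natural cubic spline with a
# single interior knot), b_s / b_z are IID random slopes for state and
# geopolitical zone, and u_s / u_z are IID mean-zero random intercepts.
# Candidate specifications vary the basis and which random terms enter;
# slopes are only allowed alongside the matching intercept, which yields a
# lattice of 7 random structures x 2 bases = 14 candidate models.

#' Build the time basis for the prior model
#'
#' `"linear"` gives a single column of centered years (centered at the
#' midpoint of `ref_years`). `"ncs1"` gives the two basis columns of a
#' natural cubic spline with one interior knot at the median of `ref_years`
#' and boundary knots at its range; beyond the boundary knots the spline
#' continues linearly (natural boundary conditions), which keeps grid-edge
#' extrapolation tame.
#'
#' @param years years at which to evaluate the basis.
#' @param basis `"linear"` or `"ncs1"`.
#' @param ref_years years that define centering/knots (defaults to `years`);
#'   pass the observed data years so that prediction grids reuse the fitted
#'   knots.
#' @return a numeric matrix (columns `.t1` or `.t1`, `.t2`) with an `info`
#'   attribute used by [eval_time_basis()].
#' @export
build_time_basis <- function(years, basis = c("linear", "ncs1"),
                             ref_years = years) {
  basis <- match.arg(basis)
  uy <- sort(unique(ref_years))
  if (basis == "linear") {
    if (length(uy) < 2) stop("linear basis needs >= 2 distinct years")
    info <- list(basis = "linear", center = mean(range(uy)))
  } else {
    if (length(uy) < 3) stop("ncs1 basis needs >= 3 distinct years")
    info <- list(basis = "ncs1", knot = median(uy), boundary = range(uy))
  }
  eval_time_basis(years, info)
}

#' Evaluate a previously-defined time basis at new years
#'
#' @param years years to evaluate at.
#' @param info the `info` attribute of a matrix from [build_time_basis()].
#' @return basis matrix with the same columns and `info` attribute.
#' @export
eval_time_basis <- function(years, info) {
  if (info$basis == "linear") {
    mat <- matrix(years - info$center, ncol = 1,
                  dimnames = list(NULL, ".t1"))
  } else {
    mat <- splines::ns(years, knots = info$knot,
                       Boundary.knots = info$boundary)
    mat <- unclass(mat)
    attributes(mat)[c("degree", "knots", "Boundary.knots", "intercept")] <- NULL
    dimnames(mat) <- list(NULL, c(".t1", ".t2"))
  }
  attr(mat, "info") <- info
  mat
}

#' Construct a prior-model specification
#'
#' @param basis `"linear"` or `"ncs1"`.
#' @param re character vector drawn from `u_s`, `u_z`, `b_s`, `b_z`; a random
#'   slope requires the matching random intercept.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(basis = c("linear", "ncs1"), re = character()) {
  basis <- match.arg(basis)
  re <- as.character(re)
  bad <- setdiff(re, c("u_s", "u_z", "b_s", "b_z"))
  if (length(bad)) stop("unknown random terms: ", paste(bad, collapse = ", "))
  if ("b_s" %in% re && !"u_s" %in% re) stop("b_s requires u_s")
  if ("b_z" %in% re && !"u_z" %in% re) stop("b_z requires u_z")
  re <- intersect(c("u_s", "u_z", "b_s", "b_z"), re)  # canonical order
  id <- paste0(basis, "|", if (length(re)) paste(re, collapse = "+") else "fixed")
  structure(list(basis = basis, re = re, id = id), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>", x$id, "\n")
  invisible(x)
}

#' Enumerate the 14 candidate prior specifications
#'
#' Two time bases (linear, one-knot natural cubic spline) crossed with seven
#' random-effect structures (none; state and/or zone intercepts; slopes added
#' only where the matching intercept is present).
#'
#' @return a list of 14 `prior_spec` objects in a stable order.
#' @export
enumerate_specs <- function() {
  res <- list(
    character(0),
    "u_s",
    "u_z",
    c("u_s", "u_z"),
    c("u_s", "b_s"),
    c("u_s", "u_z", "b_s"),
    c("u_s", "u_z", "b_s", "b_z")
  )
  specs <- list()
  for (basis in c("linear", "ncs1")) {
    for (re in res) specs[[length(specs) + 1L]] <- prior_spec(basis, re)
  }
  specs
}

#' Fit one prior specification
#'
#' Mixed specifications are fitted by restricted maximum likelihood with
#' [lme4::lmer()]; the no-random-terms specification reduces to ordinary
#' least squares. Observations are equally weighted at this stage: the
#' sampling variance of each estimate enters only through the Gaussian
#' process likelihood in stage 2. If a requested grouping factor has a single
#' level (e.g. zone terms on single-state data), those terms are fixed at
#' zero with a warning.
#'
#' @param data tibble with columns `state`, `zone`, `year`, `y` (logit scale).
#' @param spec a `prior_spec`.
#' @param ref_years years defining the basis (defaults to the data years).
#' @return an object of class `prior_fit` holding the intercept `alpha`, time
#'   coefficients `beta`, random intercepts `u_s`/`u_z`, random slopes
#'   `b_s`/`b_z`, residual SD `sigma_eps`, variance components, and the
#'   underlying model object.
#' @export
fit_prior <- function(data, spec, ref_years = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  if (nrow(data) == 0) stop("no data to fit")
  if (is.null(ref_years)) ref_years <- sort(unique(data$year))

  B <- build_time_basis(data$year, spec$basis, ref_years = ref_years)
  info <- attr(B, "info")
  bnames <- colnames(B)
  df <- data.frame(y = data$y, B,
                   state = factor(data$state), zone = factor(data$zone))

  re <- spec$re
  if (any(c("u_z", "b_z") %in% re) && nlevels(df$zone) < 2) {
    warning("single zone in data: zone terms fixed at 0")
    re <- setdiff(re, c("u_z", "b_z"))
  }
  if (any(c("u_s", "b_s") %in% re) && nlevels(df$state) < 2) {
    warning("single state in data: state terms fixed at 0")
    re <- setdiff(re, c("u_s", "b_s"))
  }

  fixed <- paste("y ~ 1 +", paste(bnames, collapse = " + "))
  re_terms <- c(
    if ("u_s" %in% re) "(1 | state)",
    if ("b_s" %in% re) sprintf("(0 + %s | state)", bnames),
    if ("u_z" %in% re) "(1 | zone)",
    if ("b_z" %in% re) sprintf("(0 + %s | zone)", bnames)
  )

  if (length(re_terms) == 0) {
    model <- lm(as.formula(fixed), data = df)
    fe <- coef(model)
    sigma_eps <- sigma(model)
    re_df <- list()
    varcomp <- c(sigma_eps = sigma_eps^2)
  } else {
    fml <- as.formula(paste(c(fixed, re_terms), collapse = " + "))
    model <- tryCatch(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore")),
      error = function(e) {
        stop("prior fit failed for spec ", spec$id, ": ",
             conditionMessage(e), call. = FALSE)
      })
    fe <- lme4::fixef(model)
    sigma_eps <- sigma(model)
    re_df <- lme4::ranef(model, condVar = FALSE)
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- setNames(vc$vcov,
                        paste(vc$grp, ifelse(is.na(vc$var1), "", vc$var1),
                              sep = ":"))
  }

  pull_re <- function(group, col) {
    d <- re_df[[group]]
    if (is.null(d) || !col %in% colnames(d)) return(NULL)
    setNames(d[[col]], rownames(d))
  }
  re_mat <- function(group) {
    lv <- levels(df[[group]])
    m <- matrix(0, nrow = length(lv), ncol = length(bnames),
                dimnames = list(lv, bnames))
    for (bn in bnames) {
      v <- pull_re(group, bn)
      if (!is.null(v)) m[names(v), bn] <- v
    }
    m
  }

  structure(list(
    spec = spec,
    alpha = unname(fe["(Intercept)"]),
    beta = fe[bnames],
    u_s = pull_re("state", "(Intercept)") %||%
      setNames(rep(0, nlevels(df$state)), levels(df$state)),
    u_z = pull_re("zone", "(Intercept)") %||%
      setNames(rep(0, nlevels(df$zone)), levels(df$zone)),
    b_s = re_mat("state"),
    b_z = re_mat("zone"),
    sigma_eps = sigma_eps,
    varcomp = varcomp,
    basis_info = info,
    state_zone = setNames(as.character(data$zone),
                          as.character(data$state))[
                            !duplicated(as.character(data$state))],
    model = model,
    fitted_re = re
  ), class = "prior_fit")
}

#' @export
print.prior_fit <- function(x, ...) {
  cat("<prior_fit>", x$spec$id, "\n")
  cat("  alpha:", format(x$alpha, digits = 4),
      " beta:", paste(format(x$beta, digits = 4), collapse = ", "), "\n")
  cat("  sigma_eps:", format(x$sigma_eps, digits = 4), "\n")
  invisible(x)
}

#' Evaluate the prior mean function for one state
#'
#' Assembles `alpha + T(beta + b_s + b_z) + u_s + u_z` from the stored
#' components at the requested years (annual estimation grids extend beyond
#' the observed years; the spline continues linearly there).
#'
#' @param fit a `prior_fit`.
#' @param state a single state name.
#' @param years years to predict at.
#' @param zone zone of the state; defaults to the zone seen during fitting,
#'   required for states unseen at fit time when `allow_new = TRUE`.
#' @param allow_new if `TRUE`, unseen states/zones predict from the fixed
#'   effects (random terms 0) instead of erroring.
#' @return numeric vector of logit-scale means.
#' @export
predict_prior <- function(fit, state, years, zone = NULL, allow_new = FALSE) {
  stopifnot(inherits(fit, "prior_fit"), length(state) == 1L)
  known <- state %in% names(fit$state_zone)
  if (!known && !allow_new) stop("unknown state: ", state)
  if (is.null(zone) && known) zone <- unname(fit$state_zone[state])

  B <- eval_time_basis(years, fit$basis_info)
  slope <- fit$beta
  if (known && state %in% rownames(fit$b_s)) {
    slope <- slope + fit$b_s[state, ]
  }
  if (!is.null(zone) && zone %in% rownames(fit$b_z)) {
    slope <- slope + fit$b_z[zone, ]
  }
  icept <- fit$alpha
  if (known && state %in% names(fit$u_s)) icept <- icept + fit$u_s[state]
  if (!is.null(zone) && zone %in% names(fit$u_z)) {
    icept <- icept + fit$u_z[zone]
  }
  drop(icept + B %*% slope)
}

# vectorized row-wise prediction for (state, zone, year) triples; used by CV
predict_prior_rows <- function(fit, states, zones, years, allow_new = TRUE) {
  out <- numeric(length(states))
  for (key in unique(paste(states, zones, sep = "\r"))) {
    idx <- paste(states, zones, sep = "\r") == key
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    out[idx] <- predict_prior(fit, parts[1], years[idx], zone = parts[2],
                              allow_new = allow_new)
  }
  out
}
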