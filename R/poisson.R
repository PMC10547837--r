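#' Significance codes for p-values
#'
#' The conventional four-threshold coding used in model tables:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `•` p < 0.1,
#' empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @export
signif_code <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ "\u2022",
    TRUE ~ ""
  )
}

#' Fit a log-link Poisson regression
#'
#' Maximum-likelihood fit of \eqn{\log E(Y) = \beta_0 + \beta_1 x_1 + \dots}
#' by iteratively reweighted least squares (convergence when the relative
#' deviance change drops below 1e-8, at most 100 iterations). Reports a
#' deviance pseudo-R-squared, \eqn{R^2_{dev} = 1 - D_{res}/D_{null}}, and
#' its Ezekiel-style adjustment
#' \eqn{R^2_{adj} = 1 - (1 - R^2_{dev})(n - 1)/(n - k - 1)} for `k`
#' predictors.
#'
#' @param data Data frame with the response and predictor columns
#'   (typically a `predictor_table`).
#' @param response Name of the count response column.
#' @param predictors Character vector of predictor columns (may be empty
#'   for the intercept-only model).
#' @return A `poisson_fit` object. Use [generics::tidy()] for the
#'   coefficient table and [generics::glance()] for fit statistics.
#' @examples
#' d <- data.frame(y = c(2L, 4L, 6L))
#' coef(fit_poisson(d, "y"))  # log(mean(y))
#' @export
fit_poisson <- function(data, response, predictors = character()) {
  y <- data[[response]]
  if (is.null(y)) {
    stop("response column `", response, "` not found", call. = FALSE)
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integer counts", call. = FALSE)
  }
  n <- length(y)
  k <- length(predictors)
  if (n <= k + 1L) {
    stop("need n > k + 1 observations to fit ", k, " predictors",
         call. = FALSE)
  }
  x <- cbind(`(Intercept)` = rep(1, n))
  if (k > 0L) {
    x <- cbind(x, as.matrix(as.data.frame(data)[predictors]))
  }
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100L)
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::poisson(), control = ctrl)
  )
  p <- ncol(x)
  # dispersion-1 covariance, as summary.glm computes it for Poisson
  covmat <- tryCatch(
    chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
    error = function(e) matrix(NA_real_, p, p)
  )
  est <- fit$coefficients
  se <- sqrt(diag(covmat))
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  mu <- fit$fitted.values
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  r2_dev <- if (fit$null.deviance > 0) 1 - fit$deviance / fit$null.deviance else 0
  r2_adj <- 1 - (1 - r2_dev) * (n - 1) / (n - k - 1)
  structure(
    list(
      response = response,
      predictors = predictors,
      coefficients = tibble::tibble(
        term = colnames(x),
        estimate = unname(est),
        std.error = unname(se),
        statistic = unname(z),
        p.value = unname(pval),
        signif = signif_code(unname(pval))
      ),
      null.deviance = fit$null.deviance,
      deviance = fit$deviance,
      logLik = ll,
      AIC = -2 * ll + 2 * p,
      BIC = -2 * ll + log(n) * p,
      n = n,
      k = k,
      r2_dev = r2_dev,
      r2_adj = r2_adj,
      converged = fit$converged,
      boundary = fit$boundary ||
        any(!is.finite(est)) || any(abs(est) > 1e6)
    ),
    class = "poisson_fit"
  )
}

#' @export
coef.poisson_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("<poisson_fit> %s ~ %s\n", x$response,
              if (x$k) paste(x$predictors, collapse = " + ") else "1"))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("n = %d, residual deviance = %.2f (null %.2f), R2_adj = %.4f\n",
              x$n, x$deviance, x$null.deviance, x$r2_adj))
  invisible(x)
}

#' Tidy a Poisson fit
#'
#' @param x A `poisson_fit`.
#' @param ... Unused.
#' @return Coefficient tibble: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `signif`.
#' @export
tidy.poisson_fit <- function(x, ...) x$coefficients

#' @rdname tidy.poisson_fit
#' @return For `glance()`: a one-row tibble of fit statistics.
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(
    null.deviance = x$null.deviance, deviance = x$deviance,
    r2_dev = x$r2_dev, r2_adj = x$r2_adj, logLik = x$logLik,
    AIC = x$AIC, BIC = x$BIC, n = x$n, k = x$k, converged = x$converged
  )
}

#' Exhaustive best-subset selection for Poisson regression
#'
#' Fits every subset of the candidate predictors (the empty, intercept-only
#' model included) and returns the fit minimizing the information
#' criterion. Ties are broken toward fewer predictors, then
#' lexicographically on the sorted predictor names. Non-converged or
#' boundary fits are excluded from the ranking.
#'
#' @param data Data frame with response and candidate columns.
#' @param response Count response column name.
#' @param candidates Character vector of candidate predictors (at most 20
#'   unless `max_k` caps the subset size).
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param max_k Optional cap on subset size.
#' @return A `best_subset` object: the selected `poisson_fit` (`$best`),
#'   the full ranking (`$results`), and the criterion name.
#' @export
best_subset <- function(data, response, candidates,
                        criterion = c("BIC", "AIC"), max_k = NULL) {
  criterion <- match.arg(criterion)
  m <- length(candidates)
  if (m > 20L && is.null(max_k)) {
    stop("more than 20 candidates (", m, "): exhaustive enumeration is ",
         "2^", m, " fits; prune further or set `max_k`", call. = FALSE)
  }
  sizes <- 0:(if (is.null(max_k)) m else min(max_k, m))
  subsets <- unlist(
    lapply(sizes, function(k) utils::combn(candidates, k, simplify = FALSE)),
    recursive = FALSE
  )
  y <- data[[response]]
  n <- length(y)
  xfull <- cbind(`(Intercept)` = rep(1, n),
                 as.matrix(as.data.frame(data)[candidates]))
  fam <- stats::poisson()
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100L)
  penalty <- if (criterion == "BIC") log(n) else 2
  # lean ranking pass: deviance and criterion only, no coefficient tables
  crit <- numeric(length(subsets))
  ok <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    cols <- c(1L, match(subsets[[i]], candidates) + 1L)
    f <- suppressWarnings(
      stats::glm.fit(xfull[, cols, drop = FALSE], y, family = fam,
                     control = ctrl)
    )
    ll <- sum(stats::dpois(y, f$fitted.values, log = TRUE))
    crit[i] <- -2 * ll + penalty * length(cols)
    ok[i] <- f$converged && !f$boundary &&
      all(is.finite(f$coefficients)) && all(abs(f$coefficients) < 1e6)
  }
  keyname <- vapply(subsets, function(s) paste(sort(s), collapse = "+"),
                    character(1))
  results <- tibble::tibble(
    subset = keyname,
    k = lengths(subsets),
    criterion = crit,
    converged = ok
  )
  if (!any(ok)) {
    stop("no candidate subset produced a converged fit", call. = FALSE)
  }
  idx <- which(ok)
  idx <- idx[order(crit[idx], lengths(subsets)[idx], keyname[idx])]
  structure(
    list(
      best = fit_poisson(data, response, subsets[[idx[1L]]]),
      results = dplyr::arrange(results, .data$criterion),
      criterion = criterion
    ),
    class = "best_subset"
  )
}

#' @export
print.best_subset <- function(x, ...) {
  cat(sprintf("<best_subset> criterion %s over %d subsets\n",
              x$criterion, nrow(x$results)))
  print(x$best)
  invisible(x)
}

#' @export
tidy.best_subset <- function(x, ...) tidy(x$best)

#' @export
glance.best_subset <- function(x, ...) {
  dplyr::mutate(glance(x$best), criterion = x$criterion,
                n_subsets = nrow(x$results))
}

#' Format fitted models as a cross-group coefficient table
#'
#' Lays out one column per group and one row per predictor, in the style
#' of best-subset Poisson model tables: coefficients carry significance
#' codes, predictors not selected in a group show an em dash, rows are
#' sectioned into environmental and landscape factors, and the footer row
#' carries each model's adjusted pseudo-R-squared.
#'
#' @param fits Named list of `poisson_fit` or `best_subset` objects (names
#'   are the group labels).
#' @param environment_vars,landscape_vars Predictor names used to section
#'   the rows; predictors in neither set are listed unsectioned after the
#'   intercept.
#' @param digits Coefficient digits (default 4).
#' @return A tibble with columns `section`, `term`, and one character
#'   column per group.
#' @export
report_table <- function(fits, environment_vars = character(),
                         landscape_vars = character(), digits = 4) {
  fits <- lapply(fits, function(f) if (inherits(f, "best_subset")) f$best else f)
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  all_terms <- unique(unlist(lapply(fits, function(f) f$predictors)))
  section <- function(t) {
    dplyr::case_when(
      t %in% environment_vars ~ "Environmental factor",
      t %in% landscape_vars ~ "Landscape factors",
      TRUE ~ ""
    )
  }
  ordered_terms <- c(
    intersect(environment_vars, all_terms),
    setdiff(all_terms, c(environment_vars, landscape_vars)),
    intersect(landscape_vars, all_terms)
  )
  rows <- tibble::tibble(
    section = c("", section(ordered_terms), ""),
    term = c("(Intercept)", ordered_terms, "R2_adj")
  )
  for (g in names(fits)) {
    f <- fits[[g]]
    cells <- vapply(rows$term, function(t) {
      if (t == "R2_adj") return(formatC(f$r2_adj, digits = digits,
                                        format = "f"))
      i <- match(t, f$coefficients$term)
      if (is.na(i)) return("\u2013")
      paste0(formatC(f$coefficients$estimate[i], digits = digits,
                     format = "f"),
             f$coefficients$signif[i])
    }, character(1))
    rows[[g]] <- unname(cells)
  }
  rows
}
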