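#' Partition explained variation between two predictor sets
#'
#' Fits three Poisson regressions — landscape-only, environment-only, and
#' their union — and partitions the response's explained variation into
#' four fractions from the adjusted pseudo-R-squared of the nested fits:
#' unique landscape `a = R2adj_full - R2adj_env`, shared
#' `b = R2adj_land + R2adj_env - R2adj_full`, unique environment
#' `c = R2adj_full - R2adj_land`, and unexplained `d = 1 - R2adj_full`.
#' The fractions always sum to one. Adjusted-R2 partitions can produce
#' small negative fractions; these are reported as computed (truncating
#' would break the sum-to-one identity) with `negative_fraction = TRUE`.
#'
#' An empty predictor set degenerates the partition to a single-set R2
#' (the empty side is the intercept-only model, R2adj = 0); this is
#' flagged in the `degenerate` column and warned about, never silent.
#'
#' @param data Data frame with response and predictors.
#' @param response Count response column name.
#' @param x_landscape,x_environment Character vectors naming the two
#'   disjoint predictor sets.
#' @return A one-row `variation_partition` tibble: the three adjusted R2
#'   values, the four fractions, `n`, and flags.
#' @export
partition_variation <- function(data, response, x_landscape, x_environment) {
  if (length(intersect(x_landscape, x_environment))) {
    stop("predictor sets must be disjoint", call. = FALSE)
  }
  if (length(x_landscape) == 0L && length(x_environment) == 0L) {
    stop("both predictor sets are empty; nothing to partition", call. = FALSE)
  }
  degenerate <- length(x_landscape) == 0L || length(x_environment) == 0L
  if (degenerate) {
    warning("one predictor set is empty: partition degenerates to a ",
            "single-set R2", call. = FALSE)
  }
  fit_land <- fit_poisson(data, response, x_landscape)
  fit_env <- fit_poisson(data, response, x_environment)
  fit_full <- fit_poisson(data, response, union(x_landscape, x_environment))
  r2l <- fit_land$r2_adj
  r2e <- fit_env$r2_adj
  r2f <- fit_full$r2_adj
  a <- r2f - r2e
  c <- r2f - r2l
  b <- r2l + r2e - r2f
  d <- 1 - r2f
  out <- tibble::tibble(
    n = fit_full$n,
    r2adj_landscape = r2l,
    r2adj_environment = r2e,
    r2adj_full = r2f,
    frac_unique_landscape = a,
    frac_shared = b,
    frac_unique_environment = c,
    frac_unexplained = d,
    degenerate = degenerate,
    negative_fraction = any(c(a, b, c, d) < 0)
  )
  if (out$negative_fraction && !degenerate) {
    warning("adjusted-R2 partition produced a negative fraction; ",
            "reported as computed", call. = FALSE)
  }
  class(out) <- c("variation_partition", class(out))
  out
}

#' Variation partitioning across groups and taxa
#'
#' Runs the full per-group modelling chain for every (group, taxon) pair:
#' collinearity pruning within the group, exhaustive best-subset selection
#' over the union of pruned candidates, splitting the selected predictors
#' back into the landscape and environmental matrices, and adjusted-R2
#' variation partitioning. Groups below the minimum sample size are
#' skipped and logged (small groups cannot support best-subset selection).
#'
#' @param table A `predictor_table` from [assemble_predictors()] (or a
#'   synthetic one).
#' @param taxa Response columns to analyse; default the table's taxa.
#' @param min_n Minimum group size (default 30).
#' @param cor_threshold Collinearity pruning threshold (default 0.7).
#' @param criterion Best-subset criterion, `"BIC"` or `"AIC"`.
#' @param max_k Optional cap on subset size passed to [best_subset()].
#' @return A `variation_partition` tibble with one row per analysed
#'   (group, taxon): selected predictor counts, adjusted R2 values and
#'   fractions. Attributes `skipped` (tibble of skipped groups) and
#'   `fits` (named list of `best_subset` objects, `"group.taxon"`).
#' @export
partition_all <- function(table, taxa = NULL, min_n = 30L,
                          cor_threshold = 0.7,
                          criterion = c("BIC", "AIC"), max_k = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(taxa)) taxa <- attr(table, "taxa")
  group_col <- attr(table, "group_col")
  stopifnot(!is.null(taxa), !is.null(group_col))
  groups <- sort(unique(as.character(table[[group_col]])))

  skipped <- tibble::tibble(group = character(), n = integer(),
                            reason = character())
  fits <- list()
  rows <- list()
  for (g in groups) {
    sub <- table[as.character(table[[group_col]]) == g, ]
    if (nrow(sub) < min_n) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        group = g, n = nrow(sub),
        reason = sprintf("n < %d: insufficient for best-subset selection",
                         min_n)
      ))
      next
    }
    pruned <- prune_collinear(sub, threshold = cor_threshold)
    cand <- c(landscape_vars(pruned), environment_vars(pruned))
    for (tx in taxa) {
      sel <- best_subset(pruned, tx, cand, criterion = criterion,
                         max_k = max_k)
      chosen <- sel$best$predictors
      xl <- intersect(chosen, landscape_vars(pruned))
      xe <- intersect(chosen, environment_vars(pruned))
      part <- withCallingHandlers(
        partition_variation(pruned, tx, xl, xe),
        warning = function(w) invokeRestart("muffleWarning")
      )
      part <- dplyr::mutate(
        part,
        group = g, taxon = tx,
        k_landscape = length(xl), k_environment = length(xe),
        .before = 1L
      )
      rows[[paste(g, tx, sep = ".")]] <- part
      fits[[paste(g, tx, sep = ".")]] <- sel
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("variation_partition", class(tibble::tibble()))
  attr(out, "skipped") <- skipped
  attr(out, "fits") <- fits
  out
}

#' @export
tidy.variation_partition <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Stacked-fraction plot of a variation partition
#'
#' One stacked bar per group (faceted by taxon) showing the unique
#' landscape, shared, unique environmental, and unexplained fractions.
#'
#' @param object A `variation_partition` with `group` and `taxon` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variation_partition <- function(object, ...) {
  stopifnot(all(c("group", "taxon") %in% names(object)))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("frac_"),
    names_to = "fraction", values_to = "value",
    names_prefix = "frac_"
  )
  long$fraction <- factor(
    long$fraction,
    levels = c("unexplained", "shared", "unique_environment",
               "unique_landscape")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$taxon)) +
    ggplot2::labs(x = NULL, y = "fraction of variation",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
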