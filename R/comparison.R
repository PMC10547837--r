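#' Tukey boxplot summary of richness per group
#'
#' Five-number boxplot statistics per group, with outliers flagged by the
#' Tukey rule: values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, quartiles by
#' linear-interpolation quantiles (R type 7). Groups with fewer than 5
#' landscapes get no fences (too few points for quartiles to be
#' meaningful).
#'
#' @param table A `predictor_table` (or any data frame with the columns
#'   below).
#' @param taxon Response column to summarize.
#' @param group_col Grouping column; defaults to the table's group column.
#' @param id_col Landscape id column used to report outlier ids.
#' @return A tibble with one row per group: `n`, `q1`, `median`, `q3`,
#'   `iqr`, `lower_fence`, `upper_fence`, and list-columns
#'   `low_outliers` / `high_outliers` of landscape ids.
#' @export
summarize_richness <- function(table, taxon, group_col = NULL,
                               id_col = "landscape_id") {
  if (is.null(group_col)) group_col <- attr(table, "group_col")
  stopifnot(!is.null(group_col), taxon %in% names(table))
  df <- tibble::tibble(
    group = as.character(table[[group_col]]),
    id = if (id_col %in% names(table)) as.character(table[[id_col]]) else
      as.character(seq_len(nrow(table))),
    y = table[[taxon]]
  )
  summarize_one <- function(d) {
    n <- nrow(d)
    q <- stats::quantile(d$y, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    if (n >= 5L) {
      lo <- q[1] - 1.5 * iqr
      hi <- q[3] + 1.5 * iqr
      low_ids <- d$id[d$y < lo]
      high_ids <- d$id[d$y > hi]
    } else {
      lo <- NA_real_
      hi <- NA_real_
      low_ids <- character()
      high_ids <- character()
    }
    tibble::tibble(
      n = n, q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
      lower_fence = lo, upper_fence = hi,
      low_outliers = list(low_ids), high_outliers = list(high_ids)
    )
  }
  out <- dplyr::group_modify(dplyr::group_by(df, .data$group),
                             ~ summarize_one(.x))
  dplyr::ungroup(out)
}

#' Boxplots of richness by group
#'
#' @param table Data frame with a group column and the taxon counts.
#' @param taxa Response columns to plot.
#' @param group_col Grouping column; defaults to the table's group column.
#' @return A ggplot object: one boxplot per group, faceted by taxon, with
#'   Tukey outliers as points.
#' @export
plot_richness_box <- function(table, taxa, group_col = NULL) {
  if (is.null(group_col)) group_col <- attr(table, "group_col")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(table)[c(group_col, taxa)],
    dplyr::all_of(taxa), names_to = "taxon", values_to = "richness"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group_col]],
                                     y = .data$richness)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$taxon), scales = "free_y") +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}

#' Compare explained-variation fractions across sets of groups
#'
#' Pools a chosen partition fraction over the (group, taxon) rows on each
#' side of a contrast (e.g. tropical versus temperate realms), then runs a
#' one-way ANOVA across the sides and pairwise two-sided t-tests (pooled
#' SD) with a p-value adjustment. Side means are reported as percentages.
#'
#' @param partitions A `variation_partition` table with `group` and
#'   `taxon` columns (from [partition_all()]).
#' @param sides Named list of character vectors of group labels, one per
#'   side of the contrast.
#' @param fraction Which fraction to compare: `"unique_landscape"`,
#'   `"shared"`, `"unique_environment"`, `"unexplained"`, or
#'   `"combined_landscape"` (unique landscape + shared).
#' @param adjust Pairwise p-value adjustment (default `"holm"`; `"none"`
#'   available).
#' @return A `fraction_comparison` object: `$anova` (F, df, p), `$pairwise`
#'   (symmetric matrix of adjusted p-values), `$means` (per-side mean in
#'   percent and n), `$values` (the pooled values used).
#' @export
compare_fractions <- function(partitions,
                              sides,
                              fraction = c("unique_landscape", "shared",
                                           "unique_environment",
                                           "unexplained",
                                           "combined_landscape"),
                              adjust = "holm") {
  fraction <- match.arg(fraction)
  stopifnot(is.list(sides), length(sides) >= 2L, !is.null(names(sides)))
  overlap <- utils::combn(seq_along(sides), 2L, function(ij) {
    length(intersect(sides[[ij[1]]], sides[[ij[2]]])) > 0
  })
  if (any(overlap)) {
    stop("sides must not share groups", call. = FALSE)
  }
  vals <- if (fraction == "combined_landscape") {
    partitions$frac_unique_landscape + partitions$frac_shared
  } else {
    partitions[[paste0("frac_", fraction)]]
  }
  df <- tibble::tibble(group = partitions$group, value = vals)
  df$side <- NA_character_
  for (s in names(sides)) {
    df$side[df$group %in% sides[[s]]] <- s
  }
  df <- df[!is.na(df$side), ]
  counts <- table(df$side)
  if (length(counts) < length(sides) || any(counts < 2L)) {
    stop("every side needs at least 2 fraction values", call. = FALSE)
  }
  df$side <- factor(df$side, levels = names(sides))

  fit <- stats::aov(value ~ side, data = df)
  av <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    F = av[1, "F value"], df1 = av[1, "Df"], df2 = av[2, "Df"],
    p.value = av[1, "Pr(>F)"]
  )
  pw <- stats::pairwise.t.test(df$value, df$side,
                               p.adjust.method = adjust, pool.sd = TRUE)
  k <- length(sides)
  pmat <- matrix(NA_real_, k, k, dimnames = list(names(sides), names(sides)))
  diag(pmat) <- 1
  for (i in rownames(pw$p.value)) {
    for (j in colnames(pw$p.value)) {
      if (!is.na(pw$p.value[i, j])) {
        pmat[i, j] <- pmat[j, i] <- pw$p.value[i, j]
      }
    }
  }
  means <- dplyr::summarise(
    dplyr::group_by(df, .data$side),
    mean_pct = mean(.data$value) * 100, n = dplyr::n(), .groups = "drop"
  )
  structure(
    list(anova = anova_tbl, pairwise = pmat, means = means,
         values = df, fraction = fraction, adjust = adjust),
    class = "fraction_comparison"
  )
}

#' @export
print.fraction_comparison <- function(x, ...) {
  cat(sprintf("<fraction_comparison> fraction: %s, adjust: %s\n",
              x$fraction, x$adjust))
  cat(sprintf("ANOVA F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p.value))
  print(as.data.frame(x$means), digits = 4)
  invisible(x)
}

#' @export
tidy.fraction_comparison <- function(x, ...) {
  pw <- x$pairwise
  combos <- utils::combn(rownames(pw), 2L, simplify = FALSE)
  tibble::tibble(
    side1 = vapply(combos, `[`, character(1), 1L),
    side2 = vapply(combos, `[`, character(1), 2L),
    p.value = vapply(combos, function(cc) pw[cc[1], cc[2]], numeric(1)),
    adjust = x$adjust
  )
}

#' @export
glance.fraction_comparison <- function(x, ...) x$anova
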