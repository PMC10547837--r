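#' Assemble the per-landscape modelling table
#'
#' Inner-joins landscape metrics, environmental covariates, and richness
#' counts on `landscape_id`, tags every predictor as landscape or
#' environmental, converts latitude to absolute latitude, and standardizes
#' predictors to mean 0 / variance 1 within each analysis group. Rows with
#' missing values after the join are dropped and logged; predictor columns
#' with zero variance in any group are dropped with a warning (their
#' standardization is undefined).
#'
#' @param metrics Per-landscape metric table (e.g. from [metrics_table()]):
#'   `landscape_id` plus metric columns.
#' @param covariates Per-landscape environmental covariates: `landscape_id`,
#'   the group column, and covariate columns (one may be `latitude`).
#' @param responses Per-landscape richness counts: `landscape_id` plus one
#'   non-negative integer column per taxon.
#' @param taxa Names of the response columns in `responses`.
#' @param group_col Name of the grouping (realm) column in `covariates`.
#' @param environment_vars Covariate columns tagged as environmental;
#'   default all covariate columns except ids and the group column. Every
#'   metric column is tagged as a landscape predictor.
#' @param abs_latitude Store `latitude` as absolute latitude (default TRUE).
#' @param standardize Standardize predictors within group (default TRUE).
#' @return A `predictor_table`: a tibble with `landscape_id`, the group
#'   column, taxa counts, and predictor columns; attributes
#'   `landscape_vars`, `environment_vars`, `taxa`, `group_col`, and
#'   `dropped` (ids dropped for missing values).
#' @export
assemble_predictors <- function(metrics, covariates, responses,
                                taxa,
                                group_col = "group",
                                environment_vars = NULL,
                                abs_latitude = TRUE,
                                standardize = TRUE) {
  for (tbl in list(metrics, covariates, responses)) {
    if (!"landscape_id" %in% names(tbl)) {
      stop("all inputs must have a `landscape_id` column", call. = FALSE)
    }
    if (anyDuplicated(tbl$landscape_id)) {
      stop("duplicated landscape_id in input", call. = FALSE)
    }
  }
  if (!group_col %in% names(covariates)) {
    stop("group column `", group_col, "` not found in covariates",
         call. = FALSE)
  }
  missing_taxa <- setdiff(taxa, names(responses))
  if (length(missing_taxa)) {
    stop("response column(s) not found: ", paste(missing_taxa, collapse = ", "),
         call. = FALSE)
  }
  for (tx in taxa) {
    y <- responses[[tx]]
    if (!is.numeric(y) || any(!is.na(y) & (y < 0 | y != round(y)))) {
      stop("response `", tx, "` must be non-negative integer counts",
           call. = FALSE)
    }
  }

  landscape_vars <- setdiff(names(metrics), "landscape_id")
  if (is.null(environment_vars)) {
    environment_vars <- setdiff(names(covariates),
                                c("landscape_id", group_col))
  }

  joined <- dplyr::inner_join(metrics, covariates, by = "landscape_id")
  joined <- dplyr::inner_join(joined, responses[c("landscape_id", taxa)],
                              by = "landscape_id")

  all_ids <- unique(c(metrics$landscape_id, covariates$landscape_id,
                      responses$landscape_id))
  dropped <- setdiff(all_ids, joined$landscape_id)

  complete <- stats::complete.cases(joined)
  if (any(!complete)) {
    dropped <- c(dropped, joined$landscape_id[!complete])
    joined <- joined[complete, , drop = FALSE]
  }
  if (length(dropped)) {
    message("dropped ", length(dropped),
            " landscape(s) with missing data: ",
            paste(utils::head(dropped, 10L), collapse = ", "))
  }

  if (abs_latitude && "latitude" %in% names(joined)) {
    joined$latitude <- abs(joined$latitude)
  }

  predictors <- c(landscape_vars, environment_vars)
  if (standardize) {
    constant <- character()
    for (v in predictors) {
      sds <- tapply(joined[[v]], joined[[group_col]], stats::sd)
      if (any(!is.finite(sds)) || any(sds == 0)) {
        constant <- c(constant, v)
      }
    }
    if (length(constant)) {
      warning("dropping constant predictor(s) (zero within-group variance): ",
              paste(constant, collapse = ", "), call. = FALSE)
      predictors <- setdiff(predictors, constant)
      landscape_vars <- setdiff(landscape_vars, constant)
      environment_vars <- setdiff(environment_vars, constant)
      joined <- joined[setdiff(names(joined), constant)]
    }
    joined <- dplyr::mutate(
      dplyr::group_by(joined, dplyr::across(dplyr::all_of(group_col))),
      dplyr::across(dplyr::all_of(predictors),
                    ~ as.numeric(scale(.x)))
    )
    joined <- dplyr::ungroup(joined)
  }

  new_predictor_table(joined, landscape_vars, environment_vars, taxa,
                      group_col, dropped)
}

new_predictor_table <- function(data, landscape_vars, environment_vars,
                                taxa, group_col, dropped = character()) {
  structure(
    tibble::as_tibble(data),
    landscape_vars = landscape_vars,
    environment_vars = environment_vars,
    taxa = taxa,
    group_col = group_col,
    dropped = dropped,
    class = c("predictor_table", class(tibble::tibble()))
  )
}

#' Predictor-set accessors
#'
#' @param table A `predictor_table` from [assemble_predictors()].
#' @return Character vector of column names in the landscape or
#'   environmental predictor set.
#' @export
landscape_vars <- function(table) attr(table, "landscape_vars")

#' @rdname landscape_vars
#' @export
environment_vars <- function(table) attr(table, "environment_vars")

# Keep predictor_table attributes through subsetting rows.
#' @export
`[.predictor_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- new_predictor_table(
      out,
      intersect(attr(x, "landscape_vars"), names(out)),
      intersect(attr(x, "environment_vars"), names(out)),
      attr(x, "taxa"), attr(x, "group_col"), attr(x, "dropped")
    )
  }
  out
}

#' Prune collinear predictors
#'
#' Removes predictors stepwise until no retained pair has \eqn{|r| >}
#' `threshold` (Pearson). At each step the pair with the largest absolute
#' correlation is found and the member with the larger mean absolute
#' correlation against all other remaining predictors is dropped; ties drop
#' the later column in the table's column order. The procedure is
#' deterministic given the column order.
#'
#' @param table A `predictor_table` (or plain data frame with the predictor
#'   columns given in `predictors`).
#' @param threshold Absolute Pearson correlation above which a pair is
#'   considered collinear (default 0.7).
#' @param predictors Columns to consider; defaults to the table's tagged
#'   landscape + environmental predictors.
#' @return The table with the dropped columns removed; attribute
#'   `removal_log` is a tibble (`step`, `dropped`, `partner`, `r`) in
#'   removal order (also retrievable with `attr(x, "removal_log")`).
#' @export
prune_collinear <- function(table, threshold = 0.7, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- c(landscape_vars(table), environment_vars(table))
  }
  if (length(predictors) < 2L) {
    stop("need at least 2 predictors to assess collinearity", call. = FALSE)
  }
  if (nrow(table) < 3L) {
    stop("need at least 3 rows to estimate correlations", call. = FALSE)
  }
  keep <- predictors
  log <- tibble::tibble(step = integer(), dropped = character(),
                        partner = character(), r = numeric())
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(stats::cor(as.data.frame(table[keep])))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- keep[c(worst[["row"]], worst[["col"]])]
    mean_abs <- rowMeans(cm[pair, setdiff(keep, pair), drop = FALSE])
    victim <- if (length(keep) == 2L || mean_abs[1L] != mean_abs[2L]) {
      if (length(keep) == 2L) {
        pair[2L]  # no third column to arbitrate: drop the later one
      } else {
        pair[which.max(mean_abs)]
      }
    } else {
      pair[which.max(match(pair, predictors))]
    }
    partner <- setdiff(pair, victim)
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = nrow(log) + 1L, dropped = victim, partner = partner,
      r = stats::cor(table[[victim]], table[[partner]])
    ))
    keep <- setdiff(keep, victim)
  }
  out <- table[setdiff(names(table), setdiff(predictors, keep))]
  attr(out, "removal_log") <- log
  out
}
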