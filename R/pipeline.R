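#' Run the full analysis pipeline
#'
#' Orchestrates the whole chain — landscape metrics, predictor assembly,
#' collinearity pruning, best-subset Poisson selection, variation
#' partitioning, and optional group contrasts — from a single
#' configuration, writing CSV outputs and a JSON run manifest to an output
#' directory. The stage order is fixed: metrics before pruning before
#' selection before partitioning (the selected predictor union is split
#' into the two matrices).
#'
#' The configuration is a list (or path to a YAML file) with:
#' \describe{
#'   \item{mode}{`"synthetic"` or `"files"`.}
#'   \item{synthetic}{For synthetic mode: arguments for [synth_config()]
#'     (all optional).}
#'   \item{files}{For files mode: `raster_dir` (one ASCII grid per
#'     landscape, `<landscape_id>.asc`), `covariates` and `responses`
#'     (CSV paths), `class_map` (named codes), `taxa`, `group_col`.}
#'   \item{cor_threshold}{Collinearity threshold (default 0.7).}
#'   \item{min_n}{Minimum group size for modelling (default 30).}
#'   \item{criterion}{`"BIC"` (default) or `"AIC"`.}
#'   \item{contrast}{Optional named list of two+ group sets for
#'     [compare_fractions()].}
#' }
#'
#' @param config List or path to a YAML config file.
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `predictor_table`, the partition
#'   table, the comparison (if requested), and the manifest.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = tempfile("richscape_")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  mode <- config$mode %||% "synthetic"
  cor_threshold <- config$cor_threshold %||% 0.7
  min_n <- config$min_n %||% 30L
  criterion <- config$criterion %||% "BIC"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    seed = as.integer(seed),
    mode = mode,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(config),
    stages = list()
  )

  if (mode == "synthetic") {
    scfg <- do.call(synth_config, config$synthetic %||% list())
    data <- generate_dataset(scfg, seed)
    table <- data$table
    metrics <- data$metrics
  } else if (mode == "files") {
    fc <- config$files
    stopifnot(!is.null(fc$raster_dir), !is.null(fc$covariates),
              !is.null(fc$responses))
    covariates <- tibble::as_tibble(
      utils::read.csv(fc$covariates, check.names = FALSE)
    )
    responses <- tibble::as_tibble(
      utils::read.csv(fc$responses, check.names = FALSE)
    )
    ids <- covariates$landscape_id
    paths <- file.path(fc$raster_dir, paste0(ids, ".asc"))
    missing <- !file.exists(paths)
    if (any(missing)) {
      stop("missing raster file(s) for landscape_id: ",
           paste(ids[missing], collapse = ", "), call. = FALSE)
    }
    rasters <- stats::setNames(lapply(paths, read_raster,
                                      cell_size = fc$cell_size), ids)
    class_map <- unlist(fc$class_map)
    metrics <- metrics_table(rasters, class_map = class_map,
                             connectivity = fc$connectivity %||% 8L)
    table <- assemble_predictors(
      metrics, covariates, responses,
      taxa = fc$taxa, group_col = fc$group_col %||% "group"
    )
  } else {
    stop("unknown mode: ", mode, call. = FALSE)
  }
  manifest$stages$metrics <- list(rows = nrow(metrics),
                                  cols = ncol(metrics) - 1L)
  manifest$stages$assembly <- list(
    rows = nrow(table),
    predictors = length(c(landscape_vars(table), environment_vars(table))),
    dropped = attr(table, "dropped")
  )

  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(tibble::as_tibble(table),
                   file.path(out_dir, "predictor_table.csv"),
                   row.names = FALSE)

  parts <- partition_all(table, min_n = min_n,
                         cor_threshold = cor_threshold,
                         criterion = criterion,
                         max_k = config$max_k)
  manifest$stages$partition <- list(
    rows = nrow(parts),
    skipped = attr(parts, "skipped")$group
  )
  utils::write.csv(tibble::as_tibble(parts),
                   file.path(out_dir, "partition.csv"), row.names = FALSE)

  fits <- attr(parts, "fits")
  for (tx in attr(table, "taxa")) {
    tx_fits <- fits[grepl(paste0("\\.", tx, "$"), names(fits))]
    if (length(tx_fits)) {
      names(tx_fits) <- sub(paste0("\\.", tx, "$"), "", names(tx_fits))
      tbl <- report_table(tx_fits,
                          environment_vars = environment_vars(table),
                          landscape_vars = landscape_vars(table))
      utils::write.csv(tbl,
                       file.path(out_dir, paste0("model_table_", tx, ".csv")),
                       row.names = FALSE)
    }
  }

  comparison <- NULL
  if (!is.null(config$contrast)) {
    sides <- lapply(config$contrast, as.character)
    comparison <- compare_fractions(parts, sides,
                                    fraction = config$fraction %||%
                                      "unique_landscape")
    utils::write.csv(tidy(comparison),
                     file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    manifest$stages$comparison <- list(
      fraction = comparison$fraction,
      anova_p = comparison$anova$p.value
    )
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(table = table, partition = parts,
                 comparison = comparison, manifest = manifest,
                 out_dir = out_dir))
}

config_hash <- function(config) {
  # order-stable structural digest; avoids an external hashing dependency
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                            force = TRUE)
  sum(utf8ToInt(canon) * (seq_len(nchar(canon)) %% 97 + 1)) %% 1e9
}

`%||%` <- function(a, b) if (is.null(a)) b else a
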