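#' Configuration for the synthetic study generator
#'
#' Bundles everything the generator needs to emulate a multi-realm urban
#' biodiversity study: per-group sample sizes and latitude belts, the
#' land-use raster regime (grid size, 30 m cells, class proportions,
#' spatial aggregation), the environmental covariate model, a latent
#' factor linking landscape composition to climate, and the generative
#' Poisson coefficients per taxon (on the standardized predictor scale).
#'
#' Defaults emulate the study conditions: five biogeographic realms plus a
#' small Australasian group (505 landscapes in total), 30 m cells,
#' forest / wetland / built-up / other land-use classes with moderate
#' spatial aggregation, climate covariates driven by latitude, and
#' realm-typical richness levels (intercepts near `log` mean counts of a
#' few hundred birds, ~150 mammals, ~10 amphibians).
#'
#' @param groups Named list; each element a list with `n` (landscapes) and
#'   `lat` (c(mean, sd) of latitude in degrees, signed).
#' @param dim Grid side length in cells (square grids, >= 8).
#' @param cell_size Cell side in meters.
#' @param proportions Named numeric vector of target class proportions
#'   (sum <= 1; the remainder is background). Names become class names.
#' @param aggregation Cluster seeding probability in `[0, 1)`: 0 gives
#'   salt-and-pepper landscapes, values near 1 give large contiguous
#'   blocks.
#' @param proportion_jitter SD of the per-landscape logit-scale jitter
#'   applied to class proportions (composition varies between cities).
#' @param latent_loading Loading in `[0, 1]` of a shared latent factor on
#'   both forest cover and climate; 0 makes the landscape and
#'   environmental predictor sets independent.
#' @param beta Named list per taxon: each a named numeric vector of
#'   generative coefficients with an `(Intercept)` entry; other names must
#'   be predictor columns (standardized scale).
#' @param connectivity Patch-labeling neighborhood for the metric columns.
#' @param landscape_predictors Metric columns entering the models as the
#'   landscape predictor set. The default mirrors the usual candidate list
#'   of such studies (class area, cohesion, and edge density of the named
#'   habitat classes plus the forest/built-up edge sum, up to ~18
#'   candidates with the covariates); all other metrics (LPI included)
#'   are still computed and reported, just not used as predictors.
#' @return A `synth_config` list.
#' @export
synth_config <- function(
    groups = list(
      NT = list(n = 75L, lat = c(-15, 12)),
      AF = list(n = 50L, lat = c(5, 12)),
      IM = list(n = 80L, lat = c(18, 8)),
      PA = list(n = 150L, lat = c(45, 8)),
      NE = list(n = 143L, lat = c(40, 7)),
      AU = list(n = 7L, lat = c(-30, 6))
    ),
    dim = 64L,
    cell_size = 30,
    proportions = c(Forest = 0.25, Wetland = 0.05, Builtup = 0.35,
                    Other = 0.25),
    aggregation = 0.55,
    proportion_jitter = 0.5,
    latent_loading = 0.4,
    beta = list(
      mammal = c(`(Intercept)` = 5.0, latitude = -1.0, elev_mean = -0.3,
                 CA_Forest = 0.4, Coh_Forest = 0.3),
      bird = c(`(Intercept)` = 5.8, latitude = -0.5,
               precip_seasonality = -0.3, CA_Forest = 0.5, ED_Forest = 0.2),
      amphibian = c(`(Intercept)` = 2.3, precip_mean = 0.8,
                    temp_seasonality = -0.5, CA_Forest = 0.6,
                    ED_Wetland = -0.4)
    ),
    connectivity = 8L,
    landscape_predictors = c("CA_Forest", "CA_Wetland", "CA_Builtup",
                             "Coh_Forest", "Coh_Wetland", "Coh_Builtup",
                             "ED_Forest", "ED_Wetland", "ED_Builtup",
                             "ES_Forest.Builtup")) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  # normalize list-form inputs (e.g. from YAML configs) to named vectors
  groups <- lapply(groups, function(g) {
    list(n = as.integer(g$n), lat = as.numeric(unlist(g$lat)))
  })
  proportions <- unlist(proportions)
  beta <- lapply(beta, function(b) {
    v <- unlist(b)
    stats::setNames(as.numeric(v), names(v))
  })
  dim <- as.integer(dim)
  if (dim < 8L) stop("`dim` must be at least 8", call. = FALSE)
  if (any(proportions < 0) || any(proportions > 1) || sum(proportions) > 1) {
    stop("class proportions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (is.null(names(proportions))) {
    stop("`proportions` must be named by class", call. = FALSE)
  }
  if (aggregation < 0 || aggregation >= 1) {
    stop("`aggregation` must be in [0, 1)", call. = FALSE)
  }
  if (length(proportions) > dim * dim) {
    stop("more classes than cells", call. = FALSE)
  }
  structure(
    list(groups = groups, dim = dim, cell_size = cell_size,
         proportions = proportions, aggregation = aggregation,
         proportion_jitter = proportion_jitter,
         latent_loading = latent_loading, beta = beta,
         connectivity = as.integer(connectivity),
         landscape_predictors = landscape_predictors),
    class = "synth_config"
  )
}

#' Preset configurations for the two explanatory regimes
#'
#' Two single-group presets contrasting which factor set drives richness:
#' `"environment"` puts large coefficients on climate/latitude and
#' near-zero ones on landscape metrics (a temperate, Nearctic-like
#' regime); `"landscape"` does the reverse (a tropical, Indo-Malayan-like
#' regime where forest amount and configuration dominate).
#'
#' @param regime `"environment"` or `"landscape"`.
#' @param n Landscapes in the single group (default 60).
#' @param dim Grid side length (default 32; small grids keep the raster
#'   stage fast in simulation studies).
#' @return A `synth_config`.
#' @export
synth_config_regime <- function(regime = c("environment", "landscape"),
                                n = 60L, dim = 32L) {
  regime <- match.arg(regime)
  beta_env <- c(`(Intercept)` = 4.5, latitude = -0.7, temp_mean = 0.5,
                precip_mean = 0.4, CA_Forest = 0.05, ED_Forest = 0.05)
  beta_land <- c(`(Intercept)` = 4.5, latitude = -0.05, temp_mean = 0.05,
                 CA_Forest = 0.6, Coh_Forest = 0.35, ED_Builtup = -0.3)
  b <- if (regime == "environment") beta_env else beta_land
  synth_config(
    groups = list(G1 = list(n = as.integer(n),
                            lat = if (regime == "environment") c(42, 8)
                                  else c(12, 8))),
    dim = dim,
    beta = list(mammal = b),
    latent_loading = 0,
    # a compact candidate list keeps the exhaustive enumeration small in
    # replicated simulation studies
    landscape_predictors = c("CA_Forest", "Coh_Forest", "ED_Forest",
                             "Coh_Builtup", "ED_Builtup")
  )
}

# Modified-random-clusters neutral landscape:
#  (i) Bernoulli seed cells at the aggregation probability,
#  (ii) 4-connectivity cluster labeling of the seed mask,
#  (iii) cluster-by-cluster class assignment chasing target proportions
#        (largest remaining deficit first),
#  (iv) unassigned cells filled from a random assigned 8-neighbor,
#       iterated until covered (i.i.d. draw when no seeds exist at all).
#' Generate one neutral land-use landscape
#'
#' Modified-random-clusters generator: spatially aggregated categorical
#' grids whose realized class proportions track the configured targets.
#' `aggregation = 0` degenerates to independent per-cell class draws.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the same seed reproduces the same grid.
#' @param proportions Optional override of the config's class proportions
#'   (used for per-landscape composition jitter).
#' @param prop_tol Largest tolerated absolute deviation of any realized
#'   class proportion from its target (default 0.05). Draws violating it,
#'   or missing a positive-target class entirely, are redrawn from derived
#'   seeds (at most 25 attempts; the best attempt is kept if none
#'   qualifies). Percolation occasionally produces one giant cluster that
#'   no whole-cluster assignment can balance; bounded resampling keeps the
#'   composition on target without breaking determinism.
#' @return A [cat_raster()] with classes coded `1..k` in the order of the
#'   proportion names.
#' @export
generate_landscape <- function(config, seed, proportions = NULL,
                               prop_tol = 0.05) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(proportions)) proportions <- config$proportions
  if (any(proportions < 0) || sum(proportions) > 1) {
    stop("infeasible class proportions", call. = FALSE)
  }
  targets_all <- c(proportions, 1 - sum(proportions))
  best <- NULL
  best_dev <- Inf
  for (try in seq_len(25L)) {
    r <- generate_landscape_once(
      config, as.integer((as.numeric(seed) + (try - 1) * 15485863) %%
                           2147483629),
      proportions
    )
    realized <- vapply(c(seq_along(proportions), 0L),
                       function(k) mean(r$grid == k), numeric(1))
    dev <- max(abs(realized - targets_all))
    present <- all(realized[seq_along(proportions)][proportions > 0] > 0)
    if (dev < best_dev && present) {
      best <- r
      best_dev <- dev
    }
    if (dev <= prop_tol && present) {
      return(r)
    }
  }
  if (is.null(best)) {
    stop("could not realize the requested class proportions", call. = FALSE)
  }
  best
}

generate_landscape_once <- function(config, seed, proportions) {
  nr <- config$dim
  nc <- config$dim
  n <- nr * nc
  set.seed(as.integer(seed))

  # background treated as one more assignable class so that empty space is
  # spatially aggregated too
  p_bg <- max(0, 1 - sum(proportions))
  targets <- c(proportions, .background = p_bg) * n
  class_codes <- c(seq_along(proportions), 0L)

  assign_class <- function(sizes) {
    # clusters are processed in decreasing size order and each is assigned
    # to the class with the largest remaining cell deficit, with targets
    # scaled to the seeded-cell total; large clusters therefore alternate
    # among the common classes while the tail of small clusters serves the
    # rare ones, keeping realized proportions close to the targets
    scaled <- targets / sum(targets) * sum(sizes)
    assigned <- numeric(length(targets))
    out <- integer(length(sizes))
    for (i in order(sizes, decreasing = TRUE)) {
      deficit <- scaled - assigned
      j <- which.max(deficit)
      out[i] <- j
      assigned[j] <- assigned[j] + sizes[i]
    }
    out
  }

  if (config$aggregation <= 0) {
    cls <- sample.int(length(targets), n, replace = TRUE,
                      prob = targets / n)
    grid <- matrix(class_codes[cls], nr, nc)
    return(cat_raster(grid, config$cell_size))
  }

  mask <- matrix(stats::runif(n) < config$aggregation, nr, nc)
  grid <- matrix(NA_integer_, nr, nc)
  if (any(mask)) {
    comp <- cluster_membership(mask)
    sizes <- tabulate(comp[mask])
    ord <- sample.int(length(sizes))   # random cluster order
    cls_of_cluster <- integer(length(sizes))
    cls_of_cluster[ord] <- assign_class(sizes[ord])
    grid[mask] <- class_codes[cls_of_cluster[comp[mask]]]
  }
  # nearest-cluster fill: repeatedly adopt the class of a random assigned
  # 8-neighbor
  while (anyNA(grid)) {
    open <- which(is.na(grid))
    nb <- neighbor_values(grid, open, nr, nc)
    pick <- apply(nb, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[sample.int(length(v), 1L)] else NA_integer_
    })
    if (all(is.na(pick))) {
      # no assigned cell anywhere: fall back to i.i.d. assignment
      cls <- sample.int(length(targets), length(open), replace = TRUE,
                        prob = targets / n)
      grid[open] <- class_codes[cls]
    } else {
      grid[open[!is.na(pick)]] <- pick[!is.na(pick)]
    }
  }
  cat_raster(grid, config$cell_size)
}

# 4-connectivity component labels of a logical mask (0 where FALSE)
cluster_membership <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- function(i, j) (j - 1L) * nr + i
  edges <- list()
  if (nc > 1L) {
    ok <- mask[, -nc, drop = FALSE] & mask[, -1L, drop = FALSE]
    if (any(ok)) {
      ij <- which(ok, arr.ind = TRUE)
      edges[[1L]] <- cbind(idx(ij[, 1L], ij[, 2L]), idx(ij[, 1L], ij[, 2L] + 1L))
    }
  }
  if (nr > 1L) {
    ok <- mask[-nr, , drop = FALSE] & mask[-1L, , drop = FALSE]
    if (any(ok)) {
      ij <- which(ok, arr.ind = TRUE)
      edges[[length(edges) + 1L]] <-
        cbind(idx(ij[, 1L], ij[, 2L]), idx(ij[, 1L] + 1L, ij[, 2L]))
    }
  }
  graph <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edges)) {
    graph <- igraph::add_edges(graph, t(do.call(rbind, edges)))
  }
  memb <- igraph::components(graph)$membership
  comp <- matrix(0L, nr, nc)
  comp[mask] <- match(memb[which(mask)], sort(unique(memb[which(mask)])))
  comp
}

# 8-neighborhood values of the given cell indices (matrix: cells x 8)
neighbor_values <- function(grid, cells, nr, nc) {
  i <- ((cells - 1L) %% nr) + 1L
  j <- ((cells - 1L) %/% nr) + 1L
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  out <- matrix(NA_integer_, length(cells), 8L)
  for (s in seq_along(shifts)) {
    ii <- i + shifts[[s]][1L]
    jj <- j + shifts[[s]][2L]
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    out[ok, s] <- grid[cbind(ii[ok], jj[ok])]
  }
  out
}

#' Generate environmental covariates
#'
#' Draws per-landscape climate, topography, and latitude values: latitude
#' from the group's belt, temperature and precipitation means declining
#' with absolute latitude, their seasonalities increasing with it, and
#' log-normal-ish elevation with a non-negative coefficient of variation.
#' A latent factor (shared with [generate_landscape()]'s forest cover via
#' `latent_loading`) shifts temperature and precipitation, inducing
#' landscape-environment correlation when the loading is non-zero.
#'
#' @param config A [synth_config()].
#' @param group Name of the group (must exist in `config$groups`).
#' @param seed Integer seed.
#' @param latent Optional numeric vector (length `n`) of latent-factor
#'   scores; drawn `N(0, 1)` if `NULL`.
#' @return A tibble with `landscape_id`, the group label, `latent`, and
#'   covariate columns `latitude`, `elev_mean`, `elev_cv`, `temp_mean`,
#'   `temp_seasonality`, `precip_mean`, `precip_seasonality`.
#' @export
generate_covariates <- function(config, group, seed, latent = NULL) {
  stopifnot(inherits(config, "synth_config"))
  gcfg <- config$groups[[group]]
  if (is.null(gcfg)) stop("unknown group: ", group, call. = FALSE)
  if (gcfg$lat[2] <= 0) stop("latitude SD must be positive", call. = FALSE)
  n <- gcfg$n
  set.seed(as.integer(seed))
  if (is.null(latent)) latent <- stats::rnorm(n)
  lam <- config$latent_loading
  lat <- stats::rnorm(n, gcfg$lat[1], gcfg$lat[2])
  alat <- abs(lat)
  tibble::tibble(
    landscape_id = sprintf("%s_%03d", group, seq_len(n)),
    group = group,
    latent = latent,
    latitude = lat,
    elev_mean = exp(stats::rnorm(n, 5.5, 0.8)),
    elev_cv = abs(stats::rnorm(n, 0.3, 0.15)),
    temp_mean = 27 - 0.45 * alat + 3 * lam * latent + stats::rnorm(n, 0, 2),
    temp_seasonality = pmax(0, 0.25 * alat + stats::rnorm(n, 1, 1.5)),
    precip_mean = pmax(50, 1600 - 18 * alat + 400 * lam * latent +
                         stats::rnorm(n, 0, 250)),
    precip_seasonality = abs(stats::rnorm(n, 50, 20))
  )
}

#' Generate Poisson richness counts from a log-linear model
#'
#' Draws \eqn{Y \sim Poisson(\exp(\beta_0 + \sum_i \beta_i x_i))}
#' independently per taxon, with taxon-specific coefficients on the
#' standardized predictor scale.
#'
#' @param predictors Data frame of (standardized) predictor columns, one
#'   row per landscape.
#' @param beta Named list per taxon of named coefficient vectors; each
#'   must contain `(Intercept)`, all other names must be columns of
#'   `predictors`.
#' @param seed Integer seed.
#' @return A tibble of integer counts, one column per taxon.
#' @export
generate_richness <- function(predictors, beta, seed) {
  stopifnot(is.list(beta), !is.null(names(beta)))
  set.seed(as.integer(seed))
  out <- purrr::map(beta, function(b) {
    if (!"(Intercept)" %in% names(b)) {
      stop("each beta vector needs an `(Intercept)` entry", call. = FALSE)
    }
    terms <- setdiff(names(b), "(Intercept)")
    missing <- setdiff(terms, names(predictors))
    if (length(missing)) {
      stop("beta names not in predictors: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    eta <- b[["(Intercept)"]]
    for (t in terms) eta <- eta + b[[t]] * predictors[[t]]
    if (any(eta > 20)) {
      stop("linear predictor exceeds 20: expected counts would overflow; ",
           "rescale the coefficients", call. = FALSE)
    }
    stats::rpois(length(eta), exp(eta))
  })
  tibble::as_tibble(out)
}

#' Generate a complete synthetic study
#'
#' Runs the whole generative chain: per landscape, a jittered-composition
#' neutral land-use raster, its landscape metrics, and environmental
#' covariates sharing a latent factor with forest cover; then
#' standardization within group and Poisson richness counts from the
#' configured coefficients. The result is the same `predictor_table` the
#' real-data path produces, plus the ingredients for audit.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed; all per-landscape seeds derive from it.
#' @param keep_rasters Keep the generated rasters in the result (default
#'   FALSE; they are bulky).
#' @return A list: `table` (a `predictor_table` with richness columns),
#'   `metrics` (raw, unstandardized metric table), `covariates` (raw
#'   covariates), `rasters` (if kept), `config`, `seed`.
#' @export
generate_dataset <- function(config, seed, keep_rasters = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  seed <- as.integer(seed)
  taxa <- names(config$beta)
  class_map <- stats::setNames(seq_along(config$proportions),
                               names(config$proportions))
  cov_list <- list()
  met_list <- list()
  rasters <- list()
  derive_seed <- function(...) {
    as.integer(sum(as.numeric(c(...))) %% 2147483629)
  }
  for (gi in seq_along(config$groups)) {
    g <- names(config$groups)[gi]
    cov_seed <- derive_seed(seed * 131, gi * 7919)
    cov <- generate_covariates(config, g, cov_seed)
    cov_list[[g]] <- cov
    for (li in seq_len(nrow(cov))) {
      ls_seed <- derive_seed(seed * 131, gi * 7919, li * 104729)
      props <- jitter_proportions(config, cov$latent[li], ls_seed)
      r <- generate_landscape(config, ls_seed, proportions = props)
      if (keep_rasters) rasters[[cov$landscape_id[li]]] <- r
      met_list[[cov$landscape_id[li]]] <- r
    }
  }
  covariates <- dplyr::bind_rows(cov_list)
  metrics <- metrics_table(met_list, class_map = class_map,
                           connectivity = config$connectivity)
  predictor_cols <- intersect(config$landscape_predictors, names(metrics))
  # standardize, then draw richness from the standardized predictors so the
  # configured coefficients live on the scale the models are fitted on
  table0 <- assemble_predictors(
    metrics[c("landscape_id", predictor_cols)],
    dplyr::select(covariates, -"latent"),
    tibble::tibble(landscape_id = covariates$landscape_id),
    taxa = character(), group_col = "group"
  )
  richness <- generate_richness(table0, config$beta,
                                derive_seed(seed * 131, 977))
  table <- dplyr::bind_cols(table0, richness)
  table <- new_predictor_table(
    table, landscape_vars(table0), environment_vars(table0),
    taxa, "group", attr(table0, "dropped")
  )
  list(table = table, metrics = metrics, covariates = covariates,
       rasters = if (keep_rasters) rasters else NULL,
       config = config, seed = seed)
}

# per-landscape composition jitter on the logit scale; the latent factor
# loads on forest cover so landscape and environment can share structure
jitter_proportions <- function(config, latent, seed) {
  set.seed(as.integer(seed))
  p <- config$proportions
  lg <- stats::qlogis(pmin(pmax(p, 1e-4), 1 - 1e-4))
  shift <- stats::rnorm(length(p), 0, config$proportion_jitter)
  if ("Forest" %in% names(p)) {
    shift[names(p) == "Forest"] <- shift[names(p) == "Forest"] +
      1.2 * config$latent_loading * latent
  }
  q <- stats::plogis(lg + shift)
  # renormalize only if the jitter pushed the total over 1, preserving a
  # background share otherwise
  tot <- sum(q)
  target_tot <- min(sum(p) + 0.05, 0.98)
  if (tot > target_tot) q <- q * target_tot / tot
  stats::setNames(q, names(p))
}
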