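make_inputs <- function(n = 6) {
  ids <- sprintf("L%02d", seq_len(n))
  set.seed(11)
  metrics <- tibble::tibble(
    landscape_id = ids,
    CA_Forest = runif(n, 0, 9e4),
    ED_Forest = runif(n, 0, 300)
  )
  covariates <- tibble::tibble(
    landscape_id = ids,
    group = rep(c("A", "B"), length.out = n),
    latitude = runif(n, -40, 40),
    temp_mean = rnorm(n, 15, 5)
  )
  responses <- tibble::tibble(
    landscape_id = ids,
    mammal = rpois(n, 20)
  )
  list(metrics = metrics, covariates = covariates, responses = responses)
}

test_that("assembly joins, tags sets, and standardizes within group", {
  x <- make_inputs(8)
  t <- assemble_predictors(x$metrics, x$covariates, x$responses,
                           taxa = "mammal", group_col = "group")
  expect_s3_class(t, "predictor_table")
  expect_equal(nrow(t), 8)
  expect_setequal(landscape_vars(t), c("CA_Forest", "ED_Forest"))
  expect_setequal(environment_vars(t), c("latitude", "temp_mean"))
  # standardized within group
  for (g in c("A", "B")) {
    v <- t$CA_Forest[t$group == g]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  # latitude became absolute before scaling: recompute independently
  raw <- x$covariates
  for (g in c("A", "B")) {
    want <- as.numeric(scale(abs(raw$latitude[raw$group == g])))
    expect_equal(t$latitude[t$group == g], want, tolerance = 1e-12)
  }
})

test_that("assembly drops unmatched and incomplete rows with a log", {
  x <- make_inputs(8)
  x$covariates <- x$covariates[-3, ]          # one id missing a covariate row
  x$metrics$CA_Forest[8] <- NA                # one incomplete row
  expect_message(
    t <- assemble_predictors(x$metrics, x$covariates, x$responses,
                             taxa = "mammal", group_col = "group"),
    "dropped 2"
  )
  expect_equal(nrow(t), 6)
  expect_setequal(attr(t, "dropped"), c("L03", "L08"))
})

test_that("assembly rejects bad keys and responses, drops constants", {
  x <- make_inputs(6)
  bad <- x$metrics
  bad$landscape_id[2] <- bad$landscape_id[1]
  expect_error(
    assemble_predictors(bad, x$covariates, x$responses,
                        taxa = "mammal", group_col = "group"),
    "duplicated"
  )
  xr <- x$responses
  xr$mammal[1] <- 2.5
  expect_error(
    assemble_predictors(x$metrics, x$covariates, xr,
                        taxa = "mammal", group_col = "group"),
    "integer"
  )
  xm <- x$metrics
  xm$ED_Forest <- 42                           # zero variance everywhere
  expect_warning(
    t <- assemble_predictors(xm, x$covariates, x$responses,
                             taxa = "mammal", group_col = "group"),
    "constant"
  )
  expect_false("ED_Forest" %in% names(t))
  expect_false("ED_Forest" %in% landscape_vars(t))
})

test_that("collinearity pruning removes the right column and stops at the threshold", {
  set.seed(21)
  n <- 100
  x1 <- rnorm(n)
  d <- tibble::tibble(
    landscape_id = as.character(1:n), group = "A",
    x1 = x1, x2 = x1, x3 = rnorm(n), mammal = rpois(n, 5)
  )
  t <- richscape:::new_predictor_table(d, c("x1", "x2"), "x3", "mammal",
                                       "group")
  pruned <- prune_collinear(t, threshold = 0.7)
  log <- attr(pruned, "removal_log")
  expect_equal(nrow(log), 1)
  expect_true(log$dropped %in% c("x1", "x2"))
  expect_true("x3" %in% names(pruned))
  expect_equal(sum(c("x1", "x2") %in% names(pruned)), 1)

  # orthogonal / sub-threshold predictors survive untouched
  d2 <- tibble::tibble(
    landscape_id = as.character(1:4), group = "A",
    x1 = c(1, 1, -1, -1), x2 = c(1, -1, 1, -1), x3 = c(1, -1, -1, 1),
    mammal = c(1L, 2L, 3L, 4L)
  )
  t2 <- richscape:::new_predictor_table(d2, c("x1", "x2"), "x3", "mammal",
                                        "group")
  p2 <- prune_collinear(t2)
  expect_equal(nrow(attr(p2, "removal_log")), 0)
  expect_setequal(names(p2), names(d2))
})

test_that("pruning is deterministic and leaves max |r| under the threshold", {
  set.seed(31)
  n <- 60
  base <- matrix(rnorm(n * 3), n, 3)
  d <- tibble::tibble(
    landscape_id = as.character(1:n), group = "A",
    a = base[, 1],
    b = base[, 1] + rnorm(n, sd = 0.2),
    c = base[, 2],
    d = base[, 2] * 0.9 + base[, 3] * 0.5,
    e = base[, 3],
    mammal = rpois(n, 10)
  )
  t <- richscape:::new_predictor_table(d, c("a", "b", "c"), c("d", "e"),
                                       "mammal", "group")
  p1 <- prune_collinear(t)
  p2 <- prune_collinear(t)
  expect_identical(attr(p1, "removal_log"), attr(p2, "removal_log"))
  kept <- intersect(c("a", "b", "c", "d", "e"), names(p1))
  cm <- abs(cor(as.data.frame(p1)[kept]))
  diag(cm) <- 0
  expect_lte(max(cm), 0.7)
})

test_that("pruning refuses degenerate inputs", {
  d <- tibble::tibble(landscape_id = c("1", "2"), group = "A",
                      x1 = c(1, 2), x2 = c(2, 1), mammal = c(1L, 2L))
  t <- richscape:::new_predictor_table(d, "x1", "x2", "mammal", "group")
  expect_error(prune_collinear(t), "3 rows")
  d3 <- dplyr::bind_rows(d, d[1, ])
  t3 <- richscape:::new_predictor_table(d3, "x1", character(), "mammal",
                                        "group")
  expect_error(prune_collinear(t3), "2 predictors")
})
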