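test_that("class area sums patch areas and handles absent classes", {
  g <- matrix(0L, 4, 4)
  g[1:2, 1:4] <- 1L   # 8 cells of class 1
  p <- label_patches(cat_raster(g, 30))
  expect_equal(class_area(p, 1L), 8 * 900)
  expect_warning(expect_equal(class_area(p, 9L), 0), "absent")
  # uniform grid: class area equals total landscape area
  pu <- label_patches(cat_raster(matrix(1L, 10, 10), 30))
  expect_equal(class_area(pu, 1L), 100 * 900)
})

test_that("edge sums match hand-enumerated faces", {
  g <- matrix(c(1L, 1L, 2L, 2L), 2, 2)   # two vertical unlike faces
  r <- cat_raster(g, 30)
  expect_equal(edge_sum(r, 1L, 2L), 60)
  expect_error(edge_sum(r, 1L, 1L), "differ")
  # uniform grid: no interior edges
  ru <- cat_raster(matrix(1L, 3, 3), 30)
  expect_equal(edge_sum(ru, 1L, 2L), 0)
  # 1x1 grid: the class-total with boundary is the full cell perimeter
  r1 <- cat_raster(matrix(1L, 1, 1), 30)
  expect_equal(edge_sum(r1, 1L, include_boundary = TRUE), 120)
  expect_equal(edge_sum(r1, 1L, include_boundary = FALSE), 0)
})

test_that("cohesion matches closed-form cases", {
  # single-cell patch in a 2x2 grid: numerator bracket collapses to 0
  g <- matrix(0L, 2, 2)
  g[1, 1] <- 1L
  expect_equal(cohesion(label_patches(cat_raster(g, 30)), 1L), 0)
  # full n x n grids score exactly 100
  for (n in c(2, 3, 5)) {
    p <- label_patches(cat_raster(matrix(1L, n, n), 30))
    expect_equal(cohesion(p, 1L), 100)
  }
  # absent class and degenerate 1-cell landscape are undefined
  expect_true(is.na(cohesion(label_patches(cat_raster(g, 30)), 5L)))
  expect_true(is.na(cohesion(label_patches(cat_raster(matrix(1L, 1, 1), 30)),
                             1L)))
})

test_that("cohesion is invariant to duplicating a patch", {
  # two identical disjoint patches give the same ratio as one alone
  g1 <- matrix(0L, 4, 9)
  g1[2:3, 2:3] <- 1L
  g2 <- g1
  g2[2:3, 6:7] <- 1L
  c1 <- cohesion(label_patches(cat_raster(g1, 30)), 1L)
  c2 <- cohesion(label_patches(cat_raster(g2, 30)), 1L)
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("edge density follows its definition and scaling law", {
  g <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  r <- cat_raster(g, 30)
  # face enumeration: 2 interior + 4 grid-boundary class-1 faces
  expect_equal(edge_density(r, 1L, include_boundary = TRUE),
               (2 + 4) * 30 / 3600 * 10000)
  expect_equal(edge_density(r, 1L, include_boundary = FALSE),
               2 * 30 / 3600 * 10000)
  # uniform grid, interior only: zero
  expect_equal(edge_density(cat_raster(matrix(1L, 3, 3), 30), 1L,
                            include_boundary = FALSE), 0)
  # doubling the cell size quadruples A, doubles length: density halves
  set.seed(7)
  g <- random_grid(5, 5)
  ed30 <- edge_density(cat_raster(g, 30), 1L)
  ed60 <- edge_density(cat_raster(g, 60), 1L)
  expect_equal(ed60, ed30 / 2, tolerance = 1e-12)
})

test_that("largest patch index matches forced cases", {
  g <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  expect_equal(largest_patch_index(label_patches(cat_raster(g, 30))), 75)
  expect_equal(
    largest_patch_index(label_patches(cat_raster(matrix(1L, 4, 4), 30))), 100
  )
  # 3x3: class 1 one 5-cell patch, class 2 two 2-cell patches
  g <- matrix(c(1L, 1L, 2L,
                1L, 1L, 2L,
                1L, 2L, 2L), 3, 3, byrow = TRUE)
  p <- label_patches(cat_raster(g, 30), connectivity = 4)
  expect_equal(sum(p$class == 1L), 1L)
  expect_equal(largest_patch_index(p), 5 / 9 * 100, tolerance = 1e-9)
  # empty landscape is undefined
  expect_true(is.na(largest_patch_index(
    label_patches(cat_raster(matrix(0L, 2, 2), 30))
  )))
})

test_that("all metrics equal the brute-force oracle on random small grids", {
  set.seed(404)
  for (rep in 1:40) {
    g <- random_grid(sample(1:6, 1), sample(1:6, 1))
    r <- cat_raster(g, 30)
    for (conn in c(4L, 8L)) {
      p <- label_patches(r, conn)
      for (cl in r$class_codes) {
        expect_equal(class_area(p, cl), oracle_class_area(g, cl, 30))
        expect_equal(cohesion(p, cl), oracle_cohesion(g, cl, 30, conn),
                     tolerance = 1e-9)
        for (ib in c(TRUE, FALSE)) {
          expect_equal(edge_density(r, cl, include_boundary = ib),
                       oracle_edge_density(g, cl, 30, ib),
                       tolerance = 1e-9)
        }
      }
      codes <- r$class_codes
      if (length(codes) >= 2) {
        prs <- utils::combn(codes, 2, simplify = FALSE)
        for (pr in prs) {
          expect_equal(edge_sum(r, pr[1], pr[2]),
                       oracle_interior_faces(g, pr[1], pr[2]) * 30)
        }
      }
      expect_equal(largest_patch_index(p), oracle_lpi(g, 30, conn),
                   tolerance = 1e-9)
    }
  }
})

test_that("metrics are invariant under rotation and reflection", {
  set.seed(505)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  for (rep in 1:10) {
    g <- random_grid(sample(2:6, 1), sample(2:6, 1))
    variants <- list(rot90(g), g[nrow(g):1, , drop = FALSE],
                     g[, ncol(g):1, drop = FALSE])
    r0 <- cat_raster(g, 30)
    p0 <- label_patches(r0)
    for (v in variants) {
      rv <- cat_raster(v, 30)
      pv <- label_patches(rv)
      for (cl in r0$class_codes) {
        expect_equal(class_area(pv, cl), class_area(p0, cl))
        expect_equal(cohesion(pv, cl), cohesion(p0, cl), tolerance = 1e-12)
        expect_equal(edge_density(rv, cl), edge_density(r0, cl),
                     tolerance = 1e-12)
      }
      expect_equal(largest_patch_index(pv), largest_patch_index(p0),
                   tolerance = 1e-12)
    }
  }
})

test_that("merging two patches never decreases cohesion", {
  set.seed(606)
  tried <- 0
  for (rep in 1:60) {
    g <- random_grid(8, 8, n_classes = 2L, p_background = 0.3)
    r <- cat_raster(g, 30)
    p <- label_patches(r, 4L)
    if (sum(p$class == 1L) < 2) next
    # find a background/other cell whose conversion to class 1 bridges
    # two distinct class-1 patches
    lab <- oracle_label(g * (g == 1L), 4L)
    cand <- which(g != 1L, arr.ind = TRUE)
    for (row in seq_len(nrow(cand))) {
      i <- cand[row, 1]; j <- cand[row, 2]
      nb <- c()
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8 && lab[ii, jj] > 0) {
          nb <- c(nb, lab[ii, jj])
        }
      }
      if (length(unique(nb)) >= 2) {
        g2 <- g
        g2[i, j] <- 1L
        c_before <- cohesion(p, 1L)
        c_after <- cohesion(label_patches(cat_raster(g2, 30), 4L), 1L)
        expect_gte(c_after, c_before - 1e-9)
        tried <- tried + 1
        break
      }
    }
    if (tried >= 15) break
  }
  expect_gte(tried, 5)
})

test_that("metrics_table pivots into the predictor naming convention", {
  g <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  m <- metrics_table(list(city1 = cat_raster(g, 30)),
                     class_map = c(Forest = 1L, Builtup = 2L))
  expect_named(m, c("landscape_id", "CA_Forest", "Coh_Forest", "ED_Forest",
                    "CA_Builtup", "Coh_Builtup", "ED_Builtup",
                    "ES_Forest.Builtup", "LPI"))
  expect_equal(m$CA_Forest, 1800)
  expect_equal(m$ES_Forest.Builtup, 60)
  expect_equal(m$LPI, 50)
})
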