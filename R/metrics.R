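#' Class area
#'
#' Total area of a land-use class: the sum of its patch areas, in m^2.
#'
#' @param patches A patch table from [label_patches()].
#' @param class_l Integer class code.
#' @return Area in m^2. A class absent from the landscape yields `0` with a
#'   warning (a class may legitimately be missing from one landscape).
#' @export
class_area <- function(patches, class_l) {
  stopifnot(inherits(patches, "patch_set"))
  rows <- patches$class == class_l
  if (!any(rows)) {
    warning("class ", class_l, " absent from landscape; class area 0",
            call. = FALSE)
    return(0)
  }
  sum(patches$area[rows])
}

# Interior 4-neighbor face count separating values a and b (either order).
interior_faces <- function(grid, a, b) {
  count <- 0L
  nc <- ncol(grid)
  nr <- nrow(grid)
  if (nc > 1L) {
    l <- grid[, -nc, drop = FALSE]
    r <- grid[, -1L, drop = FALSE]
    count <- count + sum((l == a & r == b) | (l == b & r == a))
  }
  if (nr > 1L) {
    u <- grid[-nr, , drop = FALSE]
    d <- grid[-1L, , drop = FALSE]
    count <- count + sum((u == a & d == b) | (u == b & d == a))
  }
  count
}

# Grid-boundary face count of cells with value a.
boundary_faces <- function(grid, a) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  sum(grid[1L, ] == a) + sum(grid[nr, ] == a) +
    sum(grid[, 1L] == a) + sum(grid[, nc] == a)
}

#' Edge length between land-use classes
#'
#' Length (m) of the shared edge between two classes: the number of
#' 4-neighbor cell faces separating them, times the cell size. With
#' `class_m = NULL` and `include_boundary = TRUE` the class-`l` total is
#' returned instead: all faces of class `l` against other classes,
#' background, and the grid boundary (the boundary rule used by
#' [edge_density()]).
#'
#' @param raster A [cat_raster()].
#' @param class_l Integer class code.
#' @param class_m Second class code (`0` = background), or `NULL` for the
#'   class-`l` total.
#' @param include_boundary Count grid-boundary and background faces of class
#'   `l` (only meaningful when `class_m` is `NULL`).
#' @return Edge length in meters.
#' @export
edge_sum <- function(raster, class_l, class_m = NULL, include_boundary = FALSE) {
  stopifnot(inherits(raster, "cat_raster"))
  g <- raster$grid
  if (!is.null(class_m)) {
    if (class_l == class_m) {
      stop("`class_l` and `class_m` must differ (es_ll = 0 by definition)",
           call. = FALSE)
    }
    return(interior_faces(g, class_l, class_m) * raster$cell_size)
  }
  faces <- exposed_faces(g)
  total_incl <- sum(faces[g == class_l], na.rm = TRUE)
  if (include_boundary) {
    total_incl * raster$cell_size
  } else {
    # interior faces against other non-background classes only
    (total_incl - interior_faces(g, class_l, 0L) - boundary_faces(g, class_l)) *
      raster$cell_size
  }
}

#' Patch cohesion index
#'
#' Physical connectedness of a class's patches on a 0-100 scale:
#' \deqn{coh_l = \left[1 - \frac{\sum_p P_{p,l}}{\sum_p P_{p,l}\sqrt{c_{p,l}}}\right]
#'       \left[1 - \frac{1}{\sqrt{C_r}}\right]^{-1} \times 100}
#' where \eqn{P_{p,l}} is the patch perimeter in cell faces, \eqn{c_{p,l}}
#' the patch area in cells, and \eqn{C_r} the total number of grid cells
#' (background included). A class filling the whole grid scores 100; a
#' single-cell patch scores 0.
#'
#' @param patches A patch table from [label_patches()].
#' @param class_l Integer class code.
#' @return Index in `[0, 100]`, or `NA` when the class is absent or the
#'   grid has a single cell (the normalizer is undefined).
#' @export
cohesion <- function(patches, class_l) {
  stopifnot(inherits(patches, "patch_set"))
  n_cells <- attr(patches, "n_cells")
  rows <- patches$class == class_l
  if (!any(rows) || n_cells == 1L) {
    return(NA_real_)
  }
  p <- patches$perimeter_cells[rows]
  c_cells <- patches$cell_count[rows]
  bracket1 <- 1 - sum(p) / sum(p * sqrt(c_cells))
  bracket1 / (1 - 1 / sqrt(n_cells)) * 100
}

#' Edge density
#'
#' Total edge length involving a class per unit landscape area, in meters
#' per hectare: \eqn{ed_l = \sum_m es_{l,m} / A \times 10000}. By default
#' the landscape boundary and background segments of the class are included
#' in the edge total, matching the convention that the edge sum "includes
#' landscape boundary and background edge segments"; set
#' `include_boundary = FALSE` for interior class-class edges only.
#'
#' @param raster A [cat_raster()].
#' @param class_l Integer class code.
#' @param include_boundary Include grid-boundary and background faces of the
#'   class (default `TRUE`).
#' @return Edge density in m/ha (>= 0).
#' @export
edge_density <- function(raster, class_l, include_boundary = TRUE) {
  stopifnot(inherits(raster, "cat_raster"))
  a_total <- length(raster$grid) * raster$cell_size^2
  edge_sum(raster, class_l, NULL, include_boundary = include_boundary) /
    a_total * 10000
}

#' Largest patch index
#'
#' Area of the single largest patch (any class) as a percentage of the
#' total landscape area \eqn{A} (background included):
#' \eqn{LPI = \max_p(a_{p,l}) / A \times 100}.
#'
#' @param patches A patch table from [label_patches()].
#' @return Percent in `(0, 100]`, or `NA` for an empty landscape.
#' @export
largest_patch_index <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  if (nrow(patches) == 0L) {
    return(NA_real_)
  }
  a_total <- attr(patches, "n_cells") * attr(patches, "cell_size")^2
  max(patches$area) / a_total * 100
}

#' Compute all landscape metrics for one raster
#'
#' Evaluates the five class-level metrics — class area (`ca`, m^2), patch
#' cohesion (`coh`), edge density (`ed`, m/ha), pairwise edge length (`es`,
#' m) and the landscape-level largest patch index (`lpi`, percent) — and
#' returns them in long format.
#'
#' @param raster A [cat_raster()].
#' @param class_map Optional named integer vector mapping class names to
#'   codes, e.g. `c(Forest = 1, Wetland = 2, Builtup = 3)`. Defaults to the
#'   codes present, named by their code. Classes in the map but absent from
#'   the raster get `ca = 0`, `ed = 0` and `NA` cohesion.
#' @param connectivity Patch-membership neighborhood, `4` or `8`.
#' @param include_boundary Boundary rule for edge density (see
#'   [edge_density()]).
#' @param es_pairs Optional list of 2-vectors of class names for which to
#'   report pairwise edge sums; default all unordered pairs in `class_map`.
#' @return A tibble with columns `metric`, `class` (name, or `"A.B"` for a
#'   pair, `NA` for `lpi`) and `value`.
#' @export
compute_metrics <- function(raster, class_map = NULL, connectivity = 8L,
                            include_boundary = TRUE, es_pairs = NULL) {
  stopifnot(inherits(raster, "cat_raster"))
  if (is.null(class_map)) {
    class_map <- stats::setNames(raster$class_codes,
                                 as.character(raster$class_codes))
  }
  if (is.null(names(class_map)) || any(!nzchar(names(class_map)))) {
    stop("`class_map` must be a named vector of class codes", call. = FALSE)
  }
  patches <- label_patches(raster, connectivity)
  present <- names(class_map)[class_map %in% patches$class]

  per_class <- purrr::map_dfr(names(class_map), function(nm) {
    code <- class_map[[nm]]
    ca <- if (nm %in% present) class_area(patches, code) else 0
    tibble::tibble(
      metric = c("ca", "coh", "ed"),
      class = nm,
      value = c(
        ca,
        cohesion(patches, code),
        edge_density(raster, code, include_boundary = include_boundary)
      )
    )
  })

  if (is.null(es_pairs)) {
    nms <- names(class_map)
    es_pairs <- if (length(nms) >= 2L) {
      utils::combn(nms, 2L, simplify = FALSE)
    } else {
      list()
    }
  }
  es_rows <- purrr::map_dfr(es_pairs, function(pair) {
    tibble::tibble(
      metric = "es",
      class = paste(pair, collapse = "."),
      value = edge_sum(raster, class_map[[pair[1]]], class_map[[pair[2]]])
    )
  })

  dplyr::bind_rows(
    per_class,
    es_rows,
    tibble::tibble(metric = "lpi", class = NA_character_,
                   value = largest_patch_index(patches))
  )
}

#' Landscape metrics for a set of rasters, in modelling (wide) layout
#'
#' Runs [compute_metrics()] on every raster and pivots the result into one
#' row per landscape with columns named after the field's predictor
#' convention: `CA_<class>`, `Coh_<class>`, `ED_<class>`,
#' `ES_<classA>.<classB>`, and `LPI`.
#'
#' @param rasters Named list of [cat_raster()] objects; names are the
#'   landscape ids.
#' @param ... Passed on to [compute_metrics()] (`class_map`, `connectivity`,
#'   `include_boundary`, `es_pairs`).
#' @return A tibble with a `landscape_id` column and one metric column per
#'   (metric, class) combination.
#' @export
metrics_table <- function(rasters, ...) {
  if (is.null(names(rasters)) || any(!nzchar(names(rasters)))) {
    names(rasters) <- paste0("L", seq_along(rasters))
  }
  long <- purrr::imap_dfr(rasters, function(r, id) {
    dplyr::mutate(compute_metrics(r, ...), landscape_id = id, .before = 1L)
  })
  prefix <- c(ca = "CA", coh = "Coh", ed = "ED", es = "ES", lpi = "LPI")
  long <- dplyr::mutate(
    long,
    column = dplyr::if_else(
      is.na(.data$class),
      prefix[.data$metric],
      paste(prefix[.data$metric], .data$class, sep = "_")
    )
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "landscape_id", "column", "value"),
    names_from = "column", values_from = "value"
  )
  wide
}
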