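#' Categorical land-use raster
#'
#' Constructs a categorical raster: an integer-coded grid of land-use classes
#' with a known (square) cell size in meters. Code `0` is reserved for
#' background / nodata; every other integer code is a land-use class.
#'
#' @param grid Integer matrix of class codes (`0` = background). Rows run
#'   north to south, columns west to east, as in an ESRI ASCII grid.
#' @param cell_size Side length of one cell in meters (> 0).
#' @return An object of class `cat_raster`: a list with elements `grid`
#'   (integer matrix), `cell_size` (meters), and `class_codes` (sorted
#'   integer vector of non-background codes present).
#' @examples
#' r <- cat_raster(matrix(c(1, 1, 2, 2), 2, 2), cell_size = 30)
#' r$class_codes
#' @export
cat_raster <- function(grid, cell_size) {
  if (!is.matrix(grid) || nrow(grid) < 1 || ncol(grid) < 1) {
    stop("`grid` must be a matrix with at least one cell", call. = FALSE)
  }
  if (anyNA(grid)) {
    grid[is.na(grid)] <- 0L
  }
  if (!is.numeric(grid) || any(grid != round(grid))) {
    stop("`grid` must contain integer class codes", call. = FALSE)
  }
  if (any(grid < 0)) {
    stop("class codes must be non-negative (0 = background)", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive length in meters", call. = FALSE)
  }
  storage.mode(grid) <- "integer"
  codes <- sort(unique(as.integer(grid)))
  structure(
    list(
      grid = grid,
      cell_size = as.numeric(cell_size),
      class_codes = codes[codes != 0L]
    ),
    class = "cat_raster"
  )
}

#' @export
print.cat_raster <- function(x, ...) {
  cat(sprintf(
    "<cat_raster> %d x %d cells, cell size %g m, classes: %s\n",
    nrow(x$grid), ncol(x$grid), x$cell_size,
    if (length(x$class_codes)) paste(x$class_codes, collapse = ", ") else "(none)"
  ))
  invisible(x)
}

#' Read a categorical raster from file
#'
#' Reads a single-band integer raster from an ESRI ASCII grid
#' (`ncols`/`nrows`/`cellsize` header) or a plain TIFF. Nodata values are
#' mapped to the background code `0`.
#'
#' ASCII grids carry their own cell size (`cellsize` header; `dx`/`dy`
#' variants must be equal, i.e. square cells). TIFF files carry no
#' geotransform, so `cell_size` is required for them. Non-integral band
#' values are rejected: land-use rasters are categorical.
#'
#' @param path Path to a `.asc`/`.txt` ESRI ASCII grid or a `.tif`/`.tiff`
#'   file.
#' @param cell_size Optional cell size override in meters. Mandatory for
#'   TIFF input.
#' @return A [cat_raster()].
#' @examples
#' demo <- system.file("extdata", "demo_landscape.asc", package = "richscape")
#' read_raster(demo)
#' @export
read_raster <- function(path, cell_size = NULL) {
  if (!file.exists(path)) {
    stop("raster file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    read_raster_tiff(path, cell_size)
  } else {
    read_ascii_grid(path, cell_size)
  }
}

read_ascii_grid <- function(path, cell_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows")) {
    if (is.null(hdr[[key]])) {
      stop("not an ESRI ASCII grid (missing ", key, " header): ", path,
           call. = FALSE)
    }
  }
  if (is.null(cell_size)) {
    if (!is.null(hdr$cellsize)) {
      cell_size <- hdr$cellsize
    } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
      if (hdr$dx != hdr$dy) {
        stop("non-square cells (dx != dy); supply `cell_size` to override",
             call. = FALSE)
      }
      cell_size <- hdr$dx
    } else {
      stop("grid has no cellsize header; supply `cell_size`", call. = FALSE)
    }
  }
  vals <- scan(text = paste(lines[seq.int(i, length(lines))], collapse = "\n"),
               quiet = TRUE)
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  if (length(vals) != ncols * nrows) {
    stop(sprintf("expected %d values, found %d in %s", ncols * nrows,
                 length(vals), path), call. = FALSE)
  }
  if (any(vals != round(vals))) {
    stop("non-integer band values: categorical rasters must be integer coded",
         call. = FALSE)
  }
  if (!is.null(hdr$nodata_value)) {
    vals[vals == hdr$nodata_value] <- 0
  }
  vals[vals < 0] <- 0
  grid <- matrix(as.integer(vals), nrow = nrows, ncol = ncols, byrow = TRUE)
  cat_raster(grid, cell_size)
}

read_raster_tiff <- function(path, cell_size) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF requires the `tiff` package", call. = FALSE)
  }
  if (is.null(cell_size)) {
    stop("TIFF input carries no cell size; supply `cell_size`", call. = FALSE)
  }
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) {
      stop("multi-band TIFF not supported; supply a single-band raster",
           call. = FALSE)
    }
    img <- img[, , 1L]
  }
  if (any(img != round(img))) {
    stop("non-integer band values: categorical rasters must be integer coded",
         call. = FALSE)
  }
  img[img < 0] <- 0
  cat_raster(matrix(as.integer(img), nrow(img), ncol(img)), cell_size)
}

#' Write a categorical raster as an ESRI ASCII grid
#'
#' @param raster A [cat_raster()].
#' @param path Output file path.
#' @param nodata Code written for background cells (default `-9999`;
#'   background cells hold `0` internally).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999L) {
  stopifnot(inherits(raster, "cat_raster"))
  g <- raster$grid
  g[g == 0L] <- as.integer(nodata)
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %g", raster$cell_size),
    sprintf("NODATA_value %d", as.integer(nodata))
  )
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Per-cell count of exposed 4-neighbor faces: faces toward a different value
# (class, background) or the grid boundary. Background cells get NA.
exposed_faces <- function(grid) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- grid
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  up    <- pad[1:nr, 2:(nc + 1L), drop = FALSE]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L), drop = FALSE]
  left  <- pad[2:(nr + 1L), 1:nc, drop = FALSE]
  right <- pad[2:(nr + 1L), 3:(nc + 2L), drop = FALSE]
  faces <- (core != up) + (core != down) + (core != left) + (core != right)
  faces[grid == 0L] <- NA_integer_
  faces
}

#' Decompose a raster into patches
#'
#' Labels the connected components (patches) of every land-use class and
#' returns per-patch geometry. Patch membership uses the chosen neighborhood
#' (8-connectivity by default, the FRAGSTATS convention); perimeter faces are
#' always counted on the 4-neighborhood, since a perimeter is made of cell
#' faces, not corners. A face counts toward the perimeter when it touches a
#' different class, background, or the grid boundary.
#'
#' @param raster A [cat_raster()].
#' @param connectivity Neighborhood for patch membership: `4` or `8`.
#' @return A tibble with one row per patch: `class`, `patch` (id within
#'   class), `cell_count`, `area` (m^2), `perimeter_cells` (number of cell
#'   faces). Attributes `cell_size`, `n_cells` (total grid cells, incl.
#'   background) and `connectivity` are attached for downstream metrics.
#' @examples
#' r <- cat_raster(matrix(1L, 2, 2), 30)
#' label_patches(r)   # one patch, 4 cells, 8 perimeter faces
#' @export
label_patches <- function(raster, connectivity = 8L) {
  stopifnot(inherits(raster, "cat_raster"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  g <- raster$grid
  nr <- nrow(g)
  nc <- ncol(g)
  n <- nr * nc

  idx <- function(i, j) (j - 1L) * nr + i   # column-major cell id

  edges <- list()
  # horizontal neighbors (same row, adjacent columns)
  if (nc > 1L) {
    a <- g[, -nc, drop = FALSE]
    b <- g[, -1L, drop = FALSE]
    ok <- a == b & a != 0L
    if (any(ok)) {
      ij <- which(ok, arr.ind = TRUE)
      edges[[length(edges) + 1L]] <-
        cbind(idx(ij[, 1L], ij[, 2L]), idx(ij[, 1L], ij[, 2L] + 1L))
    }
  }
  # vertical neighbors
  if (nr > 1L) {
    a <- g[-nr, , drop = FALSE]
    b <- g[-1L, , drop = FALSE]
    ok <- a == b & a != 0L
    if (any(ok)) {
      ij <- which(ok, arr.ind = TRUE)
      edges[[length(edges) + 1L]] <-
        cbind(idx(ij[, 1L], ij[, 2L]), idx(ij[, 1L] + 1L, ij[, 2L]))
    }
  }
  if (connectivity == 8L && nr > 1L && nc > 1L) {
    a <- g[-nr, -nc, drop = FALSE]    # down-right diagonal
    b <- g[-1L, -1L, drop = FALSE]
    ok <- a == b & a != 0L
    if (any(ok)) {
      ij <- which(ok, arr.ind = TRUE)
      edges[[length(edges) + 1L]] <-
        cbind(idx(ij[, 1L], ij[, 2L]), idx(ij[, 1L] + 1L, ij[, 2L] + 1L))
    }
    a <- g[-1L, -nc, drop = FALSE]    # up-right diagonal
    b <- g[-nr, -1L, drop = FALSE]
    ok <- a == b & a != 0L
    if (any(ok)) {
      ij <- which(ok, arr.ind = TRUE)
      edges[[length(edges) + 1L]] <-
        cbind(idx(ij[, 1L] + 1L, ij[, 2L]), idx(ij[, 1L], ij[, 2L] + 1L))
    }
  }

  nonbg <- which(g != 0L)
  if (length(nonbg) == 0L) {
    out <- tibble::tibble(
      class = integer(), patch = integer(), cell_count = integer(),
      area = numeric(), perimeter_cells = integer()
    )
  } else {
    graph <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (length(edges)) {
      em <- do.call(rbind, edges)
      graph <- igraph::add_edges(graph, t(em))
    }
    membership <- igraph::components(graph)$membership
    faces <- exposed_faces(g)
    comp <- membership[nonbg]
    cls <- g[nonbg]
    per <- faces[nonbg]
    agg <- rowsum(cbind(count = rep(1L, length(nonbg)), perim = per), comp)
    comp_ids <- as.integer(rownames(agg))
    comp_class <- cls[match(comp_ids, comp)]
    ord <- order(comp_class, comp_ids)
    out <- tibble::tibble(
      class = comp_class[ord],
      cell_count = as.integer(agg[ord, "count"]),
      area = agg[ord, "count"] * raster$cell_size^2,
      perimeter_cells = as.integer(agg[ord, "perim"])
    )
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$class),
      patch = dplyr::row_number(), .after = "class"
    )
    out <- dplyr::ungroup(out)
  }
  structure(
    out,
    cell_size = raster$cell_size,
    n_cells = n,
    connectivity = connectivity,
    class = c("patch_set", class(out))
  )
}
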