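# Independent brute-force oracles: plain-loop flood fill and exhaustive
# face enumeration, sharing no code with the package's vectorized /
# graph-based implementations.

oracle_label <- function(grid, connectivity = 8L) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  nbrs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L) {
    nbrs <- c(nbrs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  next_id <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (grid[i, j] != 0L && lab[i, j] == 0L) {
        next_id <- next_id + 1L
        queue <- list(c(i, j))
        lab[i, j] <- next_id
        while (length(queue)) {
          cell <- queue[[1L]]
          queue <- queue[-1L]
          for (d in nbrs) {
            ii <- cell[1L] + d[1L]
            jj <- cell[2L] + d[2L]
            if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
                grid[ii, jj] == grid[cell[1L], cell[2L]] &&
                lab[ii, jj] == 0L) {
              lab[ii, jj] <- next_id
              queue[[length(queue) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# per-cell exposed 4-neighbor faces, counted one cell at a time
oracle_cell_faces <- function(grid, i, j) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  faces <- 0L
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ii <- i + d[1L]
    jj <- j + d[2L]
    if (ii < 1L || ii > nr || jj < 1L || jj > nc ||
        grid[ii, jj] != grid[i, j]) {
      faces <- faces + 1L
    }
  }
  faces
}

oracle_patches <- function(grid, cell_size, connectivity = 8L) {
  lab <- oracle_label(grid, connectivity)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  do.call(rbind, lapply(ids, function(id) {
    cells <- which(lab == id, arr.ind = TRUE)
    perim <- 0L
    for (r in seq_len(nrow(cells))) {
      perim <- perim + oracle_cell_faces(grid, cells[r, 1L], cells[r, 2L])
    }
    data.frame(
      class = grid[cells[1L, 1L], cells[1L, 2L]],
      cell_count = nrow(cells),
      area = nrow(cells) * cell_size^2,
      perimeter_cells = perim
    )
  }))
}

# interior faces between values a and b, enumerated face by face
oracle_interior_faces <- function(grid, a, b) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  count <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (j < nc) {
        pair <- c(grid[i, j], grid[i, j + 1L])
        if (all(sort(pair) == sort(c(a, b))) && pair[1L] != pair[2L]) {
          count <- count + 1L
        }
      }
      if (i < nr) {
        pair <- c(grid[i, j], grid[i + 1L, j])
        if (all(sort(pair) == sort(c(a, b))) && pair[1L] != pair[2L]) {
          count <- count + 1L
        }
      }
    }
  }
  count
}

oracle_boundary_faces <- function(grid, a) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  count <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (grid[i, j] == a) {
        if (i == 1L) count <- count + 1L
        if (i == nr) count <- count + 1L
        if (j == 1L) count <- count + 1L
        if (j == nc) count <- count + 1L
      }
    }
  }
  count
}

oracle_class_area <- function(grid, l, cell_size) {
  sum(grid == l) * cell_size^2
}

oracle_cohesion <- function(grid, l, cell_size, connectivity = 8L) {
  if (!any(grid == l) || length(grid) == 1L) return(NA_real_)
  p <- oracle_patches(grid, cell_size, connectivity)
  p <- p[p$class == l, , drop = FALSE]
  b1 <- 1 - sum(p$perimeter_cells) /
    sum(p$perimeter_cells * sqrt(p$cell_count))
  b1 / (1 - 1 / sqrt(length(grid))) * 100
}

oracle_edge_density <- function(grid, l, cell_size, include_boundary = TRUE) {
  classes <- setdiff(sort(unique(as.vector(grid))), c(0L, l))
  faces <- sum(vapply(classes, function(m) oracle_interior_faces(grid, l, m),
                      integer(1)))
  if (include_boundary) {
    faces <- faces + oracle_interior_faces(grid, l, 0L) +
      oracle_boundary_faces(grid, l)
  }
  faces * cell_size / (length(grid) * cell_size^2) * 10000
}

oracle_lpi <- function(grid, cell_size, connectivity = 8L) {
  if (!any(grid != 0L)) return(NA_real_)
  p <- oracle_patches(grid, cell_size, connectivity)
  max(p$area) / (length(grid) * cell_size^2) * 100
}

# random small grid for property tests
random_grid <- function(nr, nc, n_classes = 3L, p_background = 0.2) {
  codes <- c(0L, seq_len(n_classes))
  probs <- c(p_background, rep((1 - p_background) / n_classes, n_classes))
  matrix(sample(codes, nr * nc, replace = TRUE, prob = probs), nr, nc)
}
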