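#' Reduced sensor layouts by recursive uniform sampling
#'
#' Generates the level-`k` sensor layout in normalised mat coordinates
#' \eqn{[0,1]^2} (`u` across columns, `v` across rows). Level 1 is the 3x3
#' lattice plus the four quadrant centres (13 sensors: one per corner, one at
#' the middle of each side, one per quadrant centre, one at the mat centre).
#' Each subsequent level adds the midpoints of the hypotenuses of the right
#' triangles formed by adjacent points, so the family alternates between
#' quincunx lattices (odd levels) and full square grids (even levels) and each
#' level's point set nests inside the next. Sensor counts for levels 1..5 are
#' 13, 25, 41, 81 and 145.
#'
#' @param level Integer >= 1.
#' @return An object of class `sensor_layout`: list with `level` and `points`
#'   (data frame of `u`, `v`, ordered by `v` then `u`).
#' @examples
#' nrow(generate_layout(1)$points)  # 13
#' @export
generate_layout <- function(level) {
  level <- as.integer(level)
  if (level < 1L) stop("layout level must be >= 1", call. = FALSE)
  if (level %% 2L == 1L) {
    n <- 2L^((level + 1L) %/% 2L) + 1L      # quincunx: n^2 grid + (n-1)^2 centres
    step <- 1 / (n - 1)
    grid <- expand.grid(u = (seq_len(n) - 1) * step, v = (seq_len(n) - 1) * step)
    cent <- expand.grid(u = (seq_len(n - 1) - 0.5) * step,
                        v = (seq_len(n - 1) - 0.5) * step)
    pts <- rbind(grid, cent)
  } else {
    n_prev <- 2L^(level %/% 2L) + 1L        # previous odd level's grid order
    n <- 2L * n_prev - 1L                   # full square grid
    step <- 1 / (n - 1)
    pts <- expand.grid(u = (seq_len(n) - 1) * step, v = (seq_len(n) - 1) * step)
  }
  pts <- pts[order(pts$v, pts$u), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(level = level, points = pts), class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> level %d: %d sensors\n", x$level, nrow(x$points)))
  invisible(x)
}

#' Closed-form sensor count of a layout level
#'
#' Odd levels `k` contain \eqn{n^2 + (n-1)^2} points with
#' \eqn{n = 2^{(k+1)/2} + 1}; even levels contain \eqn{(2n'-1)^2} points with
#' `n'` the previous odd level's `n`. Levels 1..5 give 13, 25, 41, 81, 145.
#'
#' @param level Integer >= 1 (vectorised).
#' @return Integer sensor counts.
#' @export
layout_size <- function(level) {
  level <- as.integer(level)
  if (any(level < 1L)) stop("layout level must be >= 1", call. = FALSE)
  vapply(level, function(k) {
    if (k %% 2L == 1L) {
      n <- as.integer(2^((k + 1L) %/% 2L)) + 1L
      n * n + (n - 1L) * (n - 1L)
    } else {
      n_prev <- as.integer(2^(k %/% 2L)) + 1L
      (2L * n_prev - 1L) * (2L * n_prev - 1L)
    }
  }, integer(1))
}

#' A layout that samples every cell of a geometry
#'
#' Utility for identity checks: one sensor at every cell centre, so sampling
#' followed by reconstruction is the identity map.
#'
#' @param geometry A [mat_geometry()].
#' @return A `sensor_layout` (level `NA`).
#' @export
full_resolution_layout <- function(geometry) {
  pts <- expand.grid(u = (seq_len(geometry$n_cols) - 1) / (geometry$n_cols - 1),
                     v = (seq_len(geometry$n_rows) - 1) / (geometry$n_rows - 1))
  pts <- pts[order(pts$v, pts$u), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(level = NA_integer_, points = pts), class = "sensor_layout")
}

# Physical sensor positions (cm) of a layout on a geometry: u spans the full
# column extent, v the row extent, matching the cell-centre coordinate frame.
layout_positions <- function(layout, geometry) {
  cbind(x = layout$points$u * (geometry$n_cols - 1) * geometry$cell_size,
        y = layout$points$v * (geometry$n_rows - 1) * geometry$cell_size)
}

#' Snap layout points to their nearest cells
#'
#' Each sensor point maps to the cell whose centre minimises the Euclidean
#' distance in physical coordinates. Exact ties are broken towards the
#' lexicographically smallest (row, col).
#'
#' @param layout A `sensor_layout`.
#' @param geometry A [mat_geometry()].
#' @return Data frame with columns `u`, `v`, `row`, `col` (1-based cell
#'   indices) and `cell` (column-major linear index).
#' @export
snap_to_cells <- function(layout, geometry) {
  stopifnot(inherits(layout, "sensor_layout"), inherits(geometry, "mat_geometry"))
  r <- layout$points$v * (geometry$n_rows - 1)   # 0-based fractional row
  c_ <- layout$points$u * (geometry$n_cols - 1)
  row <- pmin(pmax(ceiling(r - 0.5), 0L), geometry$n_rows - 1L) + 1L
  col <- pmin(pmax(ceiling(c_ - 0.5), 0L), geometry$n_cols - 1L) + 1L
  data.frame(u = layout$points$u, v = layout$points$v,
             row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1L) * geometry$n_rows + row))
}

#' Sample a full-resolution frame at the layout's sensors
#'
#' Reads, for every layout point, the pressure of the nearest cell
#' ("closest-cell" rule), producing the sparse measurement a reduced-resolution
#' mat would deliver.
#'
#' @param frame A [pressure_frame()].
#' @param layout A `sensor_layout`.
#' @return An object of class `sparse_sample`: list with `layout`, `geometry`,
#'   `cells` (the snap table) and `values`.
#' @export
sample_frame <- function(frame, layout) {
  stopifnot(inherits(frame, "pressure_frame"))
  cells <- snap_to_cells(layout, frame$geometry)
  structure(list(layout = layout, geometry = frame$geometry, cells = cells,
                 values = as.vector(frame$values)[cells$cell]),
            class = "sparse_sample")
}

#' Inverse-distance-weighting reconstruction operator
#'
#' Precomputes the sparse linear operator `W` such that the reconstructed
#' (vectorised) frame is `W %*% sampled_values`. Each cell is a normalised
#' inverse-distance-power weighted mean of its `n_neighbors` nearest sensor
#' points; a cell within `eps` of a sensor copies that sensor's value exactly.
#' Because rows are convex weights, reconstructed values always lie within the
#' range of the sampled values.
#'
#' @param layout A `sensor_layout`.
#' @param geometry A [mat_geometry()].
#' @param power IDW distance exponent (> 0), default 2.
#' @param n_neighbors Number of nearest sensors used per cell, default 4.
#' @param eps Exact-hit tolerance in cm.
#' @return A sparse `n_cells` x `n_sensors` matrix.
#' @export
idw_operator <- function(layout, geometry, power = 2, n_neighbors = 4L,
                         eps = 1e-12) {
  stopifnot(inherits(layout, "sensor_layout"), inherits(geometry, "mat_geometry"))
  if (!is.numeric(power) || power <= 0) {
    stop("IDW power must be positive", call. = FALSE)
  }
  np <- nrow(layout$points)
  if (np == 0L) stop("empty sensor sample", call. = FALSE)
  k <- min(as.integer(n_neighbors), np)
  pos <- layout_positions(layout, geometry)
  cc <- cell_centers(geometry)
  cx <- as.vector(cc$X); cy <- as.vector(cc$Y)
  nc <- n_cells(geometry)
  # squared distances cells x sensors
  d2 <- outer(cx, pos[, "x"], `-`)^2 + outer(cy, pos[, "y"], `-`)^2
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (cell in seq_len(nc)) {
    d <- d2[cell, ]
    hit <- which(d < eps^2)
    if (length(hit) > 0L) {
      ii <- c(ii, cell); jj <- c(jj, hit[1L]); ww <- c(ww, 1)
      next
    }
    nb <- order(d)[seq_len(k)]
    w <- d[nb]^(-power / 2)            # d2 is squared distance
    w <- w / sum(w)
    ii <- c(ii, rep(cell, k)); jj <- c(jj, nb); ww <- c(ww, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nc, np))
}

#' Reconstruct a full-resolution frame from a sparse sample by IDW
#'
#' @param sample A `sparse_sample` from [sample_frame()].
#' @param geometry Target [mat_geometry()] (defaults to the sample's).
#' @inheritParams idw_operator
#' @return A [pressure_frame()] of the full geometry.
#' @export
idw_reconstruct <- function(sample, geometry = sample$geometry, power = 2,
                            n_neighbors = 4L, eps = 1e-12) {
  stopifnot(inherits(sample, "sparse_sample"))
  if (length(sample$values) == 0L) stop("empty sensor sample", call. = FALSE)
  W <- idw_operator(sample$layout, geometry, power = power,
                    n_neighbors = n_neighbors, eps = eps)
  v <- as.vector(W %*% sample$values)
  pressure_frame(matrix(v, geometry$n_rows, geometry$n_cols), geometry)
}

#' Reconstruction error between two frames
#'
#' Elementwise root-mean-square error and maximum absolute deviation.
#'
#' @param original,reconstructed [pressure_frame()]s on the same geometry.
#' @return Named vector `c(rmse =, max_abs =)`.
#' @export
reconstruction_error <- function(original, reconstructed) {
  stopifnot(inherits(original, "pressure_frame"),
            inherits(reconstructed, "pressure_frame"))
  if (original$geometry$n_rows != reconstructed$geometry$n_rows ||
      original$geometry$n_cols != reconstructed$geometry$n_cols) {
    stop("frames have mismatching geometries", call. = FALSE)
  }
  d <- original$values - reconstructed$values
  c(rmse = sqrt(mean(d^2)), max_abs = max(abs(d)))
}

#' Export a layout (with snapped cells) as delimited text
#'
#' @param layout A `sensor_layout`.
#' @param geometry A [mat_geometry()] used for snapping.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, geometry, path) {
  snap <- snap_to_cells(layout, geometry)
  out <- data.frame(index = seq_len(nrow(snap)), u = snap$u, v = snap$v,
                    snapped_row = snap$row, snapped_col = snap$col)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
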