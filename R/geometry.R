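#' Mat geometry
#'
#' Describes the sensing grid of one pressure mat. The reference hardware has
#' 42 rows by 44 columns of effective square cells of 1.27 cm for both the
#' backrest and the seat pan.
#'
#' The coordinate convention used throughout the package: row 1 is the top of
#' the backrest / the front of the seat pan; columns run left to right from
#' the sitter's perspective. Physical coordinates are in cm, x along columns,
#' y along rows, with the origin at the centre of the top-left cell.
#'
#' @param side `"backrest"` or `"seatpan"`.
#' @param n_rows,n_cols Number of cell rows/columns (each at least 2).
#' @param cell_size Cell edge length in cm (cells are square).
#' @return An object of class `mat_geometry`.
#' @examples
#' mat_geometry("backrest")
#' @export
mat_geometry <- function(side = c("backrest", "seatpan"),
                         n_rows = 42L, n_cols = 44L, cell_size = 1.27) {
  side <- match.arg(side)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 2L) {
    stop("mat geometry needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a single positive length in cm", call. = FALSE)
  }
  structure(
    list(side = side, n_rows = n_rows, n_cols = n_cols, cell_size = cell_size),
    class = "mat_geometry"
  )
}

#' @export
print.mat_geometry <- function(x, ...) {
  cat(sprintf("<mat_geometry> %s: %d x %d cells, %.2f cm each\n",
              x$side, x$n_rows, x$n_cols, x$cell_size))
  invisible(x)
}

n_cells <- function(geometry) geometry$n_rows * geometry$n_cols

#' Physical coordinates of cell centres
#'
#' @param geometry A [mat_geometry()].
#' @return A list with vectors `x` (length `n_cols`) and `y` (length `n_rows`),
#'   in cm, plus matrices `X`, `Y` giving per-cell centre coordinates.
#' @keywords internal
cell_centers <- function(geometry) {
  x <- (seq_len(geometry$n_cols) - 1) * geometry$cell_size
  y <- (seq_len(geometry$n_rows) - 1) * geometry$cell_size
  list(
    x = x, y = y,
    X = matrix(rep(x, each = geometry$n_rows), geometry$n_rows, geometry$n_cols),
    Y = matrix(rep(y, times = geometry$n_cols), geometry$n_rows, geometry$n_cols)
  )
}

#' Pressure frame
#'
#' One mat's pressure readings at one time instant: a non-negative matrix
#' whose shape matches the mat geometry, plus identifying metadata.
#'
#' @param values Numeric matrix of non-negative pressures, `n_rows` by
#'   `n_cols` as given by `geometry`.
#' @param geometry A [mat_geometry()].
#' @param frame_index Integer frame number within a recording.
#' @param subject_id,task_id Identifiers carried through the pipeline.
#' @return An object of class `pressure_frame`.
#' @examples
#' g <- mat_geometry("seatpan", 4, 4, 1)
#' pressure_frame(matrix(1, 4, 4), g)
#' @export
pressure_frame <- function(values, geometry, frame_index = 1L,
                           subject_id = NA_character_, task_id = NA_character_) {
  stopifnot(inherits(geometry, "mat_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols) {
    stop(sprintf("frame shape %d x %d does not match geometry %d x %d",
                 nrow(values), ncol(values), geometry$n_rows, geometry$n_cols),
         call. = FALSE)
  }
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative pressure at cell (row %d, col %d)",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  structure(
    list(geometry = geometry, values = values,
         frame_index = as.integer(frame_index),
         subject_id = as.character(subject_id),
         task_id = as.character(task_id)),
    class = "pressure_frame"
  )
}

#' @export
print.pressure_frame <- function(x, ...) {
  cat(sprintf("<pressure_frame> %s frame %d (subject %s, task %s): total %.3g, peak %.3g\n",
              x$geometry$side, x$frame_index, x$subject_id, x$task_id,
              sum(x$values), max(x$values)))
  invisible(x)
}

#' Normalise a frame by its peak pressure
#'
#' Divides all cells by the frame maximum so the peak becomes 1. This mirrors
#' how pressure maps are usually displayed; it is a visualisation aid only and
#' is never applied before feature computation (features are unit-covariant).
#'
#' @param frame A [pressure_frame()] with at least one positive cell.
#' @return A `pressure_frame` with maximum value 1.
#' @export
normalize_by_peak <- function(frame) {
  stopifnot(inherits(frame, "pressure_frame"))
  peak <- max(frame$values)
  if (peak <= 0) {
    stop("cannot normalize an all-zero frame (empty contact)", call. = FALSE)
  }
  frame$values <- frame$values / peak
  frame
}

#' Read and write pressure frames as plain-text grids
#'
#' The on-disk format is one matrix row per line of whitespace-separated
#' decimal values, optionally preceded by `#`-prefixed header lines of the
#' form `# key: value` carrying side/subject/task/frame metadata.
#'
#' @param path File path.
#' @param geometry Expected [mat_geometry()]; a shape mismatch is an error.
#' @return `read_pressure_frame()` returns a [pressure_frame()];
#'   `write_pressure_frame()` invisibly returns `path`.
#' @export
read_pressure_frame <- function(path, geometry) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  meta <- parse_frame_meta(meta_lines)
  rows <- lapply(data_lines, function(l) as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  nr <- length(rows)
  ncs <- unique(lengths(rows))
  if (nr != geometry$n_rows || length(ncs) != 1L || ncs != geometry$n_cols) {
    stop(sprintf("expected %d x %d grid but found %d x %s in %s",
                 geometry$n_rows, geometry$n_cols, nr,
                 paste(ncs, collapse = "/"), path), call. = FALSE)
  }
  values <- do.call(rbind, rows)
  pressure_frame(values, geometry,
                 frame_index = if (!is.null(meta$frame)) as.integer(meta$frame) else 1L,
                 subject_id = meta$subject %||% NA_character_,
                 task_id = meta$task %||% NA_character_)
}

#' @rdname read_pressure_frame
#' @param frame A [pressure_frame()] to serialise.
#' @param digits Number of significant digits written.
#' @export
write_pressure_frame <- function(frame, path, digits = 10) {
  stopifnot(inherits(frame, "pressure_frame"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# side: ", frame$geometry$side),
    paste0("# subject: ", frame$subject_id),
    paste0("# task: ", frame$task_id),
    paste0("# frame: ", frame$frame_index)
  ), con)
  writeLines(apply(frame$values, 1L, function(r) {
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE), collapse = " ")
  }), con)
  invisible(path)
}

parse_frame_meta <- function(meta_lines) {
  out <- list()
  for (l in meta_lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
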