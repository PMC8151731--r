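#' Default mat segmentation
#'
#' Partitions the effective sensing area into named rectangular subareas:
#' 12 blocks (B1--B12) for the backrest, laid out as 4 row bands by 3 column
#' bands, and 8 blocks (S1--S8) for the seat pan, 4 row bands by 2 column
#' bands. Blocks are numbered row-major from the top-left (backrest) /
#' front-left (seat pan). Band widths are as equal as possible with the
#' remainder assigned to the outer bands, which keeps both default schemes
#' mirror-symmetric about the mat's vertical midline.
#'
#' On top of the subareas the scheme defines *regional areas* — unions of
#' adjacent subareas: every horizontally adjacent subarea pair, every full row
#' band, every full column band, and the upper and lower halves.
#'
#' @param geometry A [mat_geometry()]; its `side` selects the scheme.
#' @return An object of class `segmentation_scheme` with elements `side`,
#'   `geometry`, `subareas` (named list of logical masks), `regions` (named
#'   list of subarea-name vectors) and `global_name` (`"B"` or `"S"`).
#' @examples
#' sc <- default_segmentation(mat_geometry("backrest"))
#' names(sc$subareas)
#' @export
default_segmentation <- function(geometry) {
  stopifnot(inherits(geometry, "mat_geometry"))
  layout <- switch(geometry$side,
    backrest = list(prefix = "B", block_rows = 4L, block_cols = 3L),
    seatpan  = list(prefix = "S", block_rows = 4L, block_cols = 2L),
    stop("unknown mat type: ", geometry$side, call. = FALSE)
  )
  row_sizes <- split_sizes(geometry$n_rows, layout$block_rows)
  col_sizes <- split_sizes(geometry$n_cols, layout$block_cols)
  row_start <- cumsum(c(1L, row_sizes))[seq_len(layout$block_rows)]
  col_start <- cumsum(c(1L, col_sizes))[seq_len(layout$block_cols)]

  subareas <- list()
  k <- 0L
  for (br in seq_len(layout$block_rows)) {
    for (bc in seq_len(layout$block_cols)) {
      k <- k + 1L
      m <- matrix(FALSE, geometry$n_rows, geometry$n_cols)
      m[row_start[br]:(row_start[br] + row_sizes[br] - 1L),
        col_start[bc]:(col_start[bc] + col_sizes[bc] - 1L)] <- TRUE
      subareas[[paste0(layout$prefix, k)]] <- m
    }
  }

  regions <- default_regions(layout$prefix, layout$block_rows, layout$block_cols)
  scheme <- structure(
    list(side = geometry$side, geometry = geometry, subareas = subareas,
         regions = regions, global_name = layout$prefix,
         block_rows = layout$block_rows, block_cols = layout$block_cols),
    class = "segmentation_scheme"
  )
  validate_segmentation(scheme)
  scheme
}

# As-equal-as-possible block sizes, remainder cells assigned outside-in so the
# size vector is symmetric (e.g. 44 into 3 -> 15,14,15; 42 into 4 -> 11,10,10,11).
split_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  i <- 1L; j <- k
  while (extra > 0L) {
    sizes[i] <- sizes[i] + 1L
    extra <- extra - 1L
    if (extra > 0L) {
      sizes[j] <- sizes[j] + 1L
      extra <- extra - 1L
    }
    i <- i + 1L; j <- j - 1L
  }
  sizes
}

default_regions <- function(prefix, block_rows, block_cols) {
  sub_name <- function(r, c) paste0(prefix, (r - 1L) * block_cols + c)
  regions <- list()
  # horizontally adjacent subarea pairs
  for (r in seq_len(block_rows)) {
    for (c in seq_len(block_cols - 1L)) {
      a <- sub_name(r, c); b <- sub_name(r, c + 1L)
      regions[[paste0(a, b)]] <- c(a, b)
    }
  }
  # full row bands (front-to-back / top-to-bottom strips)
  for (r in seq_len(block_rows)) {
    regions[[paste0(prefix, "_row", r)]] <-
      vapply(seq_len(block_cols), function(c) sub_name(r, c), character(1))
  }
  # full column bands (lateral strips)
  col_band_names <- if (block_cols == 3L) c("L", "M", "R") else c("L", "R")
  for (c in seq_len(block_cols)) {
    regions[[paste0(prefix, "_col", col_band_names[c])]] <-
      vapply(seq_len(block_rows), function(r) sub_name(r, c), character(1))
  }
  # upper and lower halves (rows 1-2 vs 3-4)
  half <- block_rows %/% 2L
  regions[[paste0(prefix, "_upper")]] <- as.vector(
    vapply(seq_len(half), function(r) vapply(seq_len(block_cols), function(c)
      sub_name(r, c), character(1)), character(block_cols)))
  regions[[paste0(prefix, "_lower")]] <- as.vector(
    vapply((half + 1L):block_rows, function(r) vapply(seq_len(block_cols), function(c)
      sub_name(r, c), character(1)), character(block_cols)))
  regions
}

#' Validate a segmentation scheme
#'
#' Asserts the partition property (subareas pairwise disjoint, union equal to
#' the full sensing area), the expected subarea counts per side, and that all
#' region members refer to existing subareas with at least two members each.
#'
#' @param scheme A `segmentation_scheme`.
#' @return `scheme`, invisibly; errors on violation.
#' @export
validate_segmentation <- function(scheme) {
  stopifnot(inherits(scheme, "segmentation_scheme"))
  g <- scheme$geometry
  expected <- switch(scheme$side, backrest = 12L, seatpan = 8L)
  if (length(scheme$subareas) != expected) {
    stop(sprintf("%s scheme must have %d subareas, found %d",
                 scheme$side, expected, length(scheme$subareas)), call. = FALSE)
  }
  total <- Reduce(`+`, lapply(scheme$subareas, function(m) m * 1L))
  if (any(total != 1L)) {
    stop("subarea masks must partition the sensing area exactly", call. = FALSE)
  }
  for (rn in names(scheme$regions)) {
    members <- scheme$regions[[rn]]
    if (length(members) < 2L || !all(members %in% names(scheme$subareas))) {
      stop(sprintf("region %s must be a union of >= 2 existing subareas", rn),
           call. = FALSE)
    }
  }
  invisible(scheme)
}

#' Resolve a named area of a scheme to its logical cell mask
#'
#' @param scheme A `segmentation_scheme`.
#' @param area A subarea name (e.g. `"B3"`), region name (e.g. `"S_upper"`),
#'   or the global name (`"B"`/`"S"`).
#' @return Logical matrix mask.
#' @export
area_mask <- function(scheme, area) {
  if (area == scheme$global_name) {
    return(matrix(TRUE, scheme$geometry$n_rows, scheme$geometry$n_cols))
  }
  if (area %in% names(scheme$subareas)) return(scheme$subareas[[area]])
  if (area %in% names(scheme$regions)) {
    return(Reduce(`|`, scheme$subareas[scheme$regions[[area]]]))
  }
  stop("unknown area: ", area, call. = FALSE)
}

#' @export
print.segmentation_scheme <- function(x, ...) {
  cat(sprintf("<segmentation_scheme> %s: %d subareas (%s..%s), %d regions\n",
              x$side, length(x$subareas), names(x$subareas)[1],
              names(x$subareas)[length(x$subareas)], length(x$regions)))
  invisible(x)
}

#' Read and write segmentation schemes as declarative text
#'
#' A scheme file is line-oriented: `subarea <name> rect <r1> <r2> <c1> <c2>`
#' declares a rectangular subarea (1-based inclusive bounds), and
#' `region <name> <subarea> <subarea> ...` declares a regional union.
#'
#' @param path File path.
#' @param geometry The [mat_geometry()] the scheme applies to.
#' @return A validated `segmentation_scheme`.
#' @export
read_segmentation <- function(path, geometry) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^#", lines)])
  subareas <- list()
  regions <- list()
  for (l in lines) {
    tok <- strsplit(l, "[[:space:]]+")[[1]]
    if (tok[1] == "subarea" && tok[3] == "rect") {
      b <- as.integer(tok[4:7])
      m <- matrix(FALSE, geometry$n_rows, geometry$n_cols)
      m[b[1]:b[2], b[3]:b[4]] <- TRUE
      subareas[[tok[2]]] <- m
    } else if (tok[1] == "region") {
      regions[[tok[2]]] <- tok[-(1:2)]
    } else {
      stop("unrecognised scheme line: ", l, call. = FALSE)
    }
  }
  scheme <- structure(
    list(side = geometry$side, geometry = geometry, subareas = subareas,
         regions = regions,
         global_name = substr(names(subareas)[1], 1, 1)),
    class = "segmentation_scheme"
  )
  validate_segmentation(scheme)
  scheme
}
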