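#' Center of pressure of a masked area
#'
#' The load-weighted centroid of the cells in `mask`:
#' \eqn{(x, y) = \sum_i p_i (x_i, y_i) / \sum_i p_i}, with cell-centre
#' physical coordinates in cm.
#'
#' @param frame A [pressure_frame()].
#' @param mask Logical matrix the same shape as the frame.
#' @return Named numeric vector `c(x =, y =)` in cm. When the masked total
#'   pressure is zero the CoP is undefined and the sentinel
#'   `c(x = NA, y = NA)` is returned; callers that need dense features
#'   substitute the mask's geometric centre (see [compute_features()]).
#' @export
center_of_pressure <- function(frame, mask) {
  stopifnot(inherits(frame, "pressure_frame"))
  mask <- check_mask(mask, frame$geometry)
  p <- frame$values[mask]
  tot <- sum(p)
  if (tot <= 0) return(c(x = NA_real_, y = NA_real_))
  cc <- cell_centers(frame$geometry)
  c(x = sum(p * cc$X[mask]) / tot, y = sum(p * cc$Y[mask]) / tot)
}

#' Contact area proportion
#'
#' Fraction of an area's cells whose pressure strictly exceeds a contact
#' threshold.
#'
#' @inheritParams center_of_pressure
#' @param threshold Contact threshold in pressure units; must be >= 0. The
#'   default 0 counts any positive reading as contact.
#' @return A fraction in \[0, 1\].
#' @export
contact_area_proportion <- function(frame, mask, threshold = 0) {
  stopifnot(inherits(frame, "pressure_frame"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("contact threshold must be a single non-negative number", call. = FALSE)
  }
  mask <- check_mask(mask, frame$geometry)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sum(frame$values[mask] > threshold) / sum(mask)
}

#' Pressure ratio between two disjoint areas
#'
#' \eqn{\Sigma p(A) / (\Sigma p(A) + \Sigma p(B))}. Both sums zero yields the
#' undefined sentinel `NA`, replaced by 0.5 in dense feature vectors.
#'
#' @inheritParams center_of_pressure
#' @param mask_a,mask_b Disjoint logical masks on the same frame.
#' @return Ratio in \[0, 1\], or `NA` when both areas carry no load.
#' @export
pressure_ratio <- function(frame, mask_a, mask_b) {
  stopifnot(inherits(frame, "pressure_frame"))
  mask_a <- check_mask(mask_a, frame$geometry)
  mask_b <- check_mask(mask_b, frame$geometry)
  if (any(mask_a & mask_b)) stop("pressure ratio masks must be disjoint", call. = FALSE)
  a <- sum(frame$values[mask_a])
  b <- sum(frame$values[mask_b])
  if (a + b == 0) return(NA_real_)
  a / (a + b)
}

#' Area summary statistics
#'
#' Mean pressure over the area's cells (zeros included), peak pressure, and
#' total force (pressure integrated over the cell area, i.e.
#' \eqn{\Sigma p \cdot} `cell_size`^2).
#'
#' @inheritParams center_of_pressure
#' @return Named vector `c(mean_pressure =, peak_pressure =, total_force =)`.
#' @export
area_statistics <- function(frame, mask) {
  stopifnot(inherits(frame, "pressure_frame"))
  mask <- check_mask(mask, frame$geometry)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  p <- frame$values[mask]
  c(mean_pressure = mean(p),
    peak_pressure = max(p),
    total_force = sum(p) * frame$geometry$cell_size^2)
}

check_mask <- function(mask, geometry) {
  mask <- as.matrix(mask)
  if (nrow(mask) != geometry$n_rows || ncol(mask) != geometry$n_cols) {
    stop("mask shape does not match geometry", call. = FALSE)
  }
  storage.mode(mask) <- "logical"
  mask
}

#' Enumerate the 200-candidate feature collection
#'
#' Builds the ordered manifest of pressure feature descriptors over both mats.
#' The composition, per side, is: global CoP x/y, contact proportion, mean,
#' peak and total force (6 each); CoP x/y, contact proportion, mean and total
#' force per subarea (5 x 20 subareas); contact proportion and total force per
#' regional area (2 x 29 regions); and 30 pressure ratios (horizontally and
#' vertically adjacent subarea pairs, upper vs lower halves on both sides, and
#' left vs right halves of the seat pan). The total is exactly 200 and is
#' asserted at construction: a scheme whose areas cannot yield 200 under this
#' enumeration is an error, never silently truncated.
#'
#' @param backrest_scheme,seatpan_scheme Segmentation schemes from
#'   [default_segmentation()] (or [read_segmentation()]).
#' @param threshold Contact threshold used for all contact-proportion
#'   features.
#' @return An object of class `feature_set`: a list with `descriptors` (a
#'   data frame with columns `name`, `kind`, `side`, `area`, `area2`), the two
#'   schemes, and the threshold.
#' @examples
#' fs <- enumerate_feature_set(default_segmentation(mat_geometry("backrest")),
#'                             default_segmentation(mat_geometry("seatpan")))
#' nrow(fs$descriptors)
#' @export
enumerate_feature_set <- function(backrest_scheme, seatpan_scheme, threshold = 0) {
  stopifnot(inherits(backrest_scheme, "segmentation_scheme"),
            inherits(seatpan_scheme, "segmentation_scheme"),
            backrest_scheme$side == "backrest", seatpan_scheme$side == "seatpan")
  desc <- rbind(side_descriptors(backrest_scheme), side_descriptors(seatpan_scheme))
  if (nrow(desc) != 200L) {
    stop(sprintf("feature enumeration yields %d descriptors, not 200; ",
                 nrow(desc)),
         "the supplied schemes are incompatible with the documented manifest",
         call. = FALSE)
  }
  if (anyDuplicated(desc$name)) stop("duplicate feature names in manifest", call. = FALSE)
  structure(list(descriptors = desc, backrest_scheme = backrest_scheme,
                 seatpan_scheme = seatpan_scheme, threshold = threshold),
            class = "feature_set")
}

side_descriptors <- function(scheme) {
  g <- scheme$global_name
  side <- scheme$side
  d <- function(name, kind, area, area2 = NA_character_) {
    data.frame(name = name, kind = kind, side = side, area = area,
               area2 = area2, stringsAsFactors = FALSE)
  }
  out <- list()
  # global area
  for (k in c("cop_x", "cop_y", "contact_area_proportion", "mean_pressure",
              "peak_pressure", "total_force")) {
    out[[length(out) + 1L]] <- d(paste0(g, ".", short_kind(k)), k, g)
  }
  # subareas
  for (a in names(scheme$subareas)) {
    for (k in c("cop_x", "cop_y", "contact_area_proportion", "mean_pressure",
                "total_force")) {
      out[[length(out) + 1L]] <- d(paste0(a, ".", short_kind(k)), k, a)
    }
  }
  # regional areas
  for (a in names(scheme$regions)) {
    for (k in c("contact_area_proportion", "total_force")) {
      out[[length(out) + 1L]] <- d(paste0(a, ".", short_kind(k)), k, a)
    }
  }
  # pressure ratios over disjoint subarea/half pairs
  for (pr in side_ratio_pairs(scheme)) {
    out[[length(out) + 1L]] <- d(paste0("ratio.", pr[1], "_", pr[2]),
                                 "pressure_ratio", pr[1], pr[2])
  }
  do.call(rbind, out)
}

short_kind <- function(kind) {
  c(cop_x = "cop_x", cop_y = "cop_y", contact_area_proportion = "contact",
    mean_pressure = "mean", peak_pressure = "peak", total_force = "total")[[kind]]
}

side_ratio_pairs <- function(scheme) {
  br <- scheme$block_rows %||% 4L
  bc <- scheme$block_cols %||% (length(scheme$subareas) %/% 4L)
  g <- scheme$global_name
  sub_name <- function(r, c) paste0(g, (r - 1L) * bc + c)
  pairs <- list()
  for (r in seq_len(br)) {             # horizontally adjacent
    for (c in seq_len(bc - 1L)) {
      pairs[[length(pairs) + 1L]] <- c(sub_name(r, c), sub_name(r, c + 1L))
    }
  }
  for (c in seq_len(bc)) {             # vertically adjacent
    for (r in seq_len(br - 1L)) {
      pairs[[length(pairs) + 1L]] <- c(sub_name(r, c), sub_name(r + 1L, c))
    }
  }
  pairs[[length(pairs) + 1L]] <- c(paste0(g, "_upper"), paste0(g, "_lower"))
  if (bc == 2L) {                      # seat pan halves form a true bipartition
    pairs[[length(pairs) + 1L]] <- c(paste0(g, "_colL"), paste0(g, "_colR"))
  }
  pairs
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d descriptors (%s)\n", nrow(x$descriptors),
              paste(sprintf("%s: %d", names(table(x$descriptors$kind)),
                            table(x$descriptors$kind)), collapse = ", ")))
  invisible(x)
}

# ---- batch computation engine -------------------------------------------

# Precompute, per side, sparse aggregation operators over the vectorised
# (column-major) frame: plain sums, x- and y-weighted sums, per-area sizes and
# geometric centres. One matrix multiply then serves every frame at once.
side_plan <- function(scheme) {
  g <- scheme$geometry
  areas <- unique(c(scheme$global_name, names(scheme$subareas), names(scheme$regions)))
  cc <- cell_centers(g)
  nc <- n_cells(g)
  idx_list <- lapply(areas, function(a) which(as.vector(area_mask(scheme, a))))
  names(idx_list) <- areas
  ii <- rep(seq_along(areas), lengths(idx_list))
  jj <- unlist(idx_list, use.names = FALSE)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(length(areas), nc))
  xv <- as.vector(cc$X); yv <- as.vector(cc$Y)
  AX <- Matrix::sparseMatrix(i = ii, j = jj, x = xv[jj], dims = c(length(areas), nc))
  AY <- Matrix::sparseMatrix(i = ii, j = jj, x = yv[jj], dims = c(length(areas), nc))
  sizes <- lengths(idx_list)
  gc_x <- vapply(idx_list, function(ix) mean(xv[ix]), numeric(1))
  gc_y <- vapply(idx_list, function(ix) mean(yv[ix]), numeric(1))
  list(areas = areas, A = A, AX = AX, AY = AY, sizes = sizes,
       gc_x = gc_x, gc_y = gc_y, idx = idx_list,
       cell_area = g$cell_size^2)
}

# Aggregates for a side: F is n_cells x n_frames.
side_aggregates <- function(plan, F, threshold) {
  sums <- as.matrix(plan$A %*% F)
  cnts <- as.matrix(plan$A %*% (F > threshold))
  wx <- as.matrix(plan$AX %*% F)
  wy <- as.matrix(plan$AY %*% F)
  rownames(sums) <- rownames(cnts) <- rownames(wx) <- rownames(wy) <- plan$areas
  list(sums = sums, cnts = cnts, wx = wx, wy = wy)
}

#' Compute a feature matrix for many frame pairs at once
#'
#' Vectorised evaluation of a [enumerate_feature_set()] manifest on stacks of
#' frames. Undefined centres of pressure (zero load in the area) are replaced
#' by the area's geometric centre and undefined pressure ratios (both areas
#' unloaded) by 0.5, so the returned matrix is always dense.
#'
#' @param backrest Matrix of vectorised backrest frames, `n_cells` rows
#'   (column-major cell order) by `n_frames` columns.
#' @param seatpan Same for the seat pan.
#' @param features A `feature_set`.
#' @return Numeric matrix, `n_frames` rows by 200 named columns.
#' @export
compute_feature_matrix <- function(backrest, seatpan, features) {
  stopifnot(inherits(features, "feature_set"),
            ncol(backrest) == ncol(seatpan))
  plans <- list(backrest = side_plan(features$backrest_scheme),
                seatpan = side_plan(features$seatpan_scheme))
  aggs <- list(
    backrest = side_aggregates(plans$backrest, backrest, features$threshold),
    seatpan = side_aggregates(plans$seatpan, seatpan, features$threshold)
  )
  Fs <- list(backrest = backrest, seatpan = seatpan)
  desc <- features$descriptors
  n_frames <- ncol(backrest)
  out <- matrix(NA_real_, n_frames, nrow(desc),
                dimnames = list(NULL, desc$name))
  for (i in seq_len(nrow(desc))) {
    side <- desc$side[i]
    plan <- plans[[side]]
    agg <- aggs[[side]]
    a <- desc$area[i]
    out[, i] <- switch(desc$kind[i],
      cop_x = {
        v <- agg$wx[a, ] / agg$sums[a, ]
        v[agg$sums[a, ] == 0] <- plan$gc_x[[a]]
        v
      },
      cop_y = {
        v <- agg$wy[a, ] / agg$sums[a, ]
        v[agg$sums[a, ] == 0] <- plan$gc_y[[a]]
        v
      },
      contact_area_proportion = agg$cnts[a, ] / plan$sizes[[a]],
      mean_pressure = agg$sums[a, ] / plan$sizes[[a]],
      total_force = agg$sums[a, ] * plan$cell_area,
      peak_pressure = apply(Fs[[side]][plan$idx[[a]], , drop = FALSE], 2L, max),
      pressure_ratio = {
        b <- desc$area2[i]
        s <- agg$sums[a, ] + agg$sums[b, ]
        v <- agg$sums[a, ] / s
        v[s == 0] <- 0.5
        v
      },
      stop("unknown feature kind: ", desc$kind[i], call. = FALSE)
    )
  }
  out
}

#' Compute the feature vector for one frame pair
#'
#' @param backrest_frame,seatpan_frame [pressure_frame()]s matching the
#'   manifest's geometries.
#' @param features A `feature_set` from [enumerate_feature_set()].
#' @return Named numeric vector of length 200.
#' @export
compute_features <- function(backrest_frame, seatpan_frame, features) {
  stopifnot(inherits(backrest_frame, "pressure_frame"),
            inherits(seatpan_frame, "pressure_frame"),
            inherits(features, "feature_set"))
  check_frame_geometry(backrest_frame, features$backrest_scheme$geometry)
  check_frame_geometry(seatpan_frame, features$seatpan_scheme$geometry)
  m <- compute_feature_matrix(matrix(as.vector(backrest_frame$values), ncol = 1),
                              matrix(as.vector(seatpan_frame$values), ncol = 1),
                              features)
  stats::setNames(m[1L, ], colnames(m))
}

check_frame_geometry <- function(frame, geometry) {
  g <- frame$geometry
  if (g$n_rows != geometry$n_rows || g$n_cols != geometry$n_cols ||
      g$side != geometry$side) {
    stop(sprintf("frame geometry (%s %dx%d) does not match the manifest (%s %dx%d)",
                 g$side, g$n_rows, g$n_cols,
                 geometry$side, geometry$n_rows, geometry$n_cols), call. = FALSE)
  }
  invisible(frame)
}

#' Relative features with respect to a reference posture
#'
#' Elementwise difference `current - reference`. Differences (rather than
#' ratios) stay well defined when a reference entry is zero. The reference is
#' typically the mean feature vector over a task's opening standard-posture
#' frames (see [reference_features()]).
#'
#' @param current,reference Named feature vectors (or matrices with named
#'   columns) with identical descriptor names in identical order.
#' @return Same shape as `current`: the relative feature values.
#' @export
relative_features <- function(current, reference) {
  cn <- if (is.matrix(current)) colnames(current) else names(current)
  rn <- if (is.matrix(reference)) colnames(reference) else names(reference)
  if (is.null(cn) || !identical(cn, rn)) {
    stop("current and reference feature descriptors do not match", call. = FALSE)
  }
  if (is.matrix(current) && !is.matrix(reference)) {
    return(sweep(current, 2L, reference, `-`))
  }
  current - reference
}

#' Reference (standard posture) feature vector for a task
#'
#' Mean of the feature vectors of the first `window` frames of a task; every
#' recording opens with the standard posture, so this estimates the
#' subject-and-task-specific baseline that relative features subtract.
#'
#' @param feature_matrix Frames-by-features matrix for one task, in temporal
#'   order.
#' @param window Number of opening frames to average (default 12 frames,
#'   i.e. 0.5 s at 25 fps).
#' @return Named numeric vector.
#' @export
reference_features <- function(feature_matrix, window = 12L) {
  window <- min(as.integer(window), nrow(feature_matrix))
  colMeans(feature_matrix[seq_len(window), , drop = FALSE])
}

#' Write / read a feature manifest as delimited text
#'
#' @param features A `feature_set`.
#' @param path File path.
#' @return `write_feature_manifest()` invisibly returns `path`;
#'   `read_feature_manifest()` returns the descriptor data frame.
#' @export
write_feature_manifest <- function(features, path) {
  utils::write.table(features$descriptors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_manifest
#' @export
read_feature_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
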