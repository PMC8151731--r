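point_key <- function(pts) paste(round(pts$u, 10), round(pts$v, 10))

test_that("layout generation reproduces the design family exactly", {
  expect_identical(vapply(1:5, function(k) nrow(generate_layout(k)$points),
                          integer(1)),
                   c(13L, 25L, 41L, 81L, 145L))
  # closed form equals exhaustive generation beyond the published range
  for (k in 1:6) {
    expect_identical(layout_size(k), nrow(generate_layout(k)$points))
  }
  # level 2 is exactly the uniform 5x5 grid
  g5 <- expand.grid(u = (0:4) / 4, v = (0:4) / 4)
  expect_setequal(point_key(generate_layout(2)$points), point_key(g5))
  # levels nest and all four corners are present at every level
  corners <- point_key(data.frame(u = c(0, 1, 0, 1), v = c(0, 0, 1, 1)))
  for (k in 1:5) {
    pk <- point_key(generate_layout(k)$points)
    expect_identical(anyDuplicated(pk), 0L)
    expect_true(all(corners %in% pk))
    expect_true(all(pk %in% point_key(generate_layout(k + 1)$points)))
  }
  expect_error(generate_layout(0), ">= 1")
})

test_that("the level-5 design removes 92% of the sensors", {
  reduction <- (2 * 42 * 44 - 2 * layout_size(5)) / (2 * 42 * 44)
  expect_identical(round(100 * reduction), 92)
})

test_that("snapping picks the nearest cell with lexicographic tie-breaking", {
  g <- mat_geometry("seatpan")
  l <- generate_layout(1)
  snap <- snap_to_cells(l, g)
  expect_identical(snap$row[snap$u == 0 & snap$v == 0], 1L)
  expect_identical(snap$col[snap$u == 1 & snap$v == 1], 44L)
  expect_identical(snap$row[snap$u == 1 & snap$v == 1], 42L)
  # a point exactly at a cell centre maps to that cell
  gg <- mat_geometry("seatpan", 5, 5, 1)
  lay <- structure(list(level = 1L,
                        points = data.frame(u = 2 / 4, v = 3 / 4)),
                   class = "sensor_layout")
  s <- snap_to_cells(lay, gg)
  expect_identical(c(s$row, s$col), c(4L, 3L))
  # equidistant between two centres -> lower (row, col); verify against an
  # exhaustive candidate enumeration
  lay2 <- structure(list(level = 1L,
                         points = data.frame(u = 0.5 / 4, v = 0.5 / 4)),
                    class = "sensor_layout")
  s2 <- snap_to_cells(lay2, gg)
  cand <- expand.grid(row = 1:5, col = 1:5)
  d <- sqrt((cand$col - 1 - 0.5)^2 + (cand$row - 1 - 0.5)^2)
  best <- cand[d == min(d), ]
  best <- best[order(best$row, best$col), ][1, ]
  expect_identical(c(s2$row, s2$col), c(best$row, best$col))
  expect_identical(c(s2$row, s2$col), c(1L, 1L))
})

test_that("sampling reads the frame at the snapped cells", {
  g <- mat_geometry("seatpan")
  l <- generate_layout(2)
  fr <- pressure_frame(matrix(4.2, 42, 44), g)
  expect_true(all(sample_frame(fr, l)$values == 4.2))
  # spike at a snapped cell -> exactly one nonzero sample
  snap <- snap_to_cells(l, g)
  v <- matrix(0, 42, 44)
  v[snap$row[7], snap$col[7]] <- 1
  expect_identical(sum(sample_frame(pressure_frame(v, g), l)$values > 0), 1L)
  # random frame: sampled values equal direct lookups
  set.seed(5)
  fr <- random_frame(g)
  s <- sample_frame(fr, l)
  expect_identical(s$values,
                   fr$values[cbind(s$cells$row, s$cells$col)])
})

test_that("IDW reconstruction matches a hand-coded loop and stays bounded", {
  g <- mat_geometry("seatpan", 5, 5, 1)
  lay <- structure(list(level = NA_integer_,
                        points = data.frame(u = c(0, 1, 0.4),
                                            v = c(0, 1, 0.6))),
                   class = "sensor_layout")
  vals <- c(2, 8, 5)
  W <- idw_operator(lay, g, power = 2, n_neighbors = 3)
  got <- matrix(as.vector(W %*% vals), 5, 5)
  pos <- cbind(x = lay$points$u * 4, y = lay$points$v * 4)
  colnames(pos) <- c("x", "y")
  want <- naive_idw(pos, vals, g, power = 2, k = 3)
  expect_equal(got, want, tolerance = 1e-12)
  # constant samples reconstruct to a constant field
  Wc <- idw_operator(generate_layout(2), g)
  expect_equal(as.vector(Wc %*% rep(7, 25)), rep(7, 25), tolerance = 1e-12)
  # bounds: convex weights keep values within the sampled extrema
  set.seed(6)
  for (i in 1:10) {
    v <- runif(25, 0, 10)
    r <- as.vector(Wc %*% v)
    expect_true(all(r >= min(v) - 1e-12 & r <= max(v) + 1e-12))
  }
  expect_error(idw_operator(lay, g, power = 0), "positive")
  empty <- structure(list(level = NA_integer_,
                          points = data.frame(u = numeric(0), v = numeric(0))),
                     class = "sensor_layout")
  expect_error(idw_operator(empty, g), "empty")
})

test_that("full-resolution sampling reconstructs the identity", {
  g <- mat_geometry("backrest", 6, 7, 1.27)
  set.seed(7)
  fr <- random_frame(g)
  rec <- idw_reconstruct(sample_frame(fr, full_resolution_layout(g)), g)
  expect_equal(rec$values, fr$values, tolerance = 1e-12)
})

test_that("reconstruction error reports RMSE and max deviation", {
  g <- mat_geometry("seatpan", 6, 7, 1)
  set.seed(8)
  a <- random_frame(g)
  expect_equal(reconstruction_error(a, a), c(rmse = 0, max_abs = 0))
  b <- pressure_frame(a$values + 0.3, g)
  expect_equal(reconstruction_error(a, b), c(rmse = 0.3, max_abs = 0.3))
  d <- random_frame(g)
  expect_equal(reconstruction_error(a, d),
               c(rmse = sqrt(mean((a$values - d$values)^2)),
                 max_abs = max(abs(a$values - d$values))))
  expect_error(reconstruction_error(a, random_frame(mat_geometry("seatpan", 5, 5, 1))),
               "mismatch")
})

test_that("reconstruction fidelity improves monotonically on a smooth frame", {
  frames <- render_frames(standard_label(), standard_kinematics())
  for (side in c("backrest", "seatpan")) {
    sm <- frames[[side]]
    rmse <- vapply(1:5, function(k) {
      reconstruction_error(sm, idw_reconstruct(sample_frame(sm, generate_layout(k))))[["rmse"]]
    }, numeric(1))
    expect_true(all(diff(rmse) <= 1e-9),
                label = sprintf("%s RMSE non-increasing over levels", side))
  }
})
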