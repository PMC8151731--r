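make_mask <- function(geometry, rows, cols) {
  m <- matrix(FALSE, geometry$n_rows, geometry$n_cols)
  m[rows, cols] <- TRUE
  m
}

test_that("center of pressure matches its definition", {
  g <- small_geometry()
  # single loaded cell -> its own centre
  v <- matrix(0, 6, 7); v[3, 5] <- 4.2
  fr <- pressure_frame(v, g)
  expect_equal(center_of_pressure(fr, matrix(TRUE, 6, 7)), c(x = 4, y = 2))
  # uniform load on a rectangle -> rectangle centre
  v2 <- matrix(0, 6, 7); v2[2:5, 3:6] <- 1
  expect_equal(center_of_pressure(pressure_frame(v2, g), matrix(TRUE, 6, 7)),
               c(x = (2 + 5) / 2, y = (1 + 4) / 2))
  # random frames -> brute-force double loop
  set.seed(1)
  for (i in 1:20) {
    fr <- random_frame(g)
    mask <- matrix(runif(42) < 0.6, 6, 7)
    if (sum(fr$values[mask]) == 0) next
    expect_equal(center_of_pressure(fr, mask),
                 naive_cop(fr$values, mask, g$cell_size), tolerance = 1e-12)
  }
  # zero load -> undefined sentinel
  expect_equal(center_of_pressure(pressure_frame(matrix(0, 6, 7), g),
                                  matrix(TRUE, 6, 7)),
               c(x = NA_real_, y = NA_real_))
})

test_that("contact area proportion counts strictly-above-threshold cells", {
  g <- small_geometry()
  fr <- pressure_frame(matrix(5, 6, 7), g)
  expect_equal(contact_area_proportion(fr, matrix(TRUE, 6, 7), 1), 1)
  expect_equal(contact_area_proportion(pressure_frame(matrix(0, 6, 7), g),
                                       matrix(TRUE, 6, 7), 0), 0)
  # 3 of 10 mask cells above threshold
  v <- matrix(0, 6, 7); v[1, 1:3] <- 10
  mask <- make_mask(g, 1:2, 1:5)
  expect_equal(contact_area_proportion(pressure_frame(v, g), mask, 1), 0.3)
  expect_error(contact_area_proportion(fr, matrix(TRUE, 6, 7), -0.5),
               "non-negative")
})

test_that("pressure ratio behaves as a load share", {
  g <- small_geometry()
  a <- make_mask(g, 1:3, 1:3)
  b <- make_mask(g, 4:6, 1:3)
  v <- matrix(0, 6, 7); v[1:3, 1:3] <- 1; v[4:6, 1:3] <- 1
  expect_equal(pressure_ratio(pressure_frame(v, g), a, b), 0.5)
  v2 <- matrix(0, 6, 7); v2[1:3, 1:3] <- 2
  expect_equal(pressure_ratio(pressure_frame(v2, g), a, b), 1)
  v3 <- matrix(0, 6, 7); v3[1, 1] <- 3; v3[4, 1] <- 1
  expect_equal(pressure_ratio(pressure_frame(v3, g), a, b), 0.75)
  expect_true(is.na(pressure_ratio(pressure_frame(matrix(0, 6, 7), g), a, b)))
  expect_error(pressure_ratio(pressure_frame(v, g), a, a), "disjoint")
})

test_that("area statistics match brute force and units", {
  g <- mat_geometry("seatpan", 6, 7, 1.27)
  mask <- make_mask(g, 2:4, 2:6)
  fr <- pressure_frame(matrix(3, 6, 7), g)
  expect_equal(area_statistics(fr, mask),
               c(mean_pressure = 3, peak_pressure = 3,
                 total_force = 3 * 15 * 1.27^2))
  v <- matrix(0, 6, 7); v[3, 3] <- 9
  expect_equal(area_statistics(pressure_frame(v, g), mask)[["peak_pressure"]], 9)
  set.seed(2)
  fr <- random_frame(g)
  expect_equal(area_statistics(fr, mask),
               naive_stats(fr$values, mask, g$cell_size), tolerance = 1e-12)
})

test_that("the feature manifest has exactly 200 well-formed descriptors", {
  fs <- enumerate_feature_set(default_segmentation(mat_geometry("backrest")),
                              default_segmentation(mat_geometry("seatpan")))
  d <- fs$descriptors
  expect_identical(nrow(d), 200L)
  expect_identical(anyDuplicated(d$name), 0L)
  # referential integrity: every area name resolves in its side's scheme
  for (i in seq_len(nrow(d))) {
    sc <- if (d$side[i] == "backrest") fs$backrest_scheme else fs$seatpan_scheme
    expect_silent(area_mask(sc, d$area[i]))
    if (!is.na(d$area2[i])) {
      expect_silent(area_mask(sc, d$area2[i]))
      expect_true(!any(area_mask(sc, d$area[i]) & area_mask(sc, d$area2[i])))
    }
  }
})

test_that("a scheme that cannot yield 200 features errors instead of truncating", {
  bs <- default_segmentation(mat_geometry("backrest"))
  ss <- default_segmentation(mat_geometry("seatpan"))
  ss$regions <- ss$regions[-1]
  expect_error(enumerate_feature_set(bs, ss), "not 200")
})

test_that("computed feature vectors match the naive per-descriptor oracle", {
  bg <- mat_geometry("backrest", 8, 9, 1)
  sg <- mat_geometry("seatpan", 8, 9, 1)
  fs <- enumerate_feature_set(default_segmentation(bg), default_segmentation(sg),
                              threshold = 0.5)
  set.seed(3)
  for (i in 1:5) {
    bf <- random_frame(bg, density = 0.5)
    sf <- random_frame(sg, density = 0.5)
    got <- compute_features(bf, sf, fs)
    want <- naive_feature_vector(bf, sf, fs)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("all-zero frames produce the sentinel-replaced baseline vector", {
  bg <- mat_geometry("backrest")
  sg <- mat_geometry("seatpan")
  fs <- enumerate_feature_set(default_segmentation(bg), default_segmentation(sg))
  fv <- compute_features(pressure_frame(matrix(0, 42, 44), bg),
                         pressure_frame(matrix(0, 42, 44), sg), fs)
  d <- fs$descriptors
  expect_true(all(fv[d$kind %in% c("contact_area_proportion", "mean_pressure",
                                   "peak_pressure", "total_force")] == 0))
  expect_true(all(fv[d$kind == "pressure_ratio"] == 0.5))
  # global CoP sentinel = geometric mat centre
  expect_equal(unname(fv["B.cop_x"]), (44 - 1) / 2 * 1.27)
  expect_equal(unname(fv["S.cop_y"]), (42 - 1) / 2 * 1.27)
})

test_that("features are scale invariant / covariant as required", {
  bg <- mat_geometry("backrest")
  sg <- mat_geometry("seatpan")
  set.seed(4)
  bf <- random_frame(bg, density = 0.4)
  sf <- random_frame(sg, density = 0.4)
  k <- 3.7
  fs0 <- enumerate_feature_set(default_segmentation(bg), default_segmentation(sg),
                               threshold = 1)
  fsk <- enumerate_feature_set(default_segmentation(bg), default_segmentation(sg),
                               threshold = k)       # threshold scaled with k
  f0 <- compute_features(bf, sf, fs0)
  fk <- compute_features(pressure_frame(bf$values * k, bg),
                         pressure_frame(sf$values * k, sg), fsk)
  d <- fs0$descriptors
  inv <- d$kind %in% c("cop_x", "cop_y", "contact_area_proportion", "pressure_ratio")
  expect_equal(fk[inv], f0[inv], tolerance = 1e-12)
  expect_equal(fk[d$kind == "total_force"], k * f0[d$kind == "total_force"],
               tolerance = 1e-12)
})

test_that("shifting a blob one column shifts the global CoP x by one cell", {
  g <- mat_geometry("seatpan")
  v <- matrix(0, 42, 44)
  v[10:20, 10:20] <- matrix(runif(121, 1, 5), 11, 11)
  shifted <- cbind(matrix(0, 42, 1), v[, -44])
  all_cells <- matrix(TRUE, 42, 44)
  c0 <- center_of_pressure(pressure_frame(v, g), all_cells)
  c1 <- center_of_pressure(pressure_frame(shifted, g), all_cells)
  expect_equal(unname(c1["x"] - c0["x"]), g$cell_size, tolerance = 1e-12)
  expect_equal(unname(c1["y"]), unname(c0["y"]), tolerance = 1e-12)
})

test_that("relative features are differences with the expected symmetries", {
  x <- c(a = 1.5, b = -2, c = 0)
  y <- c(a = 0.5, b = 1, c = 0)
  expect_equal(relative_features(x, x), c(a = 0, b = 0, c = 0))
  expect_equal(relative_features(x, c(a = 0, b = 0, c = 0)), x)
  expect_equal(relative_features(x, y), -relative_features(y, x))
  expect_error(relative_features(x, c(a = 1, z = 2, c = 3)), "do not match")
  m <- rbind(x, x + 1)
  expect_equal(relative_features(m, y), sweep(m, 2, y, `-`))
})

test_that("feature manifests round-trip through delimited text", {
  fs <- enumerate_feature_set(default_segmentation(mat_geometry("backrest")),
                              default_segmentation(mat_geometry("seatpan")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_manifest(fs, path)
  back <- read_feature_manifest(path)
  expect_identical(back$name, fs$descriptors$name)
  expect_identical(back$kind, fs$descriptors$kind)
})
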