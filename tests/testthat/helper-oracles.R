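# Independent naive-loop implementations used as oracles. These deliberately
# avoid the package's vectorised code paths: everything is an explicit double
# loop over cells.

naive_cop <- function(values, mask, cell_size) {
  num_x <- 0; num_y <- 0; den <- 0
  for (r in seq_len(nrow(values))) {
    for (c in seq_len(ncol(values))) {
      if (mask[r, c]) {
        p <- values[r, c]
        num_x <- num_x + p * (c - 1) * cell_size
        num_y <- num_y + p * (r - 1) * cell_size
        den <- den + p
      }
    }
  }
  if (den <= 0) return(c(x = NA_real_, y = NA_real_))
  c(x = num_x / den, y = num_y / den)
}

naive_contact <- function(values, mask, threshold) {
  n_above <- 0; n_mask <- 0
  for (r in seq_len(nrow(values))) {
    for (c in seq_len(ncol(values))) {
      if (mask[r, c]) {
        n_mask <- n_mask + 1
        if (values[r, c] > threshold) n_above <- n_above + 1
      }
    }
  }
  n_above / n_mask
}

naive_ratio <- function(values, mask_a, mask_b) {
  a <- 0; b <- 0
  for (r in seq_len(nrow(values))) {
    for (c in seq_len(ncol(values))) {
      if (mask_a[r, c]) a <- a + values[r, c]
      if (mask_b[r, c]) b <- b + values[r, c]
    }
  }
  if (a + b == 0) return(NA_real_)
  a / (a + b)
}

naive_stats <- function(values, mask, cell_size) {
  vals <- c()
  for (r in seq_len(nrow(values))) {
    for (c in seq_len(ncol(values))) {
      if (mask[r, c]) vals <- c(vals, values[r, c])
    }
  }
  c(mean_pressure = mean(vals), peak_pressure = max(vals),
    total_force = sum(vals) * cell_size^2)
}

# Naive IDW: per cell, distances to every sensor, exact hits copy, otherwise
# normalised d^-power weights over the k nearest.
naive_idw <- function(positions, values, geometry, power, k, eps = 1e-12) {
  out <- matrix(0, geometry$n_rows, geometry$n_cols)
  for (r in seq_len(geometry$n_rows)) {
    for (c in seq_len(geometry$n_cols)) {
      cx <- (c - 1) * geometry$cell_size
      cy <- (r - 1) * geometry$cell_size
      d <- sqrt((positions[, "x"] - cx)^2 + (positions[, "y"] - cy)^2)
      if (any(d < eps)) {
        out[r, c] <- values[which(d < eps)[1]]
      } else {
        nb <- order(d)[seq_len(min(k, length(d)))]
        w <- d[nb]^(-power)
        out[r, c] <- sum(w * values[nb]) / sum(w)
      }
    }
  }
  out
}

# Naive per-class metrics straight from the printed formulas.
naive_metrics <- function(cm) {
  k <- nrow(cm)
  prec <- rec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  list(precision = prec, recall = rec, f1 = f1, macro_f1 = mean(f1))
}

# Region-membership trunk labelling oracle: explicit case analysis.
naive_trunk_label <- function(rot, inc, lat, dead_band = 10, split = 25) {
  dr <- abs(rot) / dead_band
  di <- abs(inc) / dead_band
  dl <- abs(lat) / dead_band
  if (max(dr, di, dl) <= 1) return("TP0")
  if (di >= dr && di >= dl) return("TP2")
  if (dr >= dl) return("TP3")
  if (abs(lat) > split) "TP4" else "TP1"
}

naive_nearest_zone <- function(x, y, zones) {
  best <- 1; bestd <- Inf
  for (i in seq_len(nrow(zones))) {
    d <- sqrt((x - zones$x[i])^2 + (y - zones$y[i])^2)
    if (d < bestd) { bestd <- d; best <- i }
  }
  zones$class[best]
}

# Naive full feature vector: per descriptor, masks + naive ops + the sentinel
# replacement rules (geometric centre for undefined CoP, 0.5 for undefined
# ratios).
naive_feature_vector <- function(bframe, sframe, fs) {
  desc <- fs$descriptors
  out <- numeric(nrow(desc))
  names(out) <- desc$name
  for (i in seq_len(nrow(desc))) {
    scheme <- if (desc$side[i] == "backrest") fs$backrest_scheme else fs$seatpan_scheme
    frame <- if (desc$side[i] == "backrest") bframe else sframe
    mask <- area_mask(scheme, desc$area[i])
    cs <- frame$geometry$cell_size
    out[i] <- switch(desc$kind[i],
      cop_x = {
        v <- naive_cop(frame$values, mask, cs)["x"]
        if (is.na(v)) mean(((which(mask, arr.ind = TRUE)[, 2]) - 1) * cs) else v
      },
      cop_y = {
        v <- naive_cop(frame$values, mask, cs)["y"]
        if (is.na(v)) mean(((which(mask, arr.ind = TRUE)[, 1]) - 1) * cs) else v
      },
      contact_area_proportion = naive_contact(frame$values, mask, fs$threshold),
      mean_pressure = naive_stats(frame$values, mask, cs)["mean_pressure"],
      peak_pressure = naive_stats(frame$values, mask, cs)["peak_pressure"],
      total_force = naive_stats(frame$values, mask, cs)["total_force"],
      pressure_ratio = {
        v <- naive_ratio(frame$values, mask, area_mask(scheme, desc$area2[i]))
        if (is.na(v)) 0.5 else v
      }
    )
  }
  out
}

random_frame <- function(geometry, density = 0.7) {
  v <- matrix(0, geometry$n_rows, geometry$n_cols)
  on <- runif(length(v)) < density
  v[on] <- runif(sum(on), 0, 10)
  pressure_frame(v, geometry)
}
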