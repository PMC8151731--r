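#' Extract relative features for every frame of a recording
#'
#' Computes the 200-candidate feature matrix for all frame pairs, estimates
#' each (subject, task) reference feature vector from the task's opening
#' standard-posture frames (mean over the first 0.5 s), and returns the
#' relative features (current minus reference) used for classification.
#'
#' @param recording A `bpd_recording`.
#' @param features A `feature_set`; defaults to the full 200-candidate
#'   manifest on the default segmentation.
#' @param ref_window Number of opening frames averaged into the reference;
#'   defaults to 0.5 s at the recording's frame rate.
#' @return List of class `posture_dataset`: `features` (relative), `absolute`,
#'   `labels`, and the `feature_set`.
#' @export
extract_posture_dataset <- function(recording, features = NULL,
                                    ref_window = NULL) {
  stopifnot(inherits(recording, "bpd_recording"))
  if (is.null(features)) {
    features <- enumerate_feature_set(
      default_segmentation(recording$backrest_geometry),
      default_segmentation(recording$seatpan_geometry),
      threshold = recording$spec$noise_floor %||% 0
    )
  }
  if (is.null(ref_window)) {
    fps <- recording$spec$fps %||% 25L
    ref_window <- max(1L, floor(0.5 * fps))
  }
  abs_feat <- compute_feature_matrix(recording$backrest, recording$seatpan,
                                     features)
  labels <- recording$labels
  rel <- abs_feat
  key <- paste(labels$subject_id, labels$task_id)
  for (k in unique(key)) {
    rows <- which(key == k)
    ref <- reference_features(abs_feat[rows, , drop = FALSE], ref_window)
    rel[rows, ] <- sweep(abs_feat[rows, , drop = FALSE], 2L, ref, `-`)
  }
  structure(list(features = rel, absolute = abs_feat, labels = labels,
                 feature_set = features),
            class = "posture_dataset")
}

#' Labeled samples for one body part
#'
#' Pairs the relative feature matrix with the body part's class labels and
#' (optionally) applies the intra-/inter-motion redundancy filter to drop
#' near-duplicate postures of the same subject.
#'
#' @param dataset A `posture_dataset`.
#' @param body_part `"trunk"`, `"left_foot"` or `"right_foot"`.
#' @param filter Apply [redundancy_filter()] (default `TRUE`).
#' @param ... Passed to [redundancy_filter()].
#' @return List with `x` (features), `y` (labels), `subjects`, `rows` (row
#'   indices into the dataset).
#' @export
part_samples <- function(dataset, body_part = c("trunk", "left_foot", "right_foot"),
                         filter = TRUE, ...) {
  body_part <- match.arg(body_part)
  labels <- dataset$labels
  labels$.row <- seq_len(nrow(labels))
  if (filter) labels <- redundancy_filter(labels, body_part, ...)
  rows <- labels$.row
  y <- labels[[body_part]]
  list(x = dataset$features[rows, , drop = FALSE], y = y,
       subjects = labels$subject_id, rows = rows)
}

part_classes <- function(body_part) {
  switch(body_part, trunk = trunk_classes(), left_foot = left_foot_classes(),
         right_foot = right_foot_classes())
}

#' Evaluate reduced sensor layouts against the full-resolution benchmark
#'
#' For each layout: sample every full-resolution frame at the layout's sensor
#' points (nearest-cell rule), reconstruct the full grids by inverse distance
#' weighting, recompute the *same* selected features from the reconstruction,
#' rerun leave-one-subject-out cross-validation per body part, and compare the
#' per-fold per-class F1 scores against the benchmark with a two-sided paired
#' t-test (pairing by held-out subject). Significance is flagged at p < 0.05
#' and p < 0.01.
#'
#' @param recording A `bpd_recording` with full-resolution frames.
#' @param selected Named list (`trunk`, `left_foot`, `right_foot`) of feature
#'   names used by each classifier.
#' @param levels Integer layout levels to evaluate (e.g. `1:5`).
#' @param layouts Optional list of `sensor_layout` objects overriding
#'   `levels` (e.g. [full_resolution_layout()] for an identity check); names
#'   are used as layout labels.
#' @param config Classifier configuration (default RF).
#' @param features Feature manifest; default as in [extract_posture_dataset()].
#' @param power,n_neighbors IDW reconstruction parameters.
#' @param seed Integer seed for training.
#' @return List of class `layout_benchmark`: `benchmark` (per-part
#'   `loso_result`s + pooled per-class F1), `layouts` (per layout: losos,
#'   per-class F1, paired-test table) and `table` (tidy per-layout, per-class
#'   F1 with p-values and significance flags).
#' @export
benchmark_layouts <- function(recording, selected, levels = 1:5,
                              layouts = NULL,
                              config = classifier_config("RF"),
                              features = NULL, power = 2, n_neighbors = 4L,
                              seed = 1L) {
  stopifnot(inherits(recording, "bpd_recording"))
  parts <- c("trunk", "left_foot", "right_foot")
  stopifnot(all(parts %in% names(selected)))
  if (is.null(layouts)) {
    layouts <- lapply(levels, generate_layout)
    names(layouts) <- paste0("D", levels)
  } else if (is.null(names(layouts))) {
    names(layouts) <- paste0("L", seq_along(layouts))
  }
  dataset <- extract_posture_dataset(recording, features)
  features <- dataset$feature_set

  run_parts <- function(ds) {
    out <- list()
    for (p in parts) {
      s <- part_samples(ds, p)
      out[[p]] <- loso_cv(s$x[, selected[[p]], drop = FALSE], s$y, s$subjects,
                          config = config, seed = seed,
                          classes = part_classes(p))
    }
    out
  }
  bench <- run_parts(dataset)

  reconstruct_recording <- function(layout) {
    rec <- recording
    for (side in c("backrest", "seatpan")) {
      g <- recording[[paste0(side, "_geometry")]]
      snap <- snap_to_cells(layout, g)
      W <- idw_operator(layout, g, power = power, n_neighbors = n_neighbors)
      rec[[side]] <- as.matrix(W %*% recording[[side]][snap$cell, , drop = FALSE])
    }
    rec
  }

  per_layout <- list()
  table_rows <- list()
  for (ln in names(layouts)) {
    rec_l <- reconstruct_recording(layouts[[ln]])
    ds_l <- extract_posture_dataset(rec_l, features)
    losos <- run_parts(ds_l)
    for (p in parts) {
      pc <- losos[[p]]$report$per_class
      for (ci in seq_len(nrow(pc))) {
        cls <- pc$class[ci]
        ht <- paired_fold_test(losos[[p]]$fold_f1[cls, ],
                               bench[[p]]$fold_f1[cls, ])
        table_rows[[length(table_rows) + 1L]] <- data.frame(
          layout = ln, class = cls, f1 = pc$f1[ci],
          benchmark_f1 = bench[[p]]$report$per_class$f1[ci],
          t = ht$t, p_value = ht$p,
          flag = if (is.na(ht$p)) "" else if (ht$p < 0.01) "**"
                 else if (ht$p < 0.05) "*" else "",
          stringsAsFactors = FALSE
        )
      }
    }
    per_layout[[ln]] <- losos
  }
  tab <- do.call(rbind, table_rows)
  structure(list(benchmark = bench, layouts = per_layout, table = tab),
            class = "layout_benchmark")
}

#' Pooled per-class F1 across the three body-part classifiers
#'
#' @param losos Named list of `loso_result`s (`trunk`, `left_foot`,
#'   `right_foot`).
#' @return Data frame of the 10 classes with their F1 scores, plus the
#'   unweighted average as attribute `macro_f1`.
#' @export
pooled_class_f1 <- function(losos) {
  pc <- do.call(rbind, lapply(losos, function(l) l$report$per_class))
  rownames(pc) <- NULL
  structure(pc[, c("class", "support", "f1")], macro_f1 = mean(pc$f1))
}

#' Pipeline configuration
#'
#' @param spec A [scenario_spec()]; defaults to the standard scenario with its
#'   seed replaced by `seed`.
#' @param thresholds A [posture_thresholds()].
#' @param config Classifier configuration (default RF).
#' @param n_features Number of top-ranked features per body part when
#'   `selection = "fixed"`.
#' @param selection `"fixed"` keeps the top `n_features` of the importance
#'   ranking; `"curve"` runs [select_features()] per body part.
#' @param levels Layout levels to benchmark (empty = skip the benchmark).
#' @param power,n_neighbors IDW parameters.
#' @param seed Master seed: drives the scenario and all training.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, thresholds = posture_thresholds(),
                            config = classifier_config("RF"),
                            n_features = 30L,
                            selection = c("fixed", "curve"),
                            levels = integer(0), power = 2, n_neighbors = 4L,
                            seed = 20210512L) {
  selection <- match.arg(selection)
  if (is.null(spec)) spec <- scenario_spec(seed = seed)
  structure(list(spec = spec, thresholds = thresholds, config = config,
                 n_features = as.integer(n_features), selection = selection,
                 levels = levels, power = power,
                 n_neighbors = as.integer(n_neighbors),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full posture-monitoring pipeline
#'
#' Simulate (or reuse) a recording, extract relative features, rank them by
#' OOB permutation importance per body part, select a feature subset, run
#' leave-one-subject-out cross-validation, and (optionally) benchmark reduced
#' sensor layouts against the full-resolution result. Identical configuration
#' and seeds produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @param recording Optional pre-generated `bpd_recording` (skips simulation).
#' @return List of class `pipeline_report`: `class_f1` (the 10 posture
#'   classes), `macro_f1`, per-part `losos`, `rankings`, `selected`,
#'   `curves` (when `selection = "curve"`), `benchmark` (when `levels`
#'   non-empty), and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), recording = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(recording)) {
    recording <- generate_dataset(config$spec, thresholds = config$thresholds)
  }
  dataset <- extract_posture_dataset(recording)
  parts <- c("trunk", "left_foot", "right_foot")
  rankings <- list(); selected <- list(); curves <- list(); losos <- list()
  for (p in parts) {
    s <- part_samples(dataset, p)
    rk <- oob_importance(s$x, s$y, config$config, seed = config$seed)
    rankings[[p]] <- rk
    if (config$selection == "curve") {
      cv <- select_features(rk$feature, s$x, s$y, s$subjects,
                            config = config$config, seed = config$seed)
      curves[[p]] <- cv
      selected[[p]] <- cv$best_features
    } else {
      selected[[p]] <- rk$feature[seq_len(min(config$n_features,
                                              nrow(rk)))]
    }
    losos[[p]] <- loso_cv(s$x[, selected[[p]], drop = FALSE], s$y, s$subjects,
                          config = config$config, seed = config$seed,
                          classes = part_classes(p))
  }
  class_f1 <- pooled_class_f1(losos)
  bench <- NULL
  if (length(config$levels) > 0L) {
    bench <- benchmark_layouts(recording, selected, levels = config$levels,
                               config = config$config, power = config$power,
                               n_neighbors = config$n_neighbors,
                               seed = config$seed)
  }
  structure(list(class_f1 = class_f1, macro_f1 = attr(class_f1, "macro_f1"),
                 losos = losos, rankings = rankings, selected = selected,
                 curves = curves, benchmark = bench,
                 config_hash = config_hash(config)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$class_f1, row.names = FALSE)
  cat(sprintf("macro F1 across the %d classes: %.3f\n",
              nrow(x$class_f1), x$macro_f1))
  if (!is.null(x$benchmark)) {
    cat("layout benchmark (per-class F1 vs full mats):\n")
    print(x$benchmark$table, row.names = FALSE)
  }
  cat("config hash:", x$config_hash, "\n")
  invisible(x)
}
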