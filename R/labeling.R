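#' Posture class thresholds
#'
#' Configuration for kinematics-based labelling. Trunk classes are defined by
#' three angles (rotation, inclination, lateral tilt, in degrees) relative to
#' the task-initial standard trunk position TP0:
#' * TP0 — all three |angles| within the dead band (default 10 deg);
#' * TP2 — inclination-dominant deviation (forward/backward lean);
#' * TP3 — rotation-dominant deviation;
#' * TP1 / TP4 — lateral-tilt-dominant deviation, TP1 for |tilt| up to
#'   `lateral_split` (default 25 deg), TP4 beyond it.
#'
#' When several angles exceed the dead band, the largest normalised deviation
#' (|angle| / dead band) wins; exact ties resolve in the fixed order
#' inclination (TP2) > rotation (TP3) > lateral tilt (TP1/TP4).
#'
#' Foot classes are assigned by nearest reference zone in the floor plane (cm):
#' right foot RFP0 accelerator / RFP1 brake / RFP2 floor; left foot LFP0 floor
#' / LFP1 clutch.
#'
#' @param dead_band TP0 half-width for all three angles, degrees.
#' @param lateral_split Lateral-tilt boundary between TP1 and TP4, degrees.
#' @param right_zones,left_zones Data frames with columns `class`, `x`, `y`
#'   giving each zone's reference point in cm.
#' @return A list of class `posture_thresholds`.
#' @export
posture_thresholds <- function(dead_band = 10, lateral_split = 25,
                               right_zones = NULL, left_zones = NULL) {
  if (is.null(right_zones)) {
    right_zones <- data.frame(class = c("RFP0", "RFP1", "RFP2"),
                              x = c(0, -12, -25), y = c(0, 0, -12),
                              stringsAsFactors = FALSE)
  }
  if (is.null(left_zones)) {
    left_zones <- data.frame(class = c("LFP0", "LFP1"),
                             x = c(0, 12), y = c(0, 8),
                             stringsAsFactors = FALSE)
  }
  stopifnot(dead_band > 0, lateral_split > dead_band)
  structure(list(dead_band = dead_band, lateral_split = lateral_split,
                 right_zones = right_zones, left_zones = left_zones),
            class = "posture_thresholds")
}

#' Trunk posture class levels
#' @export
trunk_classes <- function() c("TP0", "TP1", "TP2", "TP3", "TP4")

#' Left-foot posture class levels
#' @export
left_foot_classes <- function() c("LFP0", "LFP1")

#' Right-foot posture class levels
#' @export
right_foot_classes <- function() c("RFP0", "RFP1", "RFP2")

#' Label a trunk posture from its three angles
#'
#' @param rotation,inclination,lateral_tilt Trunk angles in degrees relative
#'   to the standard trunk position (vectorised).
#' @param thresholds A [posture_thresholds()].
#' @return Character vector of trunk classes (`"TP0"`..`"TP4"`).
#' @examples
#' label_trunk(0, 0, 0)          # "TP0"
#' label_trunk(0, 20, 0)         # "TP2"
#' @export
label_trunk <- function(rotation, inclination, lateral_tilt,
                        thresholds = posture_thresholds()) {
  db <- thresholds$dead_band
  # normalised deviations, evaluated in the precedence order TP2 > TP3 > TP1/TP4
  dev <- cbind(inclination = abs(inclination) / db,
               rotation = abs(rotation) / db,
               lateral = abs(lateral_tilt) / db)
  out <- rep("TP0", nrow(dev))
  beyond <- apply(dev, 1L, max) > 1
  winner <- apply(dev, 1L, which.max)      # stable: first max wins ties
  out[beyond & winner == 1L] <- "TP2"
  out[beyond & winner == 2L] <- "TP3"
  lat <- beyond & winner == 3L
  out[lat] <- ifelse(abs(lateral_tilt[lat]) > thresholds$lateral_split,
                     "TP4", "TP1")
  out
}

#' Label foot postures by nearest reference zone
#'
#' @param left_x,left_y,right_x,right_y Foot-centre coordinates in cm in the
#'   floor plane (vectorised).
#' @param thresholds A [posture_thresholds()].
#' @return List with character vectors `left` (`"LFP0"`/`"LFP1"`) and `right`
#'   (`"RFP0"`..`"RFP2"`).
#' @export
label_feet <- function(left_x, left_y, right_x, right_y,
                       thresholds = posture_thresholds()) {
  list(left = nearest_zone(left_x, left_y, thresholds$left_zones),
       right = nearest_zone(right_x, right_y, thresholds$right_zones))
}

nearest_zone <- function(x, y, zones) {
  d2 <- outer(x, zones$x, `-`)^2 + outer(y, zones$y, `-`)^2
  zones$class[apply(d2, 1L, which.min)]
}

#' Intra-/inter-motion redundancy filter
#'
#' Removes near-duplicate postures of the same subject before classifier
#' training. A greedy temporal pass keeps a sample if and only if it differs
#' from *every* previously kept sample of that subject: two trunk postures
#' differ when at least one of the three trunk angles differs by more than
#' `angle_threshold` (3 degrees); two foot positions differ when the Euclidean
#' distance between the foot centres exceeds `distance_threshold` (2 cm).
#' Filtering is performed independently per body part: the trunk filter never
#' consults foot data and vice versa.
#'
#' @param samples Data frame with a `subject_id` column, a `frame_index`
#'   column (temporal order within subject; must be non-decreasing), and the
#'   kinematic columns of the body part.
#' @param body_part `"trunk"` (columns `rotation`, `inclination`,
#'   `lateral_tilt`), `"left_foot"` (columns `left_x`, `left_y`) or
#'   `"right_foot"` (`right_x`, `right_y`).
#' @param angle_threshold Trunk similarity threshold, degrees.
#' @param distance_threshold Foot similarity threshold, cm.
#' @param compare `"all"` (default) compares each candidate against every
#'   previously kept sample; `"last"` against only the most recently kept one.
#' @return The filtered subset of `samples` (rows preserved in order).
#' @export
redundancy_filter <- function(samples, body_part = c("trunk", "left_foot", "right_foot"),
                              angle_threshold = 3, distance_threshold = 2,
                              compare = c("all", "last")) {
  body_part <- match.arg(body_part)
  compare <- match.arg(compare)
  cols <- switch(body_part,
                 trunk = c("rotation", "inclination", "lateral_tilt"),
                 left_foot = c("left_x", "left_y"),
                 right_foot = c("right_x", "right_y"))
  if (!all(c("subject_id", "frame_index", cols) %in% names(samples))) {
    stop("samples must contain subject_id, frame_index and ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  keep <- logical(nrow(samples))
  for (sid in unique(samples$subject_id)) {
    rows <- which(samples$subject_id == sid)
    fi <- samples$frame_index[rows]
    if (is.unsorted(fi)) {
      stop("samples of subject ", sid, " are not in temporal order", call. = FALSE)
    }
    vals <- as.matrix(samples[rows, cols, drop = FALSE])
    kept <- integer(0)
    for (i in seq_along(rows)) {
      against <- if (compare == "last" && length(kept) > 0L) {
        kept[length(kept)]
      } else kept
      if (length(against) == 0L) {
        kept <- c(kept, i)
        next
      }
      if (body_part == "trunk") {
        # differs from a kept sample iff some angle gap exceeds the threshold
        similar <- vapply(against, function(j) {
          all(abs(vals[i, ] - vals[j, ]) <= angle_threshold)
        }, logical(1))
      } else {
        similar <- vapply(against, function(j) {
          sqrt(sum((vals[i, ] - vals[j, ])^2)) <= distance_threshold
        }, logical(1))
      }
      if (!any(similar)) kept <- c(kept, i)
    }
    keep[rows[kept]] <- TRUE
  }
  samples[keep, , drop = FALSE]
}
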