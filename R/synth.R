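#' Subject profile for the synthetic generator
#'
#' Anthropometric variation is emulated by a global pressure multiplier
#' (`mass_scale`), a lobe-spread multiplier (`width_scale`) and a small
#' normalised seating offset (`seat_shift`).
#'
#' @param subject_id Identifier.
#' @param mass_scale,width_scale Positive multipliers, both within
#'   \[0.6, 1.6\].
#' @param seat_shift Length-2 numeric `(du, dv)`, each within ±0.08.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "s1", mass_scale = 1,
                            width_scale = 1, seat_shift = c(0, 0)) {
  if (mass_scale < 0.6 || mass_scale > 1.6 ||
      width_scale < 0.6 || width_scale > 1.6) {
    stop("subject scales must lie in [0.6, 1.6]", call. = FALSE)
  }
  if (any(abs(seat_shift) > 0.08)) {
    stop("seat_shift components must lie within +/- 0.08", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 mass_scale = mass_scale, width_scale = width_scale,
                 seat_shift = seat_shift),
            class = "subject_profile")
}

#' Draw a roster of random subject profiles
#'
#' @param n Number of subjects.
#' @return List of [subject_profile()]s (uses the current RNG state).
#' @export
random_subject_profiles <- function(n) {
  lapply(seq_len(n), function(i) {
    subject_profile(sprintf("s%02d", i),
                    mass_scale = stats::runif(1, 0.7, 1.4),
                    width_scale = stats::runif(1, 0.85, 1.2),
                    seat_shift = stats::runif(2, -0.05, 0.05))
  })
}

#' Gaussian-lobe body contact model
#'
#' The synthetic body pressure distribution is a sum of anisotropic (axis
#' aligned, hence separable) Gaussian lobes in normalised mat coordinates:
#' two ischial and two thigh lobes on the seat pan, two scapular lobes and one
#' lumbar lobe on the backrest. The base configuration is left-right mirror
#' symmetric. `gains` encodes how kinematics deform the lobes:
#' forward inclination attenuates all backrest amplitudes and shifts the seat
#' load forward while loading the thighs; lateral tilt translates all lobes
#' laterally; trunk rotation loads one scapula and unloads the other; moving a
#' foot away from its standard zone translates and attenuates the
#' corresponding thigh lobe.
#'
#' @return A list of class `body_contact_model` with `seatpan` and `backrest`
#'   lobe tables (`name`, `u`, `v`, `amp`, `su`, `sv`) and a `gains` list.
#' @export
body_contact_model <- function() {
  seatpan <- data.frame(
    name = c("ischial_l", "ischial_r", "thigh_l", "thigh_r"),
    u = c(0.38, 0.62, 0.30, 0.70),
    v = c(0.62, 0.62, 0.28, 0.28),
    amp = c(100, 100, 55, 55),
    su = c(0.10, 0.10, 0.09, 0.09),
    sv = c(0.09, 0.09, 0.16, 0.16),
    stringsAsFactors = FALSE
  )
  backrest <- data.frame(
    name = c("scap_l", "scap_r", "lumbar"),
    u = c(0.35, 0.65, 0.50),
    v = c(0.28, 0.28, 0.78),
    amp = c(70, 70, 85),
    su = c(0.11, 0.11, 0.16),
    sv = c(0.13, 0.13, 0.10),
    stringsAsFactors = FALSE
  )
  gains <- list(
    incl_backrest_rate = 1 / 15,  # per degree, exponential amplitude decay
    incl_seat_vshift = 0.003,     # normalised v per degree (forward = -v)
    incl_thigh_rate = 0.010,      # relative thigh amplitude per degree
    lat_ushift = 0.004,           # normalised u per degree of lateral tilt
    rot_scap_rate = 0.015,        # relative scapular asymmetry per degree
    foot_ushift = 0.004,          # normalised u per cm of foot displacement
    foot_vshift = 0.004,
    right_foot_amp_rate = 0.020,  # exponential thigh decay per cm from pedal
    left_foot_amp_rate = 0.015
  )
  structure(list(seatpan = seatpan, backrest = backrest, gains = gains),
            class = "body_contact_model")
}

# Deform the lobe tables according to kinematics; returns the two tables.
deform_lobes <- function(model, kin, subject) {
  g <- model$gains
  sl <- model$seatpan
  bl <- model$backrest
  # subject anthropometry
  sl$amp <- sl$amp * subject$mass_scale
  bl$amp <- bl$amp * subject$mass_scale
  sl$su <- sl$su * subject$width_scale; sl$sv <- sl$sv * subject$width_scale
  bl$su <- bl$su * subject$width_scale; bl$sv <- bl$sv * subject$width_scale
  sl$u <- sl$u + subject$seat_shift[1]; sl$v <- sl$v + subject$seat_shift[2]
  bl$u <- bl$u + subject$seat_shift[1]; bl$v <- bl$v + subject$seat_shift[2]
  # trunk inclination (positive = forward lean)
  bl$amp <- bl$amp * exp(-kin$inclination * g$incl_backrest_rate)
  sl$v <- sl$v - kin$inclination * g$incl_seat_vshift
  thigh <- grepl("^thigh", sl$name)
  sl$amp[thigh] <- sl$amp[thigh] * pmax(1 + kin$inclination * g$incl_thigh_rate, 0.1)
  # lateral tilt (positive = towards the right)
  sl$u <- sl$u + kin$lateral_tilt * g$lat_ushift
  bl$u <- bl$u + kin$lateral_tilt * g$lat_ushift
  # trunk rotation: asymmetric scapular loading
  bl$amp[bl$name == "scap_l"] <- bl$amp[bl$name == "scap_l"] *
    pmax(1 + kin$rotation * g$rot_scap_rate, 0.05)
  bl$amp[bl$name == "scap_r"] <- bl$amp[bl$name == "scap_r"] *
    pmax(1 - kin$rotation * g$rot_scap_rate, 0.05)
  # feet: displacement from the standard zone deforms the same-side thigh lobe
  rdist <- sqrt(kin$right_x^2 + kin$right_y^2)
  i <- sl$name == "thigh_r"
  sl$u[i] <- sl$u[i] + kin$right_x * g$foot_ushift
  sl$v[i] <- sl$v[i] - kin$right_y * g$foot_vshift
  sl$amp[i] <- sl$amp[i] * exp(-rdist * g$right_foot_amp_rate)
  ldist <- sqrt(kin$left_x^2 + kin$left_y^2)
  i <- sl$name == "thigh_l"
  sl$u[i] <- sl$u[i] - kin$left_x * g$foot_ushift
  sl$v[i] <- sl$v[i] - kin$left_y * g$foot_vshift
  sl$amp[i] <- sl$amp[i] * exp(-ldist * g$left_foot_amp_rate)
  list(seatpan = sl, backrest = bl)
}

# Render one lobe table on a geometry (noise-free signal matrix).
render_lobes <- function(lobes, geometry) {
  cc <- cell_centers(geometry)
  xr <- (geometry$n_cols - 1) * geometry$cell_size
  yr <- (geometry$n_rows - 1) * geometry$cell_size
  vals <- matrix(0, geometry$n_rows, geometry$n_cols)
  for (i in seq_len(nrow(lobes))) {
    cx <- lobes$u[i] * xr; cy <- lobes$v[i] * yr
    sx <- lobes$su[i] * xr; sy <- lobes$sv[i] * yr
    gx <- exp(-(cc$x - cx)^2 / (2 * sx^2))
    gy <- exp(-(cc$y - cy)^2 / (2 * sy^2))
    vals <- vals + lobes$amp[i] * (gy %o% gx)
  }
  vals
}

#' Render one synthetic frame pair
#'
#' Produces the backrest and seat-pan pressure frames for a given posture.
#' The signal is a sum of Gaussian contact lobes deformed by the kinematics
#' (see [body_contact_model()]); optional multiplicative sensor noise
#' (`value * (1 + noise_sd * N(0,1))`, clipped at 0, applied to loaded cells
#' only) and a constant additive `noise_floor` complete the measurement model.
#' The kinematics must be consistent with `label` under `thresholds`,
#' otherwise an error is raised.
#'
#' @param label List with `trunk`, `left_foot`, `right_foot` class names.
#' @param kinematics List with `rotation`, `inclination`, `lateral_tilt`
#'   (degrees) and `left_x`, `left_y`, `right_x`, `right_y` (cm).
#' @param subject A [subject_profile()].
#' @param model A [body_contact_model()].
#' @param noise_sd Multiplicative noise standard deviation (fraction of local
#'   signal).
#' @param noise_floor Additive constant pressure on every cell.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @param thresholds A [posture_thresholds()].
#' @param backrest_geometry,seatpan_geometry Mat geometries.
#' @return List with `backrest` and `seatpan` [pressure_frame()]s.
#' @export
render_frames <- function(label, kinematics, subject = subject_profile(),
                          model = body_contact_model(), noise_sd = 0,
                          noise_floor = 0, seed = NULL,
                          thresholds = posture_thresholds(),
                          backrest_geometry = mat_geometry("backrest"),
                          seatpan_geometry = mat_geometry("seatpan")) {
  check_label_consistency(label, kinematics, thresholds)
  if (!is.null(seed)) set.seed(seed)
  lobes <- deform_lobes(model, kinematics, subject)
  b <- render_lobes(lobes$backrest, backrest_geometry)
  s <- render_lobes(lobes$seatpan, seatpan_geometry)
  if (noise_sd > 0) {
    b <- pmax(b * (1 + noise_sd * matrix(stats::rnorm(length(b)), nrow(b))), 0)
    s <- pmax(s * (1 + noise_sd * matrix(stats::rnorm(length(s)), nrow(s))), 0)
  }
  list(backrest = pressure_frame(b + noise_floor, backrest_geometry,
                                 subject_id = subject$subject_id),
       seatpan = pressure_frame(s + noise_floor, seatpan_geometry,
                                subject_id = subject$subject_id))
}

check_label_consistency <- function(label, kin, thresholds) {
  tl <- label_trunk(kin$rotation, kin$inclination, kin$lateral_tilt, thresholds)
  fl <- label_feet(kin$left_x, kin$left_y, kin$right_x, kin$right_y, thresholds)
  if (tl != label$trunk || fl$left != label$left_foot ||
      fl$right != label$right_foot) {
    stop(sprintf("kinematics imply (%s, %s, %s) but label is (%s, %s, %s)",
                 tl, fl$left, fl$right,
                 label$trunk, label$left_foot, label$right_foot),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Scenario specification for the synthetic generator
#'
#' The default scenario is a desk-scale stand-in for an instrumented-seat
#' campaign: 10 subjects performing 10 tasks of 60 frames at 25 fps. Every
#' task opens (13 frames, so a full 0.5 s reference window is available) and
#' closes (5 frames) with the standard posture (TP0, LFP0, RFP0); the middle
#' segment holds one target posture whose per-frame kinematics are drawn
#' uniformly from the class band with a safety margin (10% of the band width)
#' inside the class boundaries. The task schedule cycles through the classes
#' so all 10 posture classes are visited.
#'
#' @param n_subjects,tasks_per_subject,frames_per_task Scenario size.
#' @param fps Frame rate (frames per second).
#' @param noise_sd Multiplicative sensor noise level (default 0.15).
#' @param noise_floor Additive constant pressure (default 0).
#' @param seed Integer seed governing all randomness of the scenario.
#' @param opening,closing Number of standard-posture frames at the start/end
#'   of each task.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_subjects = 10L, tasks_per_subject = 10L,
                          frames_per_task = 60L, fps = 25L, noise_sd = 0.15,
                          noise_floor = 0, seed = 20210512L,
                          opening = 13L, closing = 5L) {
  stopifnot(n_subjects >= 1L, tasks_per_subject >= 1L,
            frames_per_task > opening + closing, noise_sd >= 0,
            noise_floor >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 tasks_per_subject = as.integer(tasks_per_subject),
                 frames_per_task = as.integer(frames_per_task),
                 fps = as.integer(fps), noise_sd = noise_sd,
                 noise_floor = noise_floor, seed = as.integer(seed),
                 opening = as.integer(opening), closing = as.integer(closing)),
            class = "scenario_spec")
}

#' Default task schedule
#'
#' Target posture per task: trunk classes cycle TP0..TP4, left foot
#' alternates LFP0/LFP1 and right foot cycles RFP0..RFP2, so ten tasks cover
#' all ten classes with every trunk class targeted twice.
#'
#' @param n_tasks Number of tasks.
#' @return Data frame with columns `trunk`, `left_foot`, `right_foot`.
#' @export
default_task_schedule <- function(n_tasks) {
  i <- seq_len(n_tasks) - 1L
  data.frame(trunk = trunk_classes()[i %% 5L + 1L],
             left_foot = left_foot_classes()[i %% 2L + 1L],
             right_foot = right_foot_classes()[i %% 3L + 1L],
             stringsAsFactors = FALSE)
}

# Draw kinematics for given classes. Margin: 10% of each band width inside
# the class boundaries; non-dominant trunk angles stay within the dead band
# minus its margin so the intended angle always dominates.
draw_kinematics <- function(trunk, left_foot, right_foot,
                            thresholds = posture_thresholds(),
                            max_angle = 40, standard = FALSE) {
  db <- thresholds$dead_band
  split <- thresholds$lateral_split
  inner <- function() stats::runif(1, -0.8 * db, 0.8 * db)
  signed <- function(lo, hi) sample(c(-1, 1), 1) * stats::runif(1, lo, hi)
  rot <- incl <- lat <- 0
  if (standard) {
    rot <- stats::runif(1, -0.3 * db, 0.3 * db)
    incl <- stats::runif(1, -0.3 * db, 0.3 * db)
    lat <- stats::runif(1, -0.3 * db, 0.3 * db)
  } else if (trunk == "TP0") {
    rot <- inner(); incl <- inner(); lat <- inner()
  } else if (trunk == "TP2") {
    m <- 0.1 * (max_angle - db)
    incl <- signed(db + m, max_angle - m); rot <- inner(); lat <- inner()
  } else if (trunk == "TP3") {
    m <- 0.1 * (max_angle - db)
    rot <- signed(db + m, max_angle - m); incl <- inner(); lat <- inner()
  } else if (trunk == "TP1") {
    m <- 0.1 * (split - db)
    lat <- signed(db + m, split - m); rot <- inner(); incl <- inner()
  } else if (trunk == "TP4") {
    m <- 0.1 * (max_angle - split)
    lat <- signed(split + m, max_angle - m); rot <- inner(); incl <- inner()
  } else stop("unknown trunk class: ", trunk, call. = FALSE)
  zone_draw <- function(zones, cls, radius = 3) {
    z <- zones[zones$class == cls, ]
    r <- radius * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
    c(x = z$x + r * cos(a), y = z$y + r * sin(a))
  }
  lf <- zone_draw(thresholds$left_zones, if (standard) "LFP0" else left_foot)
  rf <- zone_draw(thresholds$right_zones, if (standard) "RFP0" else right_foot)
  list(rotation = rot, inclination = incl, lateral_tilt = lat,
       left_x = unname(lf["x"]), left_y = unname(lf["y"]),
       right_x = unname(rf["x"]), right_y = unname(rf["y"]))
}

#' Generate a synthetic recording bundle
#'
#' Simulates the full campaign described by a [scenario_spec()]: per subject,
#' a roster profile is drawn, and each task renders its frame sequence
#' (standard opening, target posture segment, standard closing). Labels are
#' derived from the drawn kinematics through [label_trunk()]/[label_feet()],
#' so stored labels and kinematics can never disagree. Deterministic given
#' the spec's seed.
#'
#' @param spec A [scenario_spec()].
#' @param thresholds A [posture_thresholds()].
#' @param model A [body_contact_model()].
#' @param schedule Task schedule data frame (recycled over tasks); defaults to
#'   [default_task_schedule()].
#' @return A list of class `bpd_recording` with `backrest` and `seatpan`
#'   (vectorised frames: `n_cells` x `n_frames` matrices), `labels` (one row
#'   per frame: ids, kinematics, classes, `is_standard`), `profiles`,
#'   geometries and the `spec`.
#' @export
generate_dataset <- function(spec = scenario_spec(),
                             thresholds = posture_thresholds(),
                             model = body_contact_model(),
                             schedule = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(schedule)) schedule <- default_task_schedule(spec$tasks_per_subject)
  bg <- mat_geometry("backrest")
  sg <- mat_geometry("seatpan")
  set.seed(spec$seed)
  profiles <- random_subject_profiles(spec$n_subjects)
  n_total <- spec$n_subjects * spec$tasks_per_subject * spec$frames_per_task
  B <- matrix(0, n_cells(bg), n_total)
  S <- matrix(0, n_cells(sg), n_total)
  rows <- vector("list", n_total)
  col <- 0L
  for (si in seq_len(spec$n_subjects)) {
    subj <- profiles[[si]]
    subj_frame <- 0L
    for (ti in seq_len(spec$tasks_per_subject)) {
      tgt <- schedule[(ti - 1L) %% nrow(schedule) + 1L, ]
      for (fi in seq_len(spec$frames_per_task)) {
        standard <- fi <= spec$opening ||
          fi > spec$frames_per_task - spec$closing
        kin <- draw_kinematics(tgt$trunk, tgt$left_foot, tgt$right_foot,
                               thresholds, standard = standard)
        lab <- list(
          trunk = label_trunk(kin$rotation, kin$inclination,
                              kin$lateral_tilt, thresholds),
          left_foot = NA, right_foot = NA
        )
        fl <- label_feet(kin$left_x, kin$left_y, kin$right_x, kin$right_y,
                         thresholds)
        lab$left_foot <- fl$left; lab$right_foot <- fl$right
        fr <- render_frames(lab, kin, subj, model,
                            noise_sd = spec$noise_sd,
                            noise_floor = spec$noise_floor,
                            thresholds = thresholds,
                            backrest_geometry = bg, seatpan_geometry = sg)
        col <- col + 1L
        subj_frame <- subj_frame + 1L
        B[, col] <- as.vector(fr$backrest$values)
        S[, col] <- as.vector(fr$seatpan$values)
        rows[[col]] <- data.frame(
          subject_id = subj$subject_id,
          task_id = sprintf("t%02d", ti),
          frame_index = subj_frame,
          rotation = kin$rotation, inclination = kin$inclination,
          lateral_tilt = kin$lateral_tilt,
          left_x = kin$left_x, left_y = kin$left_y,
          right_x = kin$right_x, right_y = kin$right_y,
          trunk = lab$trunk, left_foot = lab$left_foot,
          right_foot = lab$right_foot,
          is_standard = standard,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(spec = spec, backrest_geometry = bg, seatpan_geometry = sg,
                 backrest = B, seatpan = S,
                 labels = do.call(rbind, rows), profiles = profiles),
            class = "bpd_recording")
}

#' @export
print.bpd_recording <- function(x, ...) {
  cat(sprintf("<bpd_recording> %d subjects, %d frames (%d per task), noise_sd %.2f\n",
              x$spec$n_subjects, ncol(x$backrest), x$spec$frames_per_task,
              x$spec$noise_sd))
  invisible(x)
}

#' Write / read a recording bundle as plain text
#'
#' The bundle directory holds `backrest.txt` and `seatpan.txt` (frame grids
#' separated by `# frame` header blocks) and `labels.tsv` (the per-frame label
#' table: ids, trunk angles in degrees, foot centres in cm, classes).
#'
#' @param recording A `bpd_recording`.
#' @param dir Directory (created if needed).
#' @return `dir` invisibly / the recording.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_side <- function(M, geometry, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (j in seq_len(ncol(M))) {
      lab <- recording$labels[j, ]
      writeLines(c(sprintf("# subject: %s", lab$subject_id),
                   sprintf("# task: %s", lab$task_id),
                   sprintf("# frame: %d", lab$frame_index)), con)
      m <- matrix(M[, j], geometry$n_rows, geometry$n_cols)
      writeLines(apply(m, 1L, function(r) paste(format(r, digits = 8,
        trim = TRUE, scientific = FALSE), collapse = " ")), con)
      writeLines("", con)
    }
  }
  write_side(recording$backrest, recording$backrest_geometry,
             file.path(dir, "backrest.txt"))
  write_side(recording$seatpan, recording$seatpan_geometry,
             file.path(dir, "seatpan.txt"))
  utils::write.table(recording$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  bg <- mat_geometry("backrest")
  sg <- mat_geometry("seatpan")
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              stringsAsFactors = FALSE)
  read_side <- function(path, geometry, n_frames) {
    lines <- readLines(path)
    data_idx <- !grepl("^#", lines) & nzchar(trimws(lines))
    vals <- lines[data_idx]
    stopifnot(length(vals) == n_frames * geometry$n_rows)
    M <- matrix(0, n_cells(geometry), n_frames)
    for (j in seq_len(n_frames)) {
      block <- vals[((j - 1L) * geometry$n_rows + 1L):(j * geometry$n_rows)]
      m <- do.call(rbind, lapply(block, function(l)
        as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
      M[, j] <- as.vector(m)
    }
    M
  }
  n_frames <- nrow(labels)
  structure(list(spec = NULL, backrest_geometry = bg, seatpan_geometry = sg,
                 backrest = read_side(file.path(dir, "backrest.txt"), bg, n_frames),
                 seatpan = read_side(file.path(dir, "seatpan.txt"), sg, n_frames),
                 labels = labels, profiles = NULL),
            class = "bpd_recording")
}
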