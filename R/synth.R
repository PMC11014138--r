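# Synthetic IMU generator. Emulates the two acquisition protocols of the
# study design: a separate-execution training protocol (three single-task
# acquisitions per repetition) and a continuous-circuit test protocol
# (S2S -> W -> TN -> W -> LD in one stream), including the turn-direction
# discrepancy between them (training turns counterclockwise, the circuit
# clockwise) that shows up only in the magnetometer and in the sign of the
# yaw rate.
#
# Forward model, per site:
#   acc  = gravity projected through the pitch program (g units)
#          + gait/step oscillation + event transients + noise
#   gyro = Euler-angle rates (rad/s): yaw rate on y (vertical axis),
#          pitch rate on z + small oscillation + noise
#   mag  = stylized geomagnetic response: axes that are sensitive to the
#          execution direction carry a purely odd component
#          A * sin(signed angle program); direction-invariant axes carry
#          oscillation/sustained shifts only. This idealisation makes the
#          train/test discrepancy an exact sign inversion of the turning
#          magnetometer x/z axes and of the sit-to-stand x/y axes, while
#          accelerometer and gyroscope statistics stay direction-independent
#          up to the yaw-rate sign.

#' Subject profile for the synthetic generator
#'
#' Per-subject kinematic parameters: per-site/modality amplitude scaling,
#' gait frequency, activity durations, turn direction and sensor noise.
#'
#' @param subject_id identifier string.
#' @param amplitude_scale 4 x 3 numeric matrix (sites x modalities) of
#'   positive multipliers.
#' @param gait_frequency_hz stride frequency in Hz, in `[1.4, 2.2]`.
#' @param activity_duration_s named numeric vector of durations (seconds)
#'   for `W` (one 7 m leg), `TN`, `S2S`, `LD`; walking must last longer than
#'   sit-to-stand (this is the source of the class imbalance the balancing
#'   augmentation compensates).
#' @param turn_direction `"ccw"` (separate protocol) or `"cw"` (circuit).
#' @param noise_sd additive Gaussian sensor noise, standard deviation in
#'   normalized signal units.
#' @param phase_offset gait phase offset in radians.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            amplitude_scale = default_amplitude_scale(),
                            gait_frequency_hz = 1.8,
                            activity_duration_s = c(W = 5, TN = 2, S2S = 2, LD = 4),
                            turn_direction = c("ccw", "cw"),
                            noise_sd = 0.05,
                            phase_offset = 0) {
  turn_direction <- match.arg(turn_direction)
  stopifnot(all(amplitude_scale > 0), noise_sd >= 0,
            gait_frequency_hz >= 1.4, gait_frequency_hz <= 2.2)
  need <- c("W", "TN", "S2S", "LD")
  if (!all(need %in% names(activity_duration_s))) {
    stop("activity_duration_s needs entries for W, TN, S2S, LD")
  }
  if (any(activity_duration_s[need] <= 0)) stop("durations must be positive")
  if (activity_duration_s["W"] <= activity_duration_s["S2S"]) {
    stop("walking one leg must last longer than a chair rise (duration(W) > duration(S2S))")
  }
  structure(list(subject_id = as.character(subject_id),
                 amplitude_scale = amplitude_scale,
                 gait_frequency_hz = gait_frequency_hz,
                 activity_duration_s = activity_duration_s[need],
                 turn_direction = turn_direction,
                 noise_sd = noise_sd,
                 phase_offset = phase_offset),
            class = "subject_profile")
}

default_amplitude_scale <- function() {
  m <- matrix(1, 4, 3, dimnames = list(sensor_sites(), imu_modalities()))
  m
}

## site-dependent oscillation emphasis: the wrist swings more than the
## pelvis during gait, the sternum less
site_motion_factor <- c(RW = 1.6, RP = 1.0, LP = 1.0, S = 0.8)

#' Draw a subject profile at random
#'
#' Amplitude scales are uniform in `[0.8, 1.25]` per site and modality, gait
#' frequency uniform in `[1.4, 2.2]` Hz, and activity durations uniform
#' around the defaults (walking 4.5-6 s per leg, turning 1.5-2.5 s,
#' sit-to-stand 1.8-2.6 s, lying-down 3.5-4.5 s).
#'
#' @inheritParams subject_profile
#' @param seed integer seed making the draw reproducible.
#' @return A [subject_profile()].
#' @export
draw_subject_profile <- function(subject_id, seed, turn_direction = "ccw",
                                 noise_sd = 0.05) {
  set.seed(as.integer(seed %% 2147483647))
  amp <- matrix(stats::runif(12, 0.8, 1.25), 4, 3,
                dimnames = list(sensor_sites(), imu_modalities()))
  dur <- c(W = stats::runif(1, 4.5, 6), TN = stats::runif(1, 1.5, 2.5),
           S2S = stats::runif(1, 1.8, 2.6), LD = stats::runif(1, 3.5, 4.5))
  subject_profile(subject_id, amplitude_scale = amp,
                  gait_frequency_hz = stats::runif(1, 1.4, 2.2),
                  activity_duration_s = dur,
                  turn_direction = turn_direction,
                  noise_sd = noise_sd,
                  phase_offset = stats::runif(1, 0, 2 * pi))
}

#' Activity template
#'
#' Describes one motor action for the signal synthesiser: its orientation
#' program (heading/pitch over normalized time), periodic oscillation
#' amplitudes, and timed event transients (e.g. the wrist burst while lying
#' down). `direction` is +1 for the counterclockwise/training execution and
#' -1 for the clockwise/circuit execution; it signs the heading program of
#' turning and the direction-sensitive magnetometer axes of turning and
#' sit-to-stand.
#'
#' @param label one of `"LD"`, `"S2S"`, `"TN"`, `"W"`, or the unannotated
#'   postures `"static"` / `"static_lying"`.
#' @param direction +1 (ccw) or -1 (cw). Signs both the heading-sensitive
#'   magnetometer components and (through `yaw_chirality`'s default) the
#'   body-frame yaw rate.
#' @param oscillation_amp overall multiplier on the periodic components
#'   (set 0 for noise-free limiting cases).
#' @param yaw_chirality +1 or -1, the sign of the body-frame turn. Defaults
#'   to `direction`. Setting it apart from `direction` models a protocol
#'   whose path is reversed relative to magnetic north while the body
#'   maneuver itself is statistically unchanged — the mechanism by which
#'   the continuous circuit flips magnetometer components but leaves
#'   accelerometer and gyroscope distributions untouched.
#' @return An object of class `activity_template`.
#' @export
activity_template <- function(label, direction = 1, oscillation_amp = 1,
                              yaw_chirality = direction) {
  stopifnot(label %in% c(activity_labels(), "static", "static_lying"),
            direction %in% c(-1, 1), yaw_chirality %in% c(-1, 1))
  structure(list(label = label, direction = direction,
                 oscillation_amp = oscillation_amp,
                 yaw_chirality = yaw_chirality),
            class = "activity_template")
}

## orientation programs on normalized time u in [0,1]; angles in degrees
smoothstep <- function(u) 3 * u^2 - 2 * u^3
smoothstep_rate <- function(u) 6 * u - 6 * u^2 # d/du

orientation_program <- function(template, u, duration_s) {
  d <- template$yaw_chirality # body-frame turn sign
  zero <- numeric(length(u))
  switch(template$label,
    W = ,
    static = list(pitch = zero, pitch_rate = zero, turn = zero, yaw_rate = zero),
    static_lying = list(pitch = zero + 90, pitch_rate = zero, turn = zero,
                        yaw_rate = zero),
    TN = {
      s <- smoothstep(u)
      list(pitch = zero, pitch_rate = zero,
           turn = 180 * s, # unsigned turn progress, 0 -> 180 degrees
           yaw_rate = d * 180 * smoothstep_rate(u) / duration_s,
           pulsatile_yaw = TRUE)
    },
    S2S = {
      bell <- sin(pi * u)^2
      list(pitch = 45 * bell,
           pitch_rate = 45 * pi * sin(2 * pi * u) / duration_s,
           turn = zero, yaw_rate = zero)
    },
    LD = {
      v <- pmin(pmax((u - 0.05) / 0.5, 0), 1)
      list(pitch = 90 * smoothstep(v),
           pitch_rate = 90 * smoothstep_rate(v) / (0.5 * duration_s),
           turn = zero, yaw_rate = zero)
    })
}

#' Synthesise the nine channels of one site for one activity
#'
#' Deterministic given `seed`. With zero noise, the magnetometer of a
#' clockwise turn equals that of a counterclockwise turn with the x and z
#' axes sign-inverted (y identical), the sit-to-stand discrepancy inverts
#' the magnetometer x and y axes, and accelerometer/gyroscope signals are
#' direction-independent apart from the sign of the yaw rate.
#'
#' @param template an [activity_template()].
#' @param profile a [subject_profile()].
#' @param duration_s segment duration in seconds (>= 1 for activity
#'   segments; shorter only for unannotated padding).
#' @param seed integer seed for the noise realisation.
#' @param site site code the block is synthesised for (amplitudes and the
#'   lying-down wrist burst are site-dependent).
#' @return A [channel_block()] of `round(duration_s * 128)` samples.
#' @export
synthesize_channels <- function(template, profile, duration_s, seed,
                                site = "RP") {
  stopifnot(inherits(template, "activity_template"),
            inherits(profile, "subject_profile"),
            site %in% sensor_sites())
  if (duration_s <= 0) stop("duration_s must be positive")
  if (template$label %in% activity_labels() && duration_s < 1) {
    stop("activity segments must last at least 1 s")
  }
  fs <- char_sample_rate()
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  u <- if (n > 1) t / ((n - 1) / fs) else 0
  amp <- profile$amplitude_scale[site, ]
  mf <- site_motion_factor[[site]]
  osc <- template$oscillation_amp
  d <- template$direction
  prog <- orientation_program(template, u, duration_s)
  f <- profile$gait_frequency_hz
  ph <- profile$phase_offset
  deg2rad <- pi / 180

  gait <- function(a, mult = 1, phase = 0) {
    osc * a * amp[["acc"]] * mf * sin(2 * pi * f * mult * t + ph + phase)
  }
  zero <- numeric(n)

  ## accelerometer (g units): gravity through the pitch program + gait
  pitch <- prog$pitch * deg2rad
  acc <- cbind(x = sin(pitch), y = cos(pitch), z = zero)
  if (template$label == "W") {
    acc[, "x"] <- acc[, "x"] + gait(0.20)
    acc[, "y"] <- acc[, "y"] + gait(0.25, mult = 2, phase = 0.5)
    acc[, "z"] <- acc[, "z"] + gait(0.15, phase = 1.0)
  } else if (template$label == "TN") {
    ## stepping around the pin: slower cadence than straight walking, with
    ## a vertical bob — direction-independent turning texture
    acc[, "x"] <- acc[, "x"] + gait(0.18, mult = 0.75)
    acc[, "y"] <- acc[, "y"] + gait(0.12, mult = 1.5, phase = 0.6)
    acc[, "z"] <- acc[, "z"] + gait(0.15, mult = 0.75, phase = 1.0)
  }

  ## gyroscope (rad/s): yaw rate about the vertical (y), pitch rate about z.
  ## A step-turn's yaw rate is pulsatile: rotation accrues in
  ## step-synchronized bursts, with counter-rotation dips (and, at the
  ## wrist, continued arm swing) between steps, so instantaneous yaw rate
  ## takes both signs within every turn.
  yaw <- prog$yaw_rate
  if (isTRUE(prog$pulsatile_yaw)) {
    yaw <- yaw * (1 + 1.4 * sin(2 * pi * 0.75 * f * t + ph))
  }
  gyro <- cbind(x = zero,
                y = yaw * deg2rad * amp[["gyro"]],
                z = prog$pitch_rate * deg2rad * amp[["gyro"]])
  if (template$label == "W") {
    ## gait angular rates are large and two-sided (arm swing at the wrist,
    ## axial pelvis/trunk rotation), so every gyro axis sees substantial
    ## positive and negative values during ordinary walking
    ga <- osc * 0.9 * amp[["gyro"]] * mf
    gyro[, "x"] <- gyro[, "x"] + ga * sin(2 * pi * f * t + ph + 0.7)
    gyro[, "y"] <- gyro[, "y"] + 1.2 * ga * sin(2 * pi * f * t + ph + 2.1)
    gyro[, "z"] <- gyro[, "z"] + 0.5 * ga * sin(2 * pi * f * t + ph + 1.4)
  } else if (template$label == "TN") {
    ## trunk/pelvis wobble from stepping around, direction-independent
    ga <- osc * 0.35 * amp[["gyro"]] * mf
    gyro[, "x"] <- gyro[, "x"] + ga * sin(2 * pi * 0.75 * f * t + ph + 0.4)
    gyro[, "z"] <- gyro[, "z"] + 0.8 * ga * sin(2 * pi * 0.75 * f * t + ph + 1.1)
  }

  ## magnetometer (normalized field units): stylized direction-odd model
  ma <- amp[["mag"]]
  mag <- cbind(x = zero, y = zero, z = zero)
  if (template$label == "TN") {
    hump <- sin(prog$turn * deg2rad) # 0 -> 1 -> 0 across the 180 deg turn
    mag[, "x"] <- d * 1.0 * ma * hump
    mag[, "z"] <- d * 0.8 * ma * hump
  } else if (template$label == "S2S") {
    bell <- sin(pi * u)^2
    mag[, "x"] <- d * 0.9 * ma * bell
    mag[, "y"] <- d * 0.7 * ma * bell
  } else if (template$label %in% c("LD", "static_lying")) {
    ## sustained, direction-invariant reorientation of the field
    v <- if (template$label == "LD") pmin(pmax((u - 0.05) / 0.5, 0), 1) else 1
    mag[, "z"] <- 0.3 * ma * smoothstep(v)
  } else if (template$label == "static") {
    ## quiet standing between tasks: the field projection at the resting
    ## posture. The negative offsets mirror the positive turning and
    ## sit-to-stand excursions, keeping each channel's dataset-wide range
    ## roughly symmetric about zero (these spans are never annotated, so
    ## they shape the normalization statistics only, not any class input).
    mag[, "x"] <- -1.0 * ma
    mag[, "y"] <- -0.7 * ma
    mag[, "z"] <- -0.8 * ma
  } else if (template$label == "W") {
    mw <- osc * 0.06 * ma * mf
    mag[, "x"] <- mw * sin(2 * pi * f * t + ph)
    mag[, "y"] <- mw * sin(2 * pi * f * t + ph + 0.9)
    mag[, "z"] <- mw * sin(2 * pi * f * t + ph + 1.8)
  }

  ## event transients: wrist burst while lying down (leaning on the hands),
  ## small vertical heave during the chair rise
  if (template$label == "LD" && site == "RW") {
    env <- osc * 0.5 * amp[["acc"]] * exp(-((t - 0.45 * duration_s) /
                                              (0.12 * duration_s))^2)
    burst <- env * sin(2 * pi * 8 * t)
    acc[, "x"] <- acc[, "x"] + burst
    acc[, "z"] <- acc[, "z"] + 0.7 * burst
    gyro[, "x"] <- gyro[, "x"] + 0.8 * env * sin(2 * pi * 8 * t + 0.5)
  }
  if (template$label == "S2S") {
    acc[, "y"] <- acc[, "y"] + osc * 0.15 * amp[["acc"]] * sin(pi * u)^2 *
      sin(2 * pi * 2.5 * t)
  }

  if (profile$noise_sd > 0) {
    set.seed(as.integer(seed %% 2147483647))
    acc <- acc + matrix(stats::rnorm(3 * n, 0, profile$noise_sd), n, 3)
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, profile$noise_sd), n, 3)
    mag <- mag + matrix(stats::rnorm(3 * n, 0, profile$noise_sd), n, 3)
  }
  channel_block(acc, gyro, mag)
}

## deterministic seed derivation from string parts (stable across sessions)
stable_seed <- function(master, ...) {
  s <- paste(..., sep = "|")
  codes <- utf8ToInt(s)
  h <- as.double(master %% 2147483647)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

## assemble one multi-site recording from a list of segment descriptors:
## list(kind=, duration=, direction=, trial_id= or NULL)
build_recording <- function(recording_id, profile, protocol, segments, seed) {
  fs <- char_sample_rate()
  site_blocks <- lapply(sensor_sites(), function(site) {
    blocks <- lapply(seq_along(segments), function(i) {
      sg <- segments[[i]]
      tpl <- activity_template(sg$kind, direction = sg$direction,
                               yaw_chirality = sg$yaw_chirality)
      synthesize_channels(tpl, profile, sg$duration,
                          seed = stable_seed(seed, recording_id, site, i),
                          site = site)
    })
    channel_block(
      do.call(rbind, lapply(blocks, `[[`, "acc")),
      do.call(rbind, lapply(blocks, `[[`, "gyro")),
      do.call(rbind, lapply(blocks, `[[`, "mag")))
  })
  names(site_blocks) <- sensor_sites()
  rec <- imu_recording(recording_id, profile$subject_id, protocol, site_blocks)

  lens <- vapply(segments, function(sg) round(sg$duration * fs), double(1))
  starts <- cumsum(c(0, lens[-length(lens)]))
  ann <- lapply(seq_along(segments), function(i) {
    sg <- segments[[i]]
    if (is.null(sg$trial_id)) return(NULL)
    data.frame(recording_id = recording_id, start_sample = as.integer(starts[i]),
               end_sample = as.integer(starts[i] + lens[i]),
               label = sg$kind, trial_id = sg$trial_id)
  })
  list(recording = rec, annotations = do.call(rbind, ann))
}

seg <- function(kind, duration, direction = 1, trial_id = NULL,
                yaw_chirality = direction) {
  list(kind = kind, duration = duration, direction = direction,
       trial_id = trial_id, yaw_chirality = yaw_chirality)
}

## per-repetition duration jitter (+-5%), deterministic
jitter_dur <- function(base, seed) {
  set.seed(as.integer(seed %% 2147483647))
  base * stats::runif(length(base), 0.95, 1.05)
}

#' Generate the separate-execution (training) dataset
#'
#' Per subject and repetition, three single-task acquisitions: a
#' Walking+Turning recording (annotated W, TN, W with a counterclockwise
#' turn, padded by unannotated quiet standing), a Sit-to-Stand recording and
#' a Lying-down recording. The default cohort, 10 subjects x 10 repetitions,
#' yields 300 acquisitions.
#'
#' @param n_subjects,reps_per_task cohort size.
#' @param seed master seed; all per-recording seeds are derived from it by
#'   stable hashing of (subject, task, repetition).
#' @param noise_sd sensor noise level passed to the subject profiles.
#' @return List with `recordings` (list of [imu_recording()]) and
#'   `annotations` (data.frame).
#' @export
generate_separate_dataset <- function(n_subjects = 10, reps_per_task = 10,
                                      seed = 1, noise_sd = 0.05) {
  stopifnot(n_subjects >= 1, reps_per_task >= 1)
  recordings <- list()
  annotations <- list()
  for (si in seq_len(n_subjects)) {
    sid <- sprintf("trainS%02d", si)
    profile <- draw_subject_profile(sid, stable_seed(seed, "profile", sid),
                                    turn_direction = "ccw", noise_sd = noise_sd)
    dur <- profile$activity_duration_s
    for (r in seq_len(reps_per_task)) {
      dj <- jitter_dur(dur, stable_seed(seed, "jitter", sid, r))
      names(dj) <- names(dur)
      tid <- function(task, part) sprintf("%s_r%02d_%s_%s", sid, r, task, part)

      wt_id <- sprintf("%s_sep_WT_r%02d", sid, r)
      wt <- build_recording(wt_id, profile, "separate", list(
        seg("static", 5),
        seg("W", dj[["W"]], trial_id = tid("WT", "W1")),
        seg("TN", dj[["TN"]], direction = +1, trial_id = tid("WT", "TN")),
        seg("W", dj[["W"]] * 1.02, trial_id = tid("WT", "W2")),
        seg("static", 5)), seed)

      s2s_id <- sprintf("%s_sep_S2S_r%02d", sid, r)
      s2s <- build_recording(s2s_id, profile, "separate", list(
        seg("static", 5),
        seg("S2S", dj[["S2S"]], direction = +1, trial_id = tid("S2S", "S2S")),
        seg("static", 5)), seed)

      ld_id <- sprintf("%s_sep_LD_r%02d", sid, r)
      ld <- build_recording(ld_id, profile, "separate", list(
        seg("static", 5),
        seg("LD", dj[["LD"]], trial_id = tid("LD", "LD")),
        seg("static_lying", 5)), seed)

      for (b in list(wt, s2s, ld)) {
        recordings[[b$recording$recording_id]] <- b$recording
        annotations[[b$recording$recording_id]] <- b$annotations
      }
    }
  }
  list(recordings = recordings,
       annotations = validate_annotations(do.call(rbind, c(annotations,
                                                           make.row.names = FALSE))))
}

#' Generate the continuous-circuit (test) dataset
#'
#' Per subject and repetition, one uninterrupted recording of the circuit
#' S2S -> W -> TN -> W -> LD with clockwise turning and opposite-facing
#' sit-to-stand (the execution-direction discrepancy with respect to the
#' training protocol), separated by unannotated static spans. The default
#' cohort, 8 subjects x 5 repetitions, yields 40 acquisitions.
#'
#' @inheritParams generate_separate_dataset
#' @param reps circuit repetitions per subject.
#' @return As [generate_separate_dataset()].
#' @export
generate_continuous_dataset <- function(n_subjects = 8, reps = 5, seed = 1,
                                        noise_sd = 0.05) {
  stopifnot(n_subjects >= 1, reps >= 1)
  recordings <- list()
  annotations <- list()
  for (si in seq_len(n_subjects)) {
    sid <- sprintf("testS%02d", si)
    profile <- draw_subject_profile(sid, stable_seed(seed, "profile", sid),
                                    turn_direction = "cw", noise_sd = noise_sd)
    dur <- profile$activity_duration_s
    for (r in seq_len(reps)) {
      dj <- jitter_dur(dur, stable_seed(seed, "jitter", sid, r))
      names(dj) <- names(dur)
      tid <- function(part) sprintf("%s_c%02d_%s", sid, r, part)
      rec_id <- sprintf("%s_cont_r%02d", sid, r)
      ## direction = -1: the circuit runs the path reversed with respect to
      ## magnetic north, flipping the heading-sensitive magnetometer axes;
      ## yaw_chirality = +1: the body maneuver statistics are unchanged, so
      ## accelerometer and gyroscope distributions match the training
      ## protocol (the discrepancy lives in the magnetometer only)
      b <- build_recording(rec_id, profile, "continuous", list(
        seg("static", 5),
        seg("S2S", dj[["S2S"]], direction = -1, trial_id = tid("S2S")),
        seg("static", 1.5),
        seg("W", dj[["W"]], trial_id = tid("W1")),
        seg("TN", dj[["TN"]], direction = -1, yaw_chirality = +1,
            trial_id = tid("TN")),
        seg("W", dj[["W"]] * 1.02, trial_id = tid("W2")),
        seg("static", 1.5),
        seg("LD", dj[["LD"]], trial_id = tid("LD")),
        seg("static_lying", 5)), seed)
      recordings[[rec_id]] <- b$recording
      annotations[[rec_id]] <- b$annotations
    }
  }
  list(recordings = recordings,
       annotations = validate_annotations(do.call(rbind, c(annotations,
                                                           make.row.names = FALSE))))
}
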