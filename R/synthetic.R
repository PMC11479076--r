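#' Gait archetype presets
#'
#' Parameter sets for the synthetic circular walker. The four presets encode
#' disease-typical movement signatures as generative ground truth:
#' * hip/knee swing half-amplitudes ordered healthy > CM > PD > HD
#'   (shuffling, short-stepped gait narrows sagittal leg excursion),
#' * shoulder/elbow swing half-amplitudes ordered healthy > CM > HD > PD
#'   (arm-swing reduction is most severe in Parkinson's disease),
#' * lateral leg offsets ordered healthy < CM < PD < HD (wide-based gait is
#'   most pronounced in Hakim's disease; healthy walkers place heels slightly
#'   inward, giving a negative offset),
#' * lateral arm offsets ordered healthy > CM > HD > PD.
#'
#' Amplitudes are in degrees; lateral offsets are fractions of leg length
#' (lower limb) or upper-body length (upper limb); `cadence_hz` is gait
#' cycles per second; `step_height` is the swing-phase heel lift as a
#' fraction of leg length, realized through extra knee flexion.
#'
#' @param name `"healthy"`, `"HD"`, `"PD"`, `"CM"` or `"custom"`.
#' @param ... Overrides of individual fields (required when
#'   `name = "custom"`).
#' @return Named list of class `gait_archetype`.
#' @export
gait_archetype <- function(name = c("healthy", "HD", "PD", "CM", "custom"),
                           ...) {
  name <- match.arg(name)
  presets <- list(
    healthy = list(hip_swing_half_amp_deg = 25, knee_swing_half_amp_deg = 30,
                   shoulder_swing_half_amp_deg = 18,
                   elbow_swing_half_amp_deg = 12,
                   heel_lateral_offset = -0.02,
                   toe_lateral_offset_beyond_heel = -0.01,
                   elbow_lateral_offset = 0.08,
                   hand_lateral_offset_beyond_elbow = 0.04,
                   cadence_hz = 0.90, step_height = 0.10),
    CM = list(hip_swing_half_amp_deg = 18, knee_swing_half_amp_deg = 22,
              shoulder_swing_half_amp_deg = 13,
              elbow_swing_half_amp_deg = 9,
              heel_lateral_offset = 0.02,
              toe_lateral_offset_beyond_heel = 0.01,
              elbow_lateral_offset = 0.06,
              hand_lateral_offset_beyond_elbow = 0.03,
              cadence_hz = 0.85, step_height = 0.07),
    PD = list(hip_swing_half_amp_deg = 12, knee_swing_half_amp_deg = 15,
              shoulder_swing_half_amp_deg = 4,
              elbow_swing_half_amp_deg = 3,
              heel_lateral_offset = 0.06,
              toe_lateral_offset_beyond_heel = 0.03,
              elbow_lateral_offset = 0.015,
              hand_lateral_offset_beyond_elbow = 0.005,
              cadence_hz = 1.00, step_height = 0.04),
    HD = list(hip_swing_half_amp_deg = 7, knee_swing_half_amp_deg = 9,
              shoulder_swing_half_amp_deg = 8,
              elbow_swing_half_amp_deg = 6,
              heel_lateral_offset = 0.12,
              toe_lateral_offset_beyond_heel = 0.06,
              elbow_lateral_offset = 0.04,
              hand_lateral_offset_beyond_elbow = 0.02,
              cadence_hz = 1.00, step_height = 0.02)
  )
  base <- if (name == "custom") presets$healthy else presets[[name]]
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad) > 0) {
    stop("unknown archetype fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  base[names(over)] <- over
  stopifnot(base$cadence_hz > 0,
            base$hip_swing_half_amp_deg >= 0,
            base$knee_swing_half_amp_deg >= 0,
            base$shoulder_swing_half_amp_deg >= 0,
            base$elbow_swing_half_amp_deg >= 0)
  structure(c(list(name = name), base), class = "gait_archetype")
}

#' Synthetic walker configuration
#'
#' Describes one simulated measurement: a subject walking around a circular
#' path (default 1 m diameter, two laps, captured at 30 fps), with limb
#' kinematics from a [gait_archetype()], additive i.i.d. Gaussian coordinate
#' noise, and a two-point confidence-score mixture (score `base` normally,
#' `low_score` with probability `dropout_prob`).
#'
#' @param archetype A [gait_archetype()] or preset name.
#' @param circle_diameter_m Path diameter in meters (default 1).
#' @param n_laps Number of laps (default 2).
#' @param fps Capture rate (default 30).
#' @param leg_length,upper_body_length Segment lengths in meters (defaults
#'   0.85 and 0.52; only their ratios matter after export normalization).
#' @param noise_sd Coordinate noise SD in export (app-scale) units,
#'   default 0.01.
#' @param confidence_base,dropout_prob,low_score Confidence model.
#' @param seed RNG seed; every random element is reproducible from it.
#' @return Named list of class `walker_config`.
#' @export
walker_config <- function(archetype = "healthy", circle_diameter_m = 1,
                          n_laps = 2, fps = 30, leg_length = 0.85,
                          upper_body_length = 0.52, noise_sd = 0.01,
                          confidence_base = 0.95, dropout_prob = 0.05,
                          low_score = 0.5, seed = 1) {
  if (is.character(archetype)) archetype <- gait_archetype(archetype)
  stopifnot(inherits(archetype, "gait_archetype"),
            circle_diameter_m > 0, n_laps > 0, fps > 0,
            leg_length > 0, upper_body_length > 0, noise_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            confidence_base >= 0, confidence_base <= 1,
            low_score >= 0, low_score <= 1)
  structure(
    list(archetype = archetype, circle_diameter_m = circle_diameter_m,
         n_laps = n_laps, fps = fps, leg_length = leg_length,
         upper_body_length = upper_body_length, noise_sd = noise_sd,
         confidence_base = confidence_base, dropout_prob = dropout_prob,
         low_score = low_score, seed = seed),
    class = "walker_config"
  )
}

#' Generate a synthetic circular walk
#'
#' Rigid-segment walker: trunk plus two-segment arms and legs with
#' sinusoidal joint oscillations, contralateral limbs in antiphase, heading
#' tangent to the circular path. Lateral limb offsets are built into the
#' segment directions with the segment lengths held exactly constant, so in
#' the noise-free limit the pipeline recovers the configured leg length,
#' upper-body length and outward shifts exactly. Coordinates are exported
#' body-center-relative and scaled to the app's convention (body scale
#' normalized); the walk duration follows from cadence-derived speed:
#' `frames = ceil(n_laps * circumference / speed * fps)`.
#'
#' The `"smoothed"` variant low-pass filters the additive noise component
#' (4th-order Butterworth, 6 Hz cutoff); the kinematic signal itself is
#' band-limited well below the cutoff and is left untouched, so noise-free
#' runs are identical across variants.
#'
#' @param config A [walker_config()].
#' @param variant `"smoothed"` (default) or `"raw"`.
#' @param measurement_id,subject_id,group Metadata for the series; `group`
#'   defaults to the archetype name (or `"unknown"` for custom archetypes).
#' @return A [keypoint_series()] with an attached `truth` attribute holding
#'   the generator's ground-truth values (segment lengths, configured
#'   outward shifts, amplitudes).
#' @export
generate_walk <- function(config = walker_config(),
                          variant = c("smoothed", "raw"),
                          measurement_id = "sim1", subject_id = "sim_subj",
                          group = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "walker_config"))
  a <- config$archetype
  group <- group %||% (if (a$name %in% c("HD", "PD", "CM", "healthy"))
    a$name else "unknown")

  L <- config$leg_length
  U <- config$upper_body_length
  t_l <- 0.5 * L; s_l <- 0.5 * L; foot_len <- 0.2 * L
  w_h <- 0.12 * L; d_h <- 0.12 * L
  w_s <- 0.35 * U; u_a <- 0.55 * U; f_a <- 0.48 * U

  A_hip <- rad(a$hip_swing_half_amp_deg)
  A_knee <- rad(a$knee_swing_half_amp_deg)
  A_sh <- rad(a$shoulder_swing_half_amp_deg)
  A_el <- rad(a$elbow_swing_half_amp_deg)

  step_len <- max(2 * L * sin(A_hip), 0.05 * L)
  speed <- 2 * a$cadence_hz * step_len
  dist <- config$n_laps * pi * config$circle_diameter_m
  n <- ceiling(dist / speed * config$fps)
  tt <- (seq_len(n) - 1) / config$fps
  omega <- 2 * pi * a$cadence_hz
  radius <- config$circle_diameter_m / 2

  # trunk frame: tangent heading plus small physiological sway
  alpha <- speed * tt / radius
  psi <- alpha + pi / 2
  F0 <- cbind(cos(psi), sin(psi), 0)
  R0 <- cbind(sin(psi), -cos(psi), 0)
  U0 <- cbind(0, 0, rep(1, n))
  pitch <- rad(2) * sin(2 * omega * tt + 0.5)
  roll <- rad(2) * sin(omega * tt)
  Ftr <- cos(pitch) * F0 + sin(pitch) * U0
  U1 <- -sin(pitch) * F0 + cos(pitch) * U0
  Rtr <- cos(roll) * R0 + sin(roll) * U1
  Utr <- -sin(roll) * R0 + cos(roll) * U1

  navel <- cbind(radius * cos(alpha), radius * sin(alpha), 0.95)
  kp <- keypoint_vocabulary()
  coords <- array(NA_real_, c(n, length(kp), 3),
                  dimnames = list(NULL, kp, c("x", "y", "z")))
  put <- function(name, m) coords[, name, ] <<- m

  put("navel_center", navel)
  put("head_center", navel + U * Utr)
  put("nose", navel + U * Utr + 0.10 * U * Ftr - 0.03 * U * Utr)
  put("neck", navel + 0.80 * U * Utr)
  put("chest", navel + 0.45 * U * Utr + 0.03 * U * Ftr)
  put("hip_center", navel - d_h * Utr)
  for (side in c("l", "r")) {
    ss <- if (side == "r") 1 else -1
    put(paste0(side, "_ear"),
        navel + U * Utr + 0.12 * U * ss * Rtr)
    put(paste0(side, "_eye"),
        navel + U * Utr + 0.08 * U * Ftr + 0.05 * U * ss * Rtr +
          0.02 * U * Utr)
  }

  extra_knee <- asin(min(0.9, a$step_height * L / s_l))
  lam_heel <- a$heel_lateral_offset * L / s_l
  mu_toe <- a$toe_lateral_offset_beyond_heel * L / foot_len
  lam_elb <- a$elbow_lateral_offset * U / u_a
  lam_hand <- a$hand_lateral_offset_beyond_elbow * U / f_a
  if (any(abs(c(lam_heel, mu_toe, lam_elb, lam_hand)) >= 1)) {
    stop("lateral offset too large for the segment carrying it",
         call. = FALSE)
  }
  rho_toe <- rad(25)

  for (side in c("l", "r")) {
    ss <- if (side == "r") 1 else -1
    ph <- if (side == "l") 0 else pi

    hip <- navel + w_h * ss * Rtr - d_h * Utr
    put(paste0(side, "_hip"), hip)
    theta <- A_hip * sin(omega * tt + ph)
    knee <- hip + t_l * (sin(theta) * Ftr - cos(theta) * Utr)
    put(paste0(side, "_knee"), knee)
    gam <- (A_knee + extra_knee) * (1 - cos(omega * tt + ph)) / 2
    th_sh <- theta - gam
    heel <- knee + s_l * (lam_heel * ss * Rtr +
      sqrt(1 - lam_heel^2) * (sin(th_sh) * Ftr - cos(th_sh) * Utr))
    put(paste0(side, "_heel"), heel)
    toe <- heel + foot_len * (mu_toe * ss * Rtr +
      sqrt(1 - mu_toe^2) * (cos(rho_toe) * Ftr - sin(rho_toe) * Utr))
    put(paste0(side, "_toe"), toe)

    shoulder <- navel + w_s * ss * Rtr + 0.75 * U * Utr
    put(paste0(side, "_shoulder"), shoulder)
    th_a <- A_sh * sin(omega * tt + ph + pi)
    elbow <- shoulder + u_a * (lam_elb * ss * Rtr +
      sqrt(1 - lam_elb^2) * (sin(th_a) * Ftr - cos(th_a) * Utr))
    put(paste0(side, "_elbow"), elbow)
    th_f <- th_a + rad(20) + A_el * sin(omega * tt + ph + pi)
    hand <- elbow + f_a * (lam_hand * ss * Rtr +
      sqrt(1 - lam_hand^2) * (sin(th_f) * Ftr - cos(th_f) * Utr))
    put(paste0(side, "_hand"), hand)
  }

  # export: body-center relative, app-scale normalized
  scale <- (U + d_h + L) / 2
  for (d in 1:3) coords[, , d] <- (coords[, , d] - navel[, d]) / scale

  conf <- matrix(config$confidence_base, n, length(kp),
                 dimnames = list(NULL, kp))
  withr::with_seed(config$seed, {
    if (config$dropout_prob > 0) {
      drop <- matrix(stats::runif(n * length(kp)) < config$dropout_prob,
                     n, length(kp))
      conf[drop] <- config$low_score
    }
    if (config$noise_sd > 0) {
      eps <- array(stats::rnorm(length(coords), sd = config$noise_sd),
                   dim = dim(coords))
      if (variant == "smoothed" && n > 24) {
        bf <- signal::butter(4, min(0.99, 6 / (config$fps / 2)), "low")
        for (j in seq_along(kp)) for (d in 1:3) {
          eps[, j, d] <- signal::filtfilt(bf, eps[, j, d])
        }
      }
      coords <- coords + eps
    }
  })

  series <- keypoint_series(coords, conf, fps = config$fps,
                            measurement_id = measurement_id,
                            subject_id = subject_id, group = group,
                            variant = variant)
  attr(series, "truth") <- list(
    leg_length = L / scale, upper_body_length = U / scale,
    heel_shift = a$heel_lateral_offset,
    toe_shift = a$toe_lateral_offset_beyond_heel,
    leg_shift = a$heel_lateral_offset + a$toe_lateral_offset_beyond_heel,
    elbow_shift = a$elbow_lateral_offset,
    hand_shift = a$hand_lateral_offset_beyond_elbow,
    arm_shift = a$elbow_lateral_offset + a$hand_lateral_offset_beyond_elbow,
    hip_half_amp_deg = a$hip_swing_half_amp_deg,
    shoulder_half_amp_deg = a$shoulder_swing_half_amp_deg,
    n_frames = n, speed_m_s = speed
  )
  series
}

#' Generate a synthetic cohort
#'
#' Subjects are assigned archetypes by group with per-subject log-normal
#' parameter jitter; a shared per-subject mobility factor multiplies the hip
#' and elbow swing amplitudes, inducing the upper-lower limb coupling the
#' correlation analysis is designed to detect. Demographics (sex ratio, age
#' distribution per group) emulate a typical neurology clinic cohort.
#'
#' @param group_sizes Named integer vector over `HD`, `PD`, `CM`, `healthy`
#'   (zeros allowed).
#' @param walks_per_subject Measurements per subject (ignored when
#'   `n_measurements` is given).
#' @param n_measurements Optional total measurement count, distributed as
#'   evenly as possible across subjects (remainder to the first subjects).
#' @param seed RNG seed controlling demographics, jitter and every
#'   generated walk.
#' @param simulate Generate the keypoint series (`TRUE`) or only the cohort
#'   metadata and walker configs (`FALSE`, instant — useful for cohort
#'   bookkeeping at realistic scale).
#' @param subject_sdlog SD (log scale) of per-subject parameter jitter
#'   (default 0.15).
#' @param coupling_sdlog SD (log scale) of the shared hip+elbow mobility
#'   factor (default 0.25).
#' @param measurement_sdlog SD (log scale) of per-measurement amplitude
#'   jitter (default 0.05).
#' @param ... Overrides passed to [walker_config()] (e.g. `noise_sd`).
#' @return List with `cohort` (tibble: subject_id, group, sex, age),
#'   `measurements` (tibble: measurement_id, subject_id, group, seed,
#'   config list-column) and `series` (named list, `NULL` when
#'   `simulate = FALSE`).
#' @export
generate_cohort <- function(group_sizes = c(HD = 122, PD = 12, CM = 93,
                                            healthy = 200),
                            walks_per_subject = 1, n_measurements = NULL,
                            seed = 1, simulate = TRUE,
                            subject_sdlog = 0.15, coupling_sdlog = 0.25,
                            measurement_sdlog = 0.05, ...) {
  stopifnot(all(group_sizes >= 0),
            all(names(group_sizes) %in% c("HD", "PD", "CM", "healthy")))
  demog <- list(
    HD = list(p_male = 69 / 122, age_mean = 75.9, age_sd = 7.4,
              age_range = c(60, 93)),
    PD = list(p_male = 8 / 12, age_mean = 70.8, age_sd = 7.9,
              age_range = c(56, 83)),
    CM = list(p_male = 67 / 93, age_mean = 66.1, age_sd = 11.8,
              age_range = c(42, 88)),
    healthy = list(p_male = 71 / 149, age_mean = 60.7, age_sd = 20.2,
                   age_range = c(20, 91))
  )
  groups <- rep(names(group_sizes), group_sizes)
  n_subj <- length(groups)
  if (n_subj == 0) stop("empty cohort", call. = FALSE)

  withr::with_seed(seed, {
    subject_id <- sprintf("%s_%03d", groups,
                          stats::ave(seq_len(n_subj), groups,
                                     FUN = seq_along))
    sex <- age <- character(n_subj)
    age <- numeric(n_subj)
    for (i in seq_len(n_subj)) {
      d <- demog[[groups[i]]]
      sex[i] <- if (stats::runif(1) < d$p_male) "M" else "F"
      repeat {
        a <- stats::rnorm(1, d$age_mean, d$age_sd)
        if (a >= d$age_range[1] && a <= d$age_range[2]) break
      }
      age[i] <- round(a)
    }
    cohort <- tibble::tibble(subject_id = subject_id, group = groups,
                             sex = sex, age = age)

    n_walks <- if (!is.null(n_measurements)) {
      base <- n_measurements %/% n_subj
      extra <- n_measurements %% n_subj
      base + as.integer(seq_len(n_subj) <= extra)
    } else rep(as.integer(walks_per_subject), n_subj)

    # per-subject archetype jitter
    subj_arch <- vector("list", n_subj)
    for (i in seq_len(n_subj)) {
      a <- gait_archetype(groups[i])
      vigor <- stats::rlnorm(1, 0, coupling_sdlog)
      j <- function() stats::rlnorm(1, 0, subject_sdlog)
      a$hip_swing_half_amp_deg <- a$hip_swing_half_amp_deg * vigor * j()
      a$elbow_swing_half_amp_deg <- a$elbow_swing_half_amp_deg * vigor * j()
      a$knee_swing_half_amp_deg <- a$knee_swing_half_amp_deg * j()
      a$shoulder_swing_half_amp_deg <- a$shoulder_swing_half_amp_deg * j()
      a$heel_lateral_offset <- a$heel_lateral_offset * j()
      a$toe_lateral_offset_beyond_heel <-
        a$toe_lateral_offset_beyond_heel * j()
      a$elbow_lateral_offset <- a$elbow_lateral_offset * j()
      a$hand_lateral_offset_beyond_elbow <-
        a$hand_lateral_offset_beyond_elbow * j()
      a$cadence_hz <- a$cadence_hz * stats::rlnorm(1, 0, 0.3 * subject_sdlog)
      subj_arch[[i]] <- a
    }

    meas_rows <- list()
    for (i in seq_len(n_subj)) {
      for (w in seq_len(n_walks[i])) {
        a <- subj_arch[[i]]
        mj <- stats::rlnorm(1, 0, measurement_sdlog)
        for (f in c("hip_swing_half_amp_deg", "knee_swing_half_amp_deg",
                    "shoulder_swing_half_amp_deg",
                    "elbow_swing_half_amp_deg")) {
          a[[f]] <- a[[f]] * mj
        }
        cfg <- walker_config(archetype = a,
                             seed = sample.int(.Machine$integer.max - 1, 1),
                             ...)
        meas_rows[[length(meas_rows) + 1]] <- tibble::tibble(
          measurement_id = sprintf("%s_w%02d", subject_id[i], w),
          subject_id = subject_id[i], group = groups[i],
          seed = cfg$seed, config = list(cfg))
      }
    }
    measurements <- dplyr::bind_rows(meas_rows)
  })

  series <- NULL
  if (simulate) {
    series <- lapply(seq_len(nrow(measurements)), function(i) {
      generate_walk(measurements$config[[i]],
                    measurement_id = measurements$measurement_id[i],
                    subject_id = measurements$subject_id[i],
                    group = measurements$group[i])
    })
    names(series) <- measurements$measurement_id
  }
  list(cohort = cohort, measurements = measurements, series = series)
}
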