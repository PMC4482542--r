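#' Synthesize a kinematic trial
#'
#' Fixture generator making the force-based adaptation measures testable
#' without robot recordings. The forward trajectory is a minimum-jerk
#' 10 cm movement sampled at 200 Hz; the lateral geometry follows the
#' clamped direction `angle`. The "measured" lateral force is
#' `adaptation_level` times the ideal compensatory profile for the positive
#' field, optionally shifted later in time by `force_lag` seconds (area is
#' preserved because the grid extends past the movement), plus white sensor
#' noise. A time grid margin after the movement keeps shifted profiles
#' fully observed.
#'
#' @param angle Clamp/movement direction in degrees (0 = straight ahead).
#' @param duration Movement duration in seconds.
#' @param adaptation_level Gain on the ideal compensatory force.
#' @param ff A [force_field_spec()].
#' @param force_lag Seconds by which the produced force lags the ideal.
#' @param noise_sd Sensor noise sd (N).
#' @param amplitude Movement amplitude (m).
#' @param margin Trailing time margin (s) appended after the movement.
#' @param seed Optional integer seed.
#' @param metadata Optional list stored with the trial.
#' @return A `kinematic_trial`: list with `time`, `pos_xy`, `vel_xy`,
#'   `lateral_force`, `ideal_force`, `angle`, `dt`, `metadata`.
#' @export
synth_kinematics <- function(angle = 0, duration = 0.5,
                             adaptation_level = 0,
                             ff = force_field_spec(15),
                             force_lag = 0, noise_sd = 0,
                             amplitude = 0.10, margin = 0.15,
                             seed = NULL, metadata = list()) {
  if (duration <= 0) stop("`duration` must be positive")
  dt <- 1 / 200
  time <- seq(0, duration + margin, by = dt)
  s <- pmin(time / duration, 1)
  # minimum-jerk position and speed along the movement direction
  r <- amplitude * (10 * s^3 - 15 * s^4 + 6 * s^5)
  v <- ifelse(time <= duration,
              amplitude / duration * (30 * s^2 - 60 * s^3 + 30 * s^4), 0)
  th <- angle * pi / 180
  pos_xy <- cbind(x = r * sin(th), y = r * cos(th))
  vel_xy <- cbind(x = v * sin(th), y = v * cos(th))
  ideal <- ideal_force_profile(v * cos(th), ff)
  lag_samples <- round(force_lag / dt)
  produced <- if (lag_samples > 0) {
    c(numeric(lag_samples), ideal)[seq_along(ideal)]
  } else ideal
  noise <- if (noise_sd > 0) {
    with_seed(resolve_seed(seed), function() stats::rnorm(length(ideal), 0, noise_sd))
  } else 0
  structure(list(time = time, pos_xy = pos_xy, vel_xy = vel_xy,
                 lateral_force = adaptation_level * produced + noise,
                 ideal_force = ideal, angle = angle, dt = dt,
                 metadata = metadata),
            class = "kinematic_trial")
}

# direction of the position at target distance, degrees from straight ahead
movement_angle_deg <- function(trial, target_distance = 0.10) {
  r <- sqrt(rowSums(trial$pos_xy^2))
  idx <- which(r >= target_distance)[1L]
  if (is.na(idx)) idx <- which.max(r)
  atan2(trial$pos_xy[idx, "x"], trial$pos_xy[idx, "y"]) * 180 / pi
}

#' Movement characteristics over a window of trials
#'
#' Summaries used to compare training and retention contexts:
#' * `directional_variability` — sd of the per-trial movement angle,
#'   measured as the direction of the position at target distance;
#' * `p_reward` — fraction of trials passing within `reward_radius` of the
#'   target center between 150 and 250 ms after movement onset (onset
#'   defined by a 5 cm/s speed threshold);
#' * `duration` — mean time from onset to target distance;
#' * `curvature` — mean over trials of the sum of squared lateral
#'   deviations from the straight start-to-end path.
#'
#' @param trials List of `kinematic_trial` objects (>= 2 for variability).
#' @param target_distance Target distance from start (m).
#' @param reward_radius Reward tolerance around the target center (m).
#' @param reward_window Time window (s) after onset for a rewarded passage.
#' @param onset_speed Speed threshold defining movement onset (m/s).
#' @return List with `directional_variability` (degrees), `p_reward`,
#'   `duration` (s), `curvature` (m^2).
#' @export
movement_characteristics <- function(trials, target_distance = 0.10,
                                     reward_radius = 0.006,
                                     reward_window = c(0.150, 0.250),
                                     onset_speed = 0.05) {
  if (length(trials) == 0L) stop("empty trial window")
  target <- c(0, target_distance)
  per_trial <- lapply(trials, function(tr) {
    speed <- sqrt(rowSums(tr$vel_xy^2))
    onset_idx <- which(speed >= onset_speed)[1L]
    onset_time <- if (is.na(onset_idx)) 0 else tr$time[onset_idx]
    r <- sqrt(rowSums(tr$pos_xy^2))
    tgt_idx <- which(r >= target_distance)[1L]
    duration <- if (is.na(tgt_idx)) NA_real_ else tr$time[tgt_idx] - onset_time
    d_tgt <- sqrt((tr$pos_xy[, "x"] - target[1L])^2 +
                  (tr$pos_xy[, "y"] - target[2L])^2)
    in_window <- tr$time - onset_time >= reward_window[1L] &
                 tr$time - onset_time <= reward_window[2L]
    rewarded <- any(in_window & d_tgt <= reward_radius)
    # squared lateral deviations from the straight start-to-end chord
    p0 <- tr$pos_xy[1L, ]; p1 <- tr$pos_xy[nrow(tr$pos_xy), ]
    chord <- p1 - p0
    len <- sqrt(sum(chord^2))
    lat <- if (len == 0) rep(0, nrow(tr$pos_xy)) else {
      u <- chord / len
      dx <- sweep(tr$pos_xy, 2L, p0)
      dx[, "x"] * u["y"] - dx[, "y"] * u["x"]
    }
    list(angle = movement_angle_deg(tr, target_distance),
         rewarded = rewarded, duration = duration,
         curvature = sum(lat^2))
  })
  angles <- vapply(per_trial, `[[`, numeric(1L), "angle")
  list(directional_variability = if (length(trials) >= 2L) stats::sd(angles) else NA_real_,
       p_reward = mean(vapply(per_trial, `[[`, logical(1L), "rewarded")),
       duration = mean(vapply(per_trial, `[[`, numeric(1L), "duration"), na.rm = TRUE),
       curvature = mean(vapply(per_trial, `[[`, numeric(1L), "curvature")))
}
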