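# Synthetic movement generators: (a) two-sine joint pairs with configurable
# phase shift and amplitude ratio; (b) a two-link planar arm reaching
# vertical targets with four named coordination strategies. Both emit
# standard movement_dataset objects and can be written to disk in the
# condition-folder CSV layout.

#' Specification for the two-sine simulated datasets
#'
#' Two datasets A and B of two joints each: `theta1 = a sin(2 pi f t)` is
#' identical in both; `theta2 = ratio * a * sin(2 pi f t + shift)` with a
#' phase shift of 1 rad in A and pi/2 rad in B, and double the amplitude of
#' `theta1`. Defaults sample 5 whole periods at 100 Hz so that empirical
#' covariances match the analytic sinusoid moments closely.
#'
#' @param amplitude base amplitude `a` of `theta1` (radians).
#' @param amplitude_ratio amplitude of `theta2` relative to `theta1`.
#' @param phase_shift_a,phase_shift_b phase shift of `theta2` (radians) in
#'   datasets A and B.
#' @param frequency sine frequency in Hz.
#' @param duration signal duration in seconds.
#' @param sample_rate sampling rate in Hz (must exceed `2 * frequency`).
#' @param noise_sd SD of additive Gaussian noise (radians), default 0.
#' @param n_reps repetitions per dataset (identical signals plus fresh noise).
#' @param seed optional integer seed for the noise.
#' @return A list of class `sine_spec`.
#' @export
sine_spec <- function(amplitude = 1, amplitude_ratio = 2,
                      phase_shift_a = 1, phase_shift_b = pi / 2,
                      frequency = 1, duration = 5, sample_rate = 100,
                      noise_sd = 0, n_reps = 1L, seed = NULL) {
  if (sample_rate <= 2 * frequency)
    stop_jc("sample_rate must exceed twice the sine frequency")
  if (duration <= 0) stop_jc("duration must be positive")
  structure(list(amplitude = amplitude, amplitude_ratio = amplitude_ratio,
                 phase_shift_a = phase_shift_a, phase_shift_b = phase_shift_b,
                 frequency = frequency, duration = duration,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 n_reps = as.integer(n_reps), seed = seed),
            class = "sine_spec")
}

#' Generate the two-sine simulated dataset pair
#'
#' @param spec a [sine_spec()].
#' @return Named list with [movement_dataset()]s `A` and `B` (angle unit
#'   radians).
#' @examples
#' sim <- make_sine_datasets(sine_spec())
#' jcvpca(sim$A, sim$B)$delta
#' @export
make_sine_datasets <- function(spec = sine_spec()) {
  stopifnot(inherits(spec, "sine_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  t <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  w <- 2 * pi * spec$frequency
  one <- function(shift, rep_idx) {
    th1 <- spec$amplitude * sin(w * t)
    th2 <- spec$amplitude_ratio * spec$amplitude * sin(w * t + shift)
    ang <- cbind(theta1 = th1, theta2 = th2)
    if (spec$noise_sd > 0)
      ang <- ang + matrix(stats::rnorm(length(ang), sd = spec$noise_sd),
                          ncol = 2L)
    movement_repetition(ang, time = t, meta = list(repetition = rep_idx))
  }
  build <- function(shift, name) {
    movement_dataset(lapply(seq_len(spec$n_reps), function(i) one(shift, i)),
                     name = name, angle_unit = "rad")
  }
  list(A = build(spec$phase_shift_a, "A"), B = build(spec$phase_shift_b, "B"))
}

#' Specification of the simulated two-link planar arm and reaching protocol
#'
#' Geometry and protocol of a sagittal-plane reaching task: a shoulder
#' (flexion from the vertical-down resting direction) and an elbow (interior
#' flexion angle; 180 deg = straight arm) move the hand to one of three
#' target heights shown in front of the subject. Movements start with the
#' arm hanging (`shoulder = 0`) and the elbow comfortably flexed at about
#' 140 deg.
#'
#' Four coordination strategies are available:
#' \describe{
#'   \item{`physiological`}{shoulder and elbow share the reach
#'     simultaneously, proximal-weighted (elbow excursion =
#'     `sharing_ratio` x shoulder excursion) with a slight elbow onset lag.}
#'   \item{`desync`}{the shoulder completes its flexion first, then the
#'     elbow extends: same joint amplitudes, sequential timing.}
#'   \item{`shoulder_only`}{the elbow is held at the start angle and the
#'     shoulder alone solves the target height.}
#'   \item{`elbow_overuse`}{the shoulder follows the physiological profile
#'     while the elbow first flexes (an extra excursion of
#'     `overuse_flexion` deg) and then extends to meet the target.}
#' }
#'
#' @param upper_arm_length,forearm_length segment lengths in meters.
#' @param start_shoulder,start_elbow start posture in degrees.
#' @param target_heights hand heights relative to the shoulder (meters).
#' @param reps_per_target repetitions of each target.
#' @param strategy one of the four strategy names above.
#' @param movement_duration nominal duration of one reach (seconds).
#' @param sample_rate sampling rate in Hz.
#' @param noise_sd SD of additive Gaussian measurement noise (degrees).
#' @param posture_jitter_sd SD of the per-repetition start-posture jitter
#'   (degrees).
#' @param duration_jitter_sd SD of the per-repetition duration jitter (s).
#' @param sharing_ratio elbow-to-shoulder excursion ratio of the
#'   physiological strategy.
#' @param elbow_lag physiological elbow onset lag as a fraction of the
#'   movement duration.
#' @param desync_split fractions of the duration at which the shoulder phase
#'   ends and the elbow phase begins in the `desync` strategy.
#' @param overuse_flexion extra elbow flexion bump (degrees) of the
#'   `elbow_overuse` strategy.
#' @param seed optional integer seed.
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(upper_arm_length = 0.30, forearm_length = 0.28,
                     start_shoulder = 0, start_elbow = 140,
                     target_heights = c(-0.15, 0, 0.15),
                     reps_per_target = 5L,
                     strategy = c("physiological", "desync",
                                  "shoulder_only", "elbow_overuse"),
                     movement_duration = 2, sample_rate = 100,
                     noise_sd = 0.2, posture_jitter_sd = 1,
                     duration_jitter_sd = 0.1, sharing_ratio = 0.54,
                     elbow_lag = 0.1, desync_split = c(0.45, 0.55),
                     overuse_flexion = 15, seed = NULL) {
  strategy <- match.arg(strategy)
  if (movement_duration <= 0) stop_jc("movement_duration must be positive")
  structure(list(upper_arm_length = upper_arm_length,
                 forearm_length = forearm_length,
                 start_shoulder = start_shoulder, start_elbow = start_elbow,
                 target_heights = target_heights,
                 reps_per_target = as.integer(reps_per_target),
                 strategy = strategy, movement_duration = movement_duration,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 posture_jitter_sd = posture_jitter_sd,
                 duration_jitter_sd = duration_jitter_sd,
                 sharing_ratio = sharing_ratio, elbow_lag = elbow_lag,
                 desync_split = desync_split,
                 overuse_flexion = overuse_flexion, seed = seed),
            class = "arm_spec")
}

#' Hand height of the two-link planar arm
#'
#' Forward kinematics under the package's angle convention: shoulder flexion
#' `theta1` measured from the vertical-down direction, elbow interior
#' flexion `theta2` (180 deg = straight). The hand height relative to the
#' shoulder is
#'
#'   `h = -L1 cos(theta1) - L2 cos(theta1 + (180 - theta2))`
#'
#' so a hanging straight arm (`theta1 = 0, theta2 = 180`) gives
#' `-(L1 + L2)` and a horizontal straight arm (`theta1 = 90`) gives 0.
#'
#' @param shoulder_flex,elbow_flex joint angles in degrees (vectorized).
#' @param arm an [arm_spec()] providing segment lengths.
#' @return hand height(s) in meters, relative to the shoulder.
#' @export
forward_kinematics <- function(shoulder_flex, elbow_flex, arm = arm_spec()) {
  th1 <- deg2rad(shoulder_flex)
  th2 <- deg2rad(elbow_flex)
  -arm$upper_arm_length * cos(th1) -
    arm$forearm_length * cos(th1 + (pi - th2))
}

# Solve the shoulder amplitude A1 (deg) so that the end posture
# (th1_0 + A1, th2_0 + elbow_from_A1(A1)) reaches `target`.
solve_amplitude <- function(arm, th1_0, th2_0, target, elbow_from_A1) {
  f <- function(A1) forward_kinematics(th1_0 + A1, th2_0 + elbow_from_A1(A1),
                                       arm) - target
  # f can cross zero more than once; take the root of smallest amplitude
  # (the least movement that reaches the target).
  grid <- seq(-130, 130, by = 1)
  fg <- vapply(grid, f, numeric(1))
  cross <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (length(cross) == 0L)
    stop_jc("target height %.3f m is unreachable with the '%s' strategy",
            target, arm$strategy)
  mid <- abs(grid[cross] + grid[cross + 1L]) / 2
  i <- cross[which.min(mid)]
  stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-10)$root
}

#' Simulate one condition of the two-link reaching protocol
#'
#' Generates `reps_per_target` repetitions per target height. Each
#' repetition realizes a minimum-jerk progression from the (jittered) start
#' posture to a posture that reaches the target exactly, with joint
#' allocation and timing set by the strategy (see [arm_spec()]). Gaussian
#' measurement noise is added to all samples.
#'
#' @param arm an [arm_spec()].
#' @return A [movement_dataset()] named after the strategy, joints
#'   `shoulder` and `elbow`, angle unit degrees. Each repetition's metadata
#'   records condition, target label and repetition index.
#' @examples
#' phys <- make_reaching_dataset(arm_spec(strategy = "physiological", seed = 1))
#' phys
#' @export
make_reaching_dataset <- function(arm = arm_spec()) {
  stopifnot(inherits(arm, "arm_spec"))
  if (!is.null(arm$seed)) set.seed(arm$seed)
  reps <- list()
  target_labels <- paste0("target", seq_along(arm$target_heights))
  for (ti in seq_along(arm$target_heights)) {
    for (ri in seq_len(arm$reps_per_target)) {
      reps[[length(reps) + 1L]] <-
        simulate_reach(arm, arm$target_heights[ti], target_labels[ti], ri)
    }
  }
  movement_dataset(reps, name = arm$strategy, angle_unit = "deg")
}

# One repetition of the reaching task.
simulate_reach <- function(arm, target, target_label, rep_idx) {
  th1_0 <- arm$start_shoulder + stats::rnorm(1, sd = arm$posture_jitter_sd)
  th2_0 <- arm$start_elbow + stats::rnorm(1, sd = arm$posture_jitter_sd)
  D <- max(arm$movement_duration +
             stats::rnorm(1, sd = arm$duration_jitter_sd),
           0.5 * arm$movement_duration)
  t <- seq(0, D, by = 1 / arm$sample_rate)
  u <- t / D
  r <- arm$sharing_ratio
  lag <- arm$elbow_lag

  s_phys_sh <- min_jerk(u)
  s_phys_el <- min_jerk((u - lag) / (1 - lag))

  traj <- switch(arm$strategy,
    physiological = {
      A1 <- solve_amplitude(arm, th1_0, th2_0, target, function(A1) -r * A1)
      cbind(th1_0 + A1 * s_phys_sh, th2_0 - r * A1 * s_phys_el)
    },
    desync = {
      a <- arm$desync_split[1]; b <- arm$desync_split[2]
      s1 <- min_jerk(u / a)
      s2 <- min_jerk((u - b) / (1 - b))
      A1 <- solve_amplitude(arm, th1_0, th2_0, target, function(A1) -r * A1)
      cbind(th1_0 + A1 * s1, th2_0 - r * A1 * s2)
    },
    shoulder_only = {
      A1 <- solve_amplitude(arm, th1_0, th2_0, target, function(A1) 0)
      cbind(th1_0 + A1 * s_phys_sh, base::rep(th2_0, length(t)))
    },
    elbow_overuse = {
      A1 <- solve_amplitude(arm, th1_0, th2_0, target, function(A1) -r * A1)
      # elbow first flexes by overuse_flexion, then extends to the final
      # angle; the shoulder keeps its physiological profile.
      peak <- 0.4
      flex <- arm$overuse_flexion * min_jerk(u / peak)
      extend <- (arm$overuse_flexion + r * A1) * min_jerk((u - peak) / (1 - peak))
      cbind(th1_0 + A1 * s_phys_sh, th2_0 + flex - extend)
    })

  if (arm$noise_sd > 0)
    traj <- traj + matrix(stats::rnorm(length(traj), sd = arm$noise_sd),
                          ncol = 2L)
  movement_repetition(traj, time = t, joint_names = c("shoulder", "elbow"),
                      meta = list(condition = arm$strategy,
                                  target = target_label,
                                  repetition = rep_idx,
                                  target_height = target))
}

#' Simulate all four coordination strategies of the reaching protocol
#'
#' Runs [make_reaching_dataset()] once per strategy with a strategy-specific
#' seed derived from `seed`, so conditions are independent but the whole
#' experiment is reproducible.
#'
#' @param arm an [arm_spec()] providing the shared protocol parameters (its
#'   `strategy` field is ignored).
#' @param seed integer seed for the whole experiment.
#' @param strategies which strategies to simulate.
#' @return Named list of [movement_dataset()]s, one per strategy.
#' @export
simulate_experiment <- function(arm = arm_spec(), seed = 1L,
                                strategies = c("physiological", "desync",
                                               "shoulder_only",
                                               "elbow_overuse")) {
  out <- lapply(seq_along(strategies), function(i) {
    a <- arm
    a$strategy <- strategies[i]
    a$seed <- as.integer(seed) + i - 1L
    make_reaching_dataset(a)
  })
  names(out) <- strategies
  out
}
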