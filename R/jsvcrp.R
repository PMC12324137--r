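# Continuous relative phase (CRP) and the JsvCRP area metric.
#
# Per repetition and joint: estimate the angular velocity, range-normalize
# position and velocity into [-1, 1], and read the phase angle off the phase
# portrait (velocity against position) with a quadrant-aware arctangent. The
# CRP of a joint pair is the difference of the two phase angles; positive
# values mean the second joint leads. JsvCRP compares two datasets by
# averaging each dataset's time-normalized CRP curves and integrating the
# absolute difference between the two means.

#' Range-normalize a signal into [-1, 1]
#'
#' Linear map sending the minimum to -1 and the maximum to +1 exactly:
#' `y = 2 (x - min) / (max - min) - 1`. Required before phase-angle
#' extraction so that position and velocity share a scale. Note this
#' amplifies noise on joints that barely move; see [noise_ratio_guard()].
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @return numeric vector in [-1, 1].
#' @export
range_normalize <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop_jc("cannot range-normalize non-finite data")
  if (rng[2] <= rng[1])
    stop_jc("cannot range-normalize a constant signal (apply the noise guard first)")
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Estimate angular velocity of one joint of a repetition
#'
#' Finite differences on the (possibly non-uniform) time grid: central
#' differences on the interior, one-sided at the endpoints. Optional
#' zero-phase low-pass filtering (2nd-order Butterworth, applied forwards
#' and backwards) of the position signal before differencing, off by
#' default; smoothing requires an approximately uniform sample rate.
#'
#' @param rep a [movement_repetition()] with a time vector and at least 3
#'   samples.
#' @param joint joint name or column index.
#' @param smooth logical, default `FALSE`.
#' @param cutoff_hz low-pass cutoff used when `smooth = TRUE`.
#' @return numeric vector of velocities (angle unit per second).
#' @export
estimate_velocity <- function(rep, joint = 1L, smooth = FALSE, cutoff_hz = 10) {
  stopifnot(inherits(rep, "movement_repetition"))
  if (is.null(rep$time))
    stop_jc("velocity estimation needs a time vector; this repetition has none")
  t <- rep$time
  if (length(t) < 3L) stop_jc("need at least 3 samples to estimate velocity")
  x <- rep$angles[, joint]
  if (isTRUE(smooth)) {
    dt <- diff(t)
    if (max(dt) / min(dt) > 1.01)
      stop_jc("low-pass smoothing requires a uniform sample rate")
    fs <- 1 / stats::median(dt)
    wn <- min(2 * cutoff_hz / fs, 0.99)
    bf <- signal::butter(2, wn, type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  finite_diff(x, t)
}

# Central differences on a non-uniform grid; second-order three-point
# one-sided formulas at the ends.
finite_diff <- function(x, t) {
  n <- length(x)
  v <- numeric(n)
  end3 <- function(i1, i2, i3) {
    # derivative at t[i1] of the quadratic through the three points
    x[i1] * (2 * t[i1] - t[i2] - t[i3]) / ((t[i1] - t[i2]) * (t[i1] - t[i3])) +
      x[i2] * (t[i1] - t[i3]) / ((t[i2] - t[i1]) * (t[i2] - t[i3])) +
      x[i3] * (t[i1] - t[i2]) / ((t[i3] - t[i1]) * (t[i3] - t[i2]))
  }
  v[1] <- end3(1L, 2L, 3L)
  v[n] <- end3(n, n - 1L, n - 2L)
  if (n > 2L) {
    i <- 2:(n - 1)
    v[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  v
}

#' Decide whether a joint's range of motion is resolvable above noise
#'
#' Range normalization blows up when the recorded range of motion is mostly
#' sensor noise. If the ratio `noise_range / (max(x) - min(x))` exceeds 1,
#' the joint should not be phase-analyzed: its normalized position, velocity
#' and phase are all substituted by the constant 0 and the joint is flagged
#' non-contributing (the hypothesis that it neither synchronizes with nor
#' contributes to the movement).
#'
#' @param x raw joint-angle vector.
#' @param noise_range expected peak-to-peak noise magnitude in the same unit
#'   as `x` (from a sensor spec or a quiet-period estimate). Must be >= 0.
#' @return list with `action` (`"keep"` or `"zero_substitute"`) and `ratio`.
#' @export
noise_ratio_guard <- function(x, noise_range) {
  if (length(noise_range) != 1L || !is.finite(noise_range) || noise_range < 0)
    stop_jc("`noise_range` must be a single non-negative number")
  rom <- diff(range(x))
  ratio <- if (rom > 0) noise_range / rom else Inf
  list(action = if (ratio > 1) "zero_substitute" else "keep", ratio = ratio)
}

#' Phase angle of normalized position/velocity pairs
#'
#' The angle between the horizontal (zero-velocity) axis and the point
#' (position, velocity) on the phase portrait, via the two-argument
#' arctangent `atan2(velocity, position)` so all four quadrants are
#' resolved. Range (-pi, pi]; the degenerate origin point maps to 0.
#'
#' @param theta_norm normalized position in [-1, 1].
#' @param dtheta_norm normalized velocity in [-1, 1].
#' @return numeric vector of phase angles in radians.
#' @export
phase_angle <- function(theta_norm, dtheta_norm) {
  if (length(theta_norm) != length(dtheta_norm))
    stop_jc("position and velocity must have the same length")
  ph <- atan2(dtheta_norm, theta_norm)
  ph[ph == -pi] <- pi
  ph
}

#' Phase portrait of one joint of a repetition
#'
#' Bundles the range-normalized position, range-normalized velocity and the
#' phase angle of one joint, applying the noise guard first: a joint whose
#' range of motion is below `noise_range` gets identically zero signals and
#' `contributing = FALSE`.
#'
#' @inheritParams estimate_velocity
#' @param noise_range see [noise_ratio_guard()]; default 0 (always keep).
#' @return An object of class `phase_portrait` with fields `theta_norm`,
#'   `dtheta_norm`, `phase`, `time`, `joint`, `contributing`.
#' @export
phase_portrait <- function(rep, joint = 1L, noise_range = 0,
                           smooth = FALSE, cutoff_hz = 10) {
  stopifnot(inherits(rep, "movement_repetition"))
  x <- rep$angles[, joint]
  jname <- if (is.character(joint)) joint else rep$joint_names[joint]
  guard <- noise_ratio_guard(x, noise_range)
  if (guard$action == "zero_substitute") {
    z <- numeric(length(x))
    return(structure(list(theta_norm = z, dtheta_norm = z, phase = z,
                          time = rep$time, joint = jname,
                          contributing = FALSE, noise_ratio = guard$ratio),
                     class = "phase_portrait"))
  }
  v <- estimate_velocity(rep, joint, smooth = smooth, cutoff_hz = cutoff_hz)
  structure(list(theta_norm = range_normalize(x),
                 dtheta_norm = range_normalize(v),
                 phase = phase_angle(range_normalize(x), range_normalize(v)),
                 time = rep$time, joint = jname,
                 contributing = TRUE, noise_ratio = guard$ratio),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase_portrait> joint '%s', %d samples%s\n", x$joint,
              length(x$phase),
              if (!x$contributing) " (zero-substituted: noise above range of motion)" else ""))
  invisible(x)
}

# Internal crp_curve constructor.
new_crp_curve <- function(grid, values, pair, axis = c("seconds", "percent"),
                          unit = "rad", sd = NULL, duration = NULL) {
  axis <- match.arg(axis)
  structure(list(grid = grid, values = values, pair = pair, axis = axis,
                 unit = unit, sd = sd, duration = duration),
            class = "crp_curve")
}

#' Continuous relative phase of a joint pair
#'
#' `CRP(t) = phi_j(t) - phi_i(t)`. A constant curve means the phase relation
#' between the joints is constant; its sign encodes which joint is ahead.
#' Under the phase-portrait construction (`atan2(velocity, position)`, a
#' clockwise-rotating portrait for oscillatory motion) a joint ahead in time
#' sits at a lower phase angle, so a second joint leading by a lag `d` gives
#' `CRP = -d`. By default the wrapped phase angles are subtracted and
#' the difference is re-wrapped into (-pi, pi]; with `unwrap = TRUE` each
#' phase is unwrapped over time before subtraction (no re-wrap), which
#' preserves accumulated phase lead at the cost of sensitivity to wrap
#' detection.
#'
#' @param phase_i,phase_j phase-angle vectors (radians) of equal length, or
#'   [phase_portrait()] objects.
#' @param time optional time vector for the curve's axis; defaults to the
#'   portraits' time when available, else sample index.
#' @param pair character vector of the two joint labels.
#' @param unwrap logical wrap-handling policy (see Details).
#' @return An object of class `crp_curve` (`grid`, `values` in radians,
#'   `pair`, `axis`).
#' @export
crp <- function(phase_i, phase_j, time = NULL, pair = c("i", "j"),
                unwrap = FALSE) {
  if (inherits(phase_i, "phase_portrait")) {
    if (is.null(time)) time <- phase_i$time
    pair[1] <- phase_i$joint
    phase_i <- phase_i$phase
  }
  if (inherits(phase_j, "phase_portrait")) {
    if (is.null(time)) time <- phase_j$time
    pair[2] <- phase_j$joint
    phase_j <- phase_j$phase
  }
  if (length(phase_i) != length(phase_j))
    stop_jc("phase vectors differ in length (%d vs %d)",
            length(phase_i), length(phase_j))
  values <- if (isTRUE(unwrap)) {
    pracma::unwrap(phase_j) - pracma::unwrap(phase_i)
  } else {
    wrap_pi(phase_j - phase_i)
  }
  grid <- time %||% seq_along(values)
  new_crp_curve(grid = grid, values = values, pair = pair, axis = "seconds")
}

#' @export
print.crp_curve <- function(x, ...) {
  cat(sprintf("<crp_curve> %s vs %s, %d points on a %s axis, unit %s\n",
              x$pair[1], x$pair[2], length(x$values), x$axis, x$unit))
  invisible(x)
}

#' Plot a CRP curve
#' @param x a `crp_curve`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.crp_curve <- function(x, ...) {
  xl <- if (x$axis == "percent") "movement progression (%)" else "time (s)"
  graphics::plot(x$grid, x$values, type = "l", xlab = xl,
                 ylab = sprintf("CRP %s-%s (%s)", x$pair[1], x$pair[2], x$unit),
                 ...)
  if (!is.null(x$sd)) {
    graphics::lines(x$grid, x$values + x$sd, lty = 3)
    graphics::lines(x$grid, x$values - x$sd, lty = 3)
  }
  invisible(x)
}

#' Resample a CRP curve onto a 0-100% movement-progression grid
#'
#' Linear interpolation onto `G` equally spaced points spanning 0 to 100% of
#' the movement duration, so curves from repetitions of different durations
#' become comparable. The original duration (seconds) is kept alongside so
#' areas can still be expressed on a seconds axis.
#'
#' @param curve a `crp_curve` on a raw time axis.
#' @param G grid size (default 101: 0, 1, ..., 100%).
#' @return A `crp_curve` with `axis = "percent"`.
#' @export
time_normalize <- function(curve, G = 101L) {
  stopifnot(inherits(curve, "crp_curve"))
  if (length(curve$values) < 2L)
    stop_jc("need at least 2 samples to time-normalize")
  if (curve$axis == "percent" && length(curve$values) == G)
    return(curve)
  src <- if (curve$axis == "percent") curve$grid else {
    (curve$grid - curve$grid[1]) / diff(range(curve$grid)) * 100
  }
  out_grid <- seq(0, 100, length.out = G)
  values <- stats::approx(src, curve$values, xout = out_grid, rule = 2)$y
  dur <- curve$duration %||%
    (if (curve$axis == "seconds") diff(range(curve$grid)) else NULL)
  new_crp_curve(grid = out_grid, values = values, pair = curve$pair,
                axis = "percent", unit = curve$unit, duration = dur)
}

# Full per-repetition CRP pipeline for one joint pair.
rep_crp <- function(repn, pair, noise_range = c(0, 0), unwrap = FALSE,
                    smooth = FALSE, cutoff_hz = 10) {
  if (length(noise_range) == 1L) noise_range <- c(noise_range, noise_range)
  pp_i <- phase_portrait(repn, pair[1], noise_range = noise_range[1],
                         smooth = smooth, cutoff_hz = cutoff_hz)
  pp_j <- phase_portrait(repn, pair[2], noise_range = noise_range[2],
                         smooth = smooth, cutoff_hz = cutoff_hz)
  crp(pp_i, pp_j, unwrap = unwrap)
}

#' Mean CRP curve of a dataset
#'
#' Computes the CRP of `pair` for every repetition (pooling all targets and
#' conditions present in the dataset), time-normalizes each curve onto a
#' common 0-100% grid, and averages pointwise. The pointwise standard
#' deviation across repetitions is returned alongside.
#'
#' @param ds a [movement_dataset()] whose repetitions carry time vectors.
#' @param pair joint pair as names or indices (default the first two joints,
#'   ordered by the dataset's joint order).
#' @param G grid size for time normalization.
#' @param noise_range per-joint (length 2) or shared noise magnitude for
#'   [noise_ratio_guard()], in the dataset's angle unit.
#' @param unwrap wrap-handling policy passed to [crp()].
#' @param smooth,cutoff_hz velocity smoothing, see [estimate_velocity()].
#' @return A `crp_curve` with `axis = "percent"`, `sd` filled in, and
#'   `duration` the mean repetition duration in seconds.
#' @export
mean_crp <- function(ds, pair = c(1L, 2L), G = 101L, noise_range = 0,
                     unwrap = FALSE, smooth = FALSE, cutoff_hz = 10) {
  stopifnot(inherits(ds, "movement_dataset"))
  pair_idx <- resolve_pair(ds, pair)
  curves <- lapply(ds$repetitions, function(r)
    time_normalize(rep_crp(r, pair_idx, noise_range = noise_range,
                           unwrap = unwrap, smooth = smooth,
                           cutoff_hz = cutoff_hz), G = G))
  vals <- vapply(curves, function(cv) cv$values, numeric(G))
  vals <- matrix(vals, nrow = G)
  durs <- vapply(curves, function(cv) cv$duration %||% NA_real_, numeric(1))
  mu <- rowMeans(vals)
  sdv <- if (ncol(vals) > 1L) apply(vals, 1L, stats::sd) else numeric(G)
  new_crp_curve(grid = seq(0, 100, length.out = G), values = mu,
                pair = ds$joint_names[pair_idx], axis = "percent",
                sd = sdv, duration = mean(durs, na.rm = TRUE))
}

# Joint pair as integer indices ordered by dataset joint order.
resolve_pair <- function(ds, pair) {
  if (length(pair) != 2L) stop_jc("`pair` must have exactly 2 entries")
  idx <- if (is.character(pair)) match(pair, ds$joint_names) else as.integer(pair)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_joints(ds)))
    stop_jc("joint pair (%s) not found in dataset joints (%s)",
            paste(pair, collapse = ", "), paste(ds$joint_names, collapse = ", "))
  if (idx[1] == idx[2]) stop_jc("`pair` must name two distinct joints")
  sort(idx)
}

#' Area between two curves sampled on a common grid
#'
#' Trapezoidal integral of the absolute pointwise difference. Used by
#' [jsvcrp()]; exposed for direct use on precomputed mean curves.
#'
#' @param curve_a,curve_b `crp_curve` objects on identical grids.
#' @param x optional abscissa overriding the curves' grid (e.g. seconds).
#' @return non-negative scalar area.
#' @export
crp_area <- function(curve_a, curve_b, x = NULL) {
  stopifnot(inherits(curve_a, "crp_curve"), inherits(curve_b, "crp_curve"))
  if (length(curve_a$values) != length(curve_b$values) ||
      max(abs(curve_a$grid - curve_b$grid)) > 1e-9)
    stop_jc("curves must share the same grid")
  x <- x %||% curve_a$grid
  pracma::trapz(x, abs(curve_b$values - curve_a$values))
}

#' JsvCRP: area between the mean CRP curves of two datasets
#'
#' Summarizes the change in synchronization of one joint pair between two
#' datasets as the integral over the movement of the absolute difference
#' between the two mean CRP curves. Zero when the mean curves coincide;
#' symmetric in the dataset order; larger areas mean more dissimilar
#' lead-lag patterns.
#'
#' Units: phase is dimensionless-in-origin but conventionally reported in
#' the dataset's angle unit (`unit = "deg"` multiplies the radian curves by
#' 180/pi). The abscissa is either the 0-100 movement-progression axis
#' (`axis = "percent"`, unit of the result: angle x percent) or seconds
#' (`axis = "seconds"`, progression rescaled by the mean repetition duration
#' of both datasets; unit: angle x s).
#'
#' @param ref,cmp [movement_dataset()] objects containing `pair`.
#' @param pair joint pair (names or indices).
#' @param G time-normalization grid size.
#' @param axis `"percent"` (default) or `"seconds"`.
#' @param noise_range,unwrap,smooth,cutoff_hz passed to [mean_crp()].
#' @param unit output angle unit, `"rad"` or `"deg"`; defaults to the
#'   reference dataset's angle unit.
#' @return Scalar area with attributes `unit`, `axis`, and `mean_curves`
#'   (list of the two mean `crp_curve`s, in the output unit).
#' @examples
#' sim <- make_sine_datasets(sine_spec())
#' jsvcrp(sim$A, sim$B, axis = "seconds")
#' @export
jsvcrp <- function(ref, cmp, pair = c(1L, 2L), G = 101L,
                   axis = c("percent", "seconds"), noise_range = 0,
                   unwrap = FALSE, unit = NULL, smooth = FALSE,
                   cutoff_hz = 10) {
  axis <- match.arg(axis)
  stopifnot(inherits(ref, "movement_dataset"), inherits(cmp, "movement_dataset"))
  if (!identical(ref$joint_names, cmp$joint_names))
    stop_jc("datasets must share joint names and order")
  unit <- unit %||% ref$angle_unit
  mc_ref <- mean_crp(ref, pair = pair, G = G, noise_range = noise_range,
                     unwrap = unwrap, smooth = smooth, cutoff_hz = cutoff_hz)
  mc_cmp <- mean_crp(cmp, pair = pair, G = G, noise_range = noise_range,
                     unwrap = unwrap, smooth = smooth, cutoff_hz = cutoff_hz)
  scale <- if (identical(unit, "deg")) 180 / pi else 1
  mc_ref$values <- mc_ref$values * scale
  mc_cmp$values <- mc_cmp$values * scale
  if (!is.null(mc_ref$sd)) mc_ref$sd <- mc_ref$sd * scale
  if (!is.null(mc_cmp$sd)) mc_cmp$sd <- mc_cmp$sd * scale
  mc_ref$unit <- mc_cmp$unit <- unit
  x <- if (axis == "seconds") {
    dur <- mean(c(mc_ref$duration, mc_cmp$duration), na.rm = TRUE)
    if (!is.finite(dur))
      stop_jc("axis = 'seconds' needs repetitions with time vectors")
    mc_ref$grid / 100 * dur
  } else {
    mc_ref$grid
  }
  area <- pracma::trapz(x, abs(mc_cmp$values - mc_ref$values))
  structure(area, unit = unit, axis = axis,
            mean_curves = list(ref = mc_ref, cmp = mc_cmp))
}

#' JsvCRP for every joint pair of two datasets
#'
#' @inheritParams jsvcrp
#' @return Named numeric vector with one `choose(n, 2)` entry per pair
#'   (`"<joint_i>:<joint_j>"`), with the same attributes-free scalar values
#'   as [jsvcrp()]; the full per-pair results (mean curves included) are
#'   attached as attribute `details`.
#' @export
jsvcrp_all <- function(ref, cmp, G = 101L, axis = c("percent", "seconds"),
                       noise_range = 0, unwrap = FALSE, unit = NULL,
                       smooth = FALSE, cutoff_hz = 10) {
  axis <- match.arg(axis)
  n <- n_joints(ref)
  if (n < 2L) stop_jc("need at least 2 joints for pairwise CRP")
  pairs <- utils::combn(n, 2L, simplify = FALSE)
  nr <- if (length(noise_range) == 1L) rep(noise_range, n) else noise_range
  details <- lapply(pairs, function(p)
    jsvcrp(ref, cmp, pair = p, G = G, axis = axis, noise_range = nr[p],
           unwrap = unwrap, unit = unit, smooth = smooth, cutoff_hz = cutoff_hz))
  vals <- vapply(details, as.numeric, numeric(1))
  names(vals) <- vapply(pairs, function(p)
    paste(ref$joint_names[p], collapse = ":"), character(1))
  attr(vals, "details") <- details
  vals
}
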