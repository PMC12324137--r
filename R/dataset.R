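#' Construct a single movement repetition
#'
#' A repetition holds the joint-angle trajectories recorded (or simulated)
#' during one execution of a movement task: an optional strictly increasing
#' time vector and one angle column per joint. Angles are stored as-is; the
#' unit (degrees or radians) is a property of the enclosing dataset.
#'
#' @param angles numeric matrix (or data frame), one row per sample and one
#'   column per joint.
#' @param time optional numeric vector of timestamps in seconds, strictly
#'   increasing, same length as `nrow(angles)`. JcvPCA ignores timing, so
#'   `time` may be `NULL`; JsvCRP requires it.
#' @param joint_names character vector of joint labels; defaults to the
#'   column names of `angles`.
#' @param meta named list of free-form tags (condition, target, repetition
#'   index, ...).
#' @return An object of class `movement_repetition`.
#' @export
movement_repetition <- function(angles, time = NULL,
                                joint_names = colnames(angles),
                                meta = list()) {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  if (nrow(angles) < 2L)
    stop_jc("a movement repetition needs at least 2 samples, got %d", nrow(angles))
  if (anyNA(angles) || any(!is.finite(angles)))
    stop_jc("joint angles contain missing or non-finite values")
  if (is.null(joint_names))
    joint_names <- paste0("joint", seq_len(ncol(angles)))
  joint_names <- as.character(joint_names)
  if (length(joint_names) != ncol(angles))
    stop_jc("`angles` has %d columns but %d joint names were given",
            ncol(angles), length(joint_names))
  colnames(angles) <- joint_names
  if (!is.null(time)) {
    time <- as.numeric(time)
    if (length(time) != nrow(angles))
      stop_jc("`time` has length %d but `angles` has %d rows",
              length(time), nrow(angles))
    if (anyNA(time) || any(!is.finite(time)))
      stop_jc("`time` contains missing or non-finite values")
    if (any(diff(time) <= 0))
      stop_jc("`time` must be strictly increasing (duplicated or reversed timestamps)")
  }
  structure(list(time = time, angles = angles, joint_names = joint_names,
                 meta = as.list(meta)),
            class = "movement_repetition")
}

#' Construct a multi-repetition movement dataset
#'
#' A dataset is a named collection of repetitions of the same task sharing a
#' joint list and an angle unit. Repetitions may differ in duration and
#' sample count.
#'
#' @param repetitions list of [movement_repetition()] objects (at least one).
#' @param name dataset label (e.g. `"physiological"`).
#' @param angle_unit `"deg"` or `"rad"`.
#' @param centered logical; `TRUE` only for datasets returned by
#'   [center_dataset()].
#' @return An object of class `movement_dataset`.
#' @export
movement_dataset <- function(repetitions, name = "dataset",
                             angle_unit = c("deg", "rad"),
                             centered = FALSE) {
  angle_unit <- match.arg(angle_unit)
  if (inherits(repetitions, "movement_repetition"))
    repetitions <- list(repetitions)
  if (!is.list(repetitions) || length(repetitions) < 1L)
    stop_jc("`repetitions` must be a non-empty list of movement repetitions")
  ok <- vapply(repetitions, inherits, logical(1), "movement_repetition")
  if (!all(ok))
    stop_jc("all elements of `repetitions` must be movement_repetition objects")
  jn <- repetitions[[1L]]$joint_names
  for (i in seq_along(repetitions)) {
    if (!identical(repetitions[[i]]$joint_names, jn))
      stop_jc("repetition %d has joint names (%s) that differ from the first (%s)",
              i, paste(repetitions[[i]]$joint_names, collapse = ", "),
              paste(jn, collapse = ", "))
  }
  structure(list(name = name, repetitions = repetitions, joint_names = jn,
                 angle_unit = angle_unit, centered = isTRUE(centered)),
            class = "movement_dataset")
}

#' @export
print.movement_repetition <- function(x, ...) {
  cat(sprintf("<movement_repetition> %d samples x %d joints (%s)%s\n",
              nrow(x$angles), length(x$joint_names),
              paste(x$joint_names, collapse = ", "),
              if (is.null(x$time)) ", no time vector" else
                sprintf(", %.3f s", diff(range(x$time)))))
  invisible(x)
}

#' @export
print.movement_dataset <- function(x, ...) {
  cat(sprintf("<movement_dataset> '%s': %d repetitions, %d joints (%s), unit %s%s\n",
              x$name, length(x$repetitions), length(x$joint_names),
              paste(x$joint_names, collapse = ", "), x$angle_unit,
              if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Number of joints / repetitions in a dataset
#' @param ds a `movement_dataset`.
#' @return integer count.
#' @export
n_joints <- function(ds) length(ds$joint_names)

#' @rdname n_joints
#' @export
n_repetitions <- function(ds) length(ds$repetitions)

#' Stack all samples of all repetitions into one matrix
#'
#' Rows are time samples (all repetitions concatenated in order), columns are
#' joints. This is the matrix the PCA steps operate on: timing is discarded.
#'
#' @param ds a `movement_dataset`.
#' @return numeric matrix with `sum(sample counts)` rows and one column per joint.
#' @export
dataset_samples <- function(ds) {
  stopifnot(inherits(ds, "movement_dataset"))
  do.call(rbind, lapply(ds$repetitions, function(r) r$angles))
}

#' Center a dataset to zero mean per joint
#'
#' Subtracts, for each joint, the grand mean over all samples of all
#' repetitions pooled together. No amplitude scaling is applied, so joints
#' that move a lot keep their weight in later PCA steps. Pooling the mean
#' across repetitions (rather than centering each repetition on itself)
#' matches the PCA, which is computed on the concatenated samples; it also
#' removes small constant offsets in the starting posture.
#'
#' @param ds a `movement_dataset`.
#' @return A `movement_dataset` with `centered = TRUE` and an attribute-like
#'   field `joint_means` holding the removed per-joint means.
#' @export
center_dataset <- function(ds) {
  stopifnot(inherits(ds, "movement_dataset"))
  mu <- colMeans(dataset_samples(ds))
  reps <- lapply(ds$repetitions, function(r) {
    r$angles <- sweep(r$angles, 2L, mu, "-")
    r
  })
  out <- movement_dataset(reps, name = ds$name, angle_unit = ds$angle_unit,
                          centered = TRUE)
  out$joint_means <- mu
  out
}

# Center only if not already flagged centered.
ensure_centered <- function(ds) if (isTRUE(ds$centered)) ds else center_dataset(ds)

# Subset repetitions, keeping metadata.
subset_repetitions <- function(ds, idx, name = ds$name) {
  movement_dataset(ds$repetitions[idx], name = name,
                   angle_unit = ds$angle_unit, centered = ds$centered)
}
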