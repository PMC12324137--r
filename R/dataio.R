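# CSV reading/writing for multi-repetition joint-angle datasets.
#
# Two on-disk layouts are supported:
#   * "generic": a flat directory of CSV files, first column `time_s`
#     (optional), remaining columns joint angles. One file per repetition.
#   * "s4": a condition folder containing one CSV per repetition named
#     `<target>_<rep>.csv` (the layout used by exoskeleton reaching
#     recordings: one folder per condition, repetitions of the movements for
#     the different target heights in individual csv files).
# A JSON sidecar `dataset.json` records name, angle unit and joint order.

TIME_COL <- "time_s"

#' Load a multi-repetition joint-angle dataset from a directory of CSV files
#'
#' Reads every `.csv` file under `path` (one repetition per file), enforcing
#' a common joint-column set and order taken from the first file. File and
#' folder names are parsed into repetition metadata: for the `s4` layout the
#' enclosing folder is the condition and a file `high_2.csv` is repetition 2
#' towards target "high". Rows containing missing cells are dropped with a
#' warning, never imputed.
#'
#' @param path directory containing the CSV files (for the `s4` layout, one
#'   condition folder), or a single CSV file.
#' @param layout `"auto"` (default), `"s4"` or `"generic"`. `"auto"` uses the
#'   sidecar if present, else treats any `<stem>_<number>.csv` naming as s4.
#' @param angle_unit `"deg"` or `"rad"`; overridden by a `dataset.json`
#'   sidecar if one is present.
#' @param name dataset label; defaults to the directory name.
#' @param time_col name of the timestamp column, default `"time_s"`. Files
#'   without this column load with `time = NULL` (sufficient for JcvPCA,
#'   rejected by JsvCRP).
#' @return A [movement_dataset()] with one repetition per file, ordered by
#'   file name.
#' @seealso [write_dataset()], [load_conditions()]
#' @export
load_dataset <- function(path, layout = c("auto", "s4", "generic"),
                         angle_unit = "deg", name = NULL,
                         time_col = TIME_COL) {
  layout <- match.arg(layout)
  if (length(path) != 1L || !is.character(path))
    stop_jc("`path` must be a single file or directory path")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L)
      stop_jc("no CSV files found in '%s'", path)
    root <- path
  } else if (file.exists(path)) {
    files <- path
    root <- dirname(path)
  } else {
    stop_jc("path '%s' does not exist", path)
  }

  sidecar <- file.path(root, "dataset.json")
  side <- NULL
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    angle_unit <- side$angle_unit %||% angle_unit
    if (is.null(name)) name <- side$name
  }
  if (is.null(name)) name <- basename(normalizePath(root, mustWork = FALSE))

  joint_order <- NULL
  reps <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[[i]]
    df <- utils::read.csv(f, check.names = FALSE)
    if (ncol(df) < 1L) stop_jc("'%s' has no columns", f)
    has_time <- time_col %in% names(df)
    joints <- setdiff(names(df), time_col)
    if (length(joints) < 1L)
      stop_jc("'%s' has no joint columns besides '%s'", f, time_col)
    if (is.null(joint_order)) {
      joint_order <- joints
    } else if (!identical(sort(joints), sort(joint_order))) {
      stop_jc("joint columns in '%s' (%s) do not match the first file (%s)",
              f, paste(joints, collapse = ", "),
              paste(joint_order, collapse = ", "))
    }
    keep <- stats::complete.cases(df)
    if (!all(keep)) {
      warning(sprintf("'%s': dropped %d row(s) with missing cells",
                      f, sum(!keep)), call. = FALSE)
      df <- df[keep, , drop = FALSE]
    }
    meta <- parse_rep_meta(f, root, layout)
    reps[[i]] <- movement_repetition(
      angles = as.matrix(df[, joint_order, drop = FALSE]),
      time = if (has_time) df[[time_col]] else NULL,
      joint_names = joint_order, meta = meta)
  }
  movement_dataset(reps, name = name, angle_unit = angle_unit)
}

# Condition/target/repetition tags from the file path.
parse_rep_meta <- function(file, root, layout) {
  stem <- tools::file_path_sans_ext(basename(file))
  meta <- list(file = basename(file))
  cond <- basename(normalizePath(dirname(file), mustWork = FALSE))
  meta$condition <- cond
  m <- regmatches(stem, regexec("^(.*)_([0-9]+)$", stem))[[1L]]
  if (length(m) == 3L) {
    meta$target <- m[[2L]]
    meta$repetition <- as.integer(m[[3L]])
  }
  meta
}

#' Write a dataset as a directory of CSV files
#'
#' Mirrors [load_dataset()]: one CSV per repetition with a `time_s` column
#' (when the repetition has timestamps) followed by one column per joint, and
#' a `dataset.json` sidecar recording the dataset name, angle unit and joint
#' order. Repetitions carrying `target`/`repetition` metadata are written as
#' `<target>_<rep>.csv`; others as `rep_<i>.csv`.
#'
#' @param ds a [movement_dataset()].
#' @param path output directory (created, including parents, if needed).
#' @param overwrite logical; error if the directory already contains CSV
#'   files and this is `FALSE`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, overwrite = FALSE) {
  stopifnot(inherits(ds, "movement_dataset"))
  if (length(ds$repetitions) == 0L)
    stop_jc("refusing to write a dataset with no repetitions")
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop_jc("cannot create directory '%s'", path)
  existing <- list.files(path, pattern = "\\.csv$")
  if (length(existing) > 0L && !overwrite)
    stop_jc("'%s' already contains CSV files; use overwrite = TRUE", path)
  for (i in seq_along(ds$repetitions)) {
    r <- ds$repetitions[[i]]
    fname <- if (!is.null(r$meta$target) && !is.null(r$meta$repetition)) {
      sprintf("%s_%d.csv", r$meta$target, as.integer(r$meta$repetition))
    } else {
      sprintf("rep_%03d.csv", i)
    }
    df <- as.data.frame(r$angles, check.names = FALSE)
    if (!is.null(r$time)) df <- cbind(stats::setNames(data.frame(r$time), TIME_COL), df)
    utils::write.csv(df, file.path(path, fname), row.names = FALSE)
  }
  jsonlite::write_json(
    list(name = ds$name, angle_unit = ds$angle_unit,
         joint_names = ds$joint_names, n_repetitions = length(ds$repetitions)),
    file.path(path, "dataset.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load every condition folder under a root directory
#'
#' Convenience wrapper for the one-folder-per-condition tree: each
#' subdirectory of `root` containing CSV files becomes one dataset named
#' after the folder.
#'
#' @param root directory whose subdirectories are condition folders.
#' @inheritParams load_dataset
#' @return Named list of [movement_dataset()] objects.
#' @export
load_conditions <- function(root, angle_unit = "deg", time_col = TIME_COL) {
  if (!dir.exists(root)) stop_jc("'%s' is not a directory", root)
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[vapply(dirs, function(d)
    length(list.files(d, pattern = "\\.csv$")) > 0L, logical(1))]
  if (length(dirs) == 0L)
    stop_jc("no condition folders with CSV files under '%s'", root)
  out <- lapply(dirs, load_dataset, angle_unit = angle_unit, time_col = time_col)
  names(out) <- basename(dirs)
  out
}
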