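# JcvPCA: joint contribution variation via PCA reprojection.
#
# Pipeline: (1) PCA on the centered reference dataset A, giving an
# orthonormal frame R_A whose rows are PCs expressed over joints; (2) project
# the centered comparison dataset B into R_A; (3) re-run PCA on the projected
# data; (4) compose the comparison PCs back to joint space (the Joint
# Reprojection Weights, JRW) and subtract absolute weights per joint and PC;
# (5) optionally scale each PC's row by the reference explained-variance
# ratio. Positive entries mean the joint contributes more in the comparison
# dataset, negative entries less; everything lives in [-1, 1].

#' Principal component analysis of a centered movement dataset
#'
#' Computes the PCA of the concatenated samples of all repetitions via
#' singular value decomposition (numerically safer than forming the
#' covariance explicitly). Components are ordered by decreasing variance and
#' each eigenvector row is sign-flipped so that its largest-magnitude
#' coefficient is positive, which makes downstream results deterministic.
#' Covariance normalization uses 1/(N-1).
#'
#' A warning (not an error) is issued when the total sample count is below 5
#' samples per joint, the low end of the usual variable-to-factor guidance
#' for PCA sample sizes.
#'
#' @param ds a centered [movement_dataset()] (see [center_dataset()]).
#' @param m number of components to retain, `1 <= m <= n` joints. Default:
#'   all `n`.
#' @return An object of class `pca_frame` with fields `eigvecs` (m x n, rows
#'   are PCs over joints), `eigvals` (descending variances), `evr`
#'   (explained-variance ratios of the retained components), `joint_means`
#'   (per-joint offsets removed at centering), `m`, `n`, `joint_names`.
#' @export
fit_pca <- function(ds, m = NULL) {
  stopifnot(inherits(ds, "movement_dataset"))
  if (!isTRUE(ds$centered))
    stop_jc("fit_pca() expects a centered dataset; call center_dataset() first")
  X <- dataset_samples(ds)
  n <- ncol(X); N <- nrow(X)
  m <- m %||% n
  if (m < 1L || m > n)
    stop_jc("m = %d components requested but the dataset has n = %d joints", m, n)
  if (N < 5L * n)
    warning(sprintf(paste0("only %d samples for %d joints; at least %d ",
                           "(5 per joint) are recommended for a stable PCA"),
                    N, n, 5L * n), call. = FALSE)
  sv <- svd(X, nu = 0)
  eigvals <- sv$d^2 / (N - 1)
  V <- t(sv$v)                       # rows = PCs over joints
  for (u in seq_len(nrow(V))) {
    i <- which.max(abs(V[u, ]))
    if (V[u, i] < 0) V[u, ] <- -V[u, ]
  }
  tot <- sum(eigvals)
  evr <- if (tot > 0) eigvals / tot else rep(0, n)
  rn <- paste0("PC", seq_len(m))
  eigvecs <- V[seq_len(m), , drop = FALSE]
  dimnames(eigvecs) <- list(rn, ds$joint_names)
  structure(list(eigvecs = eigvecs,
                 eigvals = stats::setNames(eigvals[seq_len(m)], rn),
                 evr = stats::setNames(evr[seq_len(m)], rn),
                 joint_means = ds$joint_means %||% rep(0, n),
                 m = m, n = n, joint_names = ds$joint_names),
            class = "pca_frame")
}

#' @export
print.pca_frame <- function(x, ...) {
  cat(sprintf("<pca_frame> %d of %d components over joints: %s\n",
              x$m, x$n, paste(x$joint_names, collapse = ", ")))
  cat("explained variance ratio:",
      paste(sprintf("%s %.3f", names(x$evr), x$evr), collapse = ", "), "\n")
  invisible(x)
}

#' Project a dataset into a reference PCA frame
#'
#' Replaces every joint-space sample x by `eigvecs %*% x`, expressing the
#' comparison movements in the coordinates of the reference dataset's
#' principal components. Joint names and order must match the frame exactly;
#' no silent reordering is performed. The result carries PC labels instead of
#' joint labels and is flagged centered (the input must already be centered).
#'
#' @param ds a centered [movement_dataset()] with the same joints, in the
#'   same order, as `frame`.
#' @param frame a [fit_pca()] result.
#' @return A `movement_dataset` in PC coordinates (one column per retained
#'   component).
#' @export
reproject <- function(ds, frame) {
  stopifnot(inherits(ds, "movement_dataset"), inherits(frame, "pca_frame"))
  if (!isTRUE(ds$centered))
    stop_jc("reproject() expects a centered dataset")
  if (!identical(ds$joint_names, frame$joint_names))
    stop_jc("joint names/order of the dataset (%s) do not match the PCA frame (%s)",
            paste(ds$joint_names, collapse = ", "),
            paste(frame$joint_names, collapse = ", "))
  pc_names <- rownames(frame$eigvecs)
  reps <- lapply(ds$repetitions, function(r) {
    movement_repetition(angles = r$angles %*% t(frame$eigvecs),
                        time = r$time, joint_names = pc_names, meta = r$meta)
  })
  out <- movement_dataset(reps, name = paste0(ds$name, "@ref"),
                          angle_unit = ds$angle_unit, centered = TRUE)
  out$joint_means <- rep(0, frame$m)
  out
}

#' Joint Reprojection Weights
#'
#' Expresses the comparison dataset's principal components in the reference
#' dataset's joint space. With `C` the eigenvector rows of the PCA on the
#' projected comparison data (coordinates: reference PCs) and `R` the
#' reference eigenvector rows (coordinates: joints), the signed comparison
#' weights are `C %*% R`. The JRW stores the element-wise absolute values of
#' both weight matrices together with both explained-variance ratio vectors.
#' Rows of the signed matrices are unit-norm, so all weights lie in [0, 1].
#'
#' @param frame_ref `pca_frame` of the reference dataset (over joints).
#' @param frame_cmp `pca_frame` fitted on the comparison dataset after
#'   [reproject()]ion (over reference PC coordinates).
#' @return An object of class `jrw` with fields `ref_weights`, `cmp_weights`
#'   (m x n absolute weights), `signed_ref`, `signed_cmp`, `evr_ref`,
#'   `evr_cmp`.
#' @export
joint_reprojection_weights <- function(frame_ref, frame_cmp) {
  stopifnot(inherits(frame_ref, "pca_frame"), inherits(frame_cmp, "pca_frame"))
  if (frame_cmp$n != frame_ref$m)
    stop_jc("comparison frame spans %d coordinates but the reference retains %d PCs",
            frame_cmp$n, frame_ref$m)
  if (frame_cmp$m != frame_ref$m)
    stop_jc("frames retain different component counts (%d vs %d)",
            frame_cmp$m, frame_ref$m)
  signed_cmp <- frame_cmp$eigvecs %*% frame_ref$eigvecs
  dimnames(signed_cmp) <- dimnames(frame_ref$eigvecs)
  structure(list(ref_weights = abs(frame_ref$eigvecs),
                 cmp_weights = abs(signed_cmp),
                 signed_ref = frame_ref$eigvecs,
                 signed_cmp = signed_cmp,
                 evr_ref = frame_ref$evr,
                 evr_cmp = frame_cmp$evr),
            class = "jrw")
}

#' @export
print.jrw <- function(x, ...) {
  cat("<jrw> reference |weights|:\n"); print(round(x$ref_weights, 3))
  cat("comparison |weights| (in the reference joint space):\n")
  print(round(x$cmp_weights, 3))
  invisible(x)
}

#' JcvPCA: per-joint, per-PC contribution change between two datasets
#'
#' Quantifies how much each joint's contribution to each principal component
#' changes from a reference dataset to a comparison dataset. Both datasets
#' are centered (each on its own per-joint grand mean, which removes small
#' starting-posture offsets), the reference PCA frame is fitted, the
#' comparison data are reprojected into it and re-decomposed, and the
#' absolute joint weights are subtracted:
#'
#'   `delta[u, i] = |b[u, i]| - |a[u, i]|`
#'
#' where `a` are the reference weights and `b` the comparison weights
#' expressed in the reference joint space. A positive entry means joint `i`
#' contributes more to component `u` in the comparison dataset, a negative
#' entry less; entries lie in [-1, 1] and the result is the zero matrix when
#' the two datasets are identical. The comparison is intentionally
#' asymmetric: the reference dataset defines the frame, so `jcvpca(A, B)`
#' generally differs from `-jcvpca(B, A)`.
#'
#' The first `p` components (with `p` the task's degrees of freedom) describe
#' joints functionally used for the task; trailing components describe
#' redundant (null-space) coordination. `m = p + 1` is a good default, hence
#' the `task_dof` shortcut.
#'
#' @param ref reference [movement_dataset()] (defines the PCA frame).
#' @param cmp comparison dataset; same joints, same order.
#' @param m number of PCs to retain; default `task_dof + 1` when `task_dof`
#'   is given, else all joints.
#' @param task_dof minimum number of degrees of freedom of the task; used
#'   only to default `m`.
#' @param weight_by_evr if `TRUE`, also return `weighted_delta`, each PC row
#'   multiplied by the reference frame's explained-variance ratio (ratios
#'   rather than raw variances keep the result in [-1, 1]).
#' @return An object of class `jcvpca_result`: `delta` (m x n), optional
#'   `weighted_delta`, `jrw`, `frame_ref`, `frame_cmp`, `m`, `joint_names`.
#' @examples
#' sim <- make_sine_datasets(sine_spec())
#' jcvpca(sim$A, sim$B, m = 2)
#' @export
jcvpca <- function(ref, cmp, m = NULL, task_dof = NULL, weight_by_evr = FALSE) {
  stopifnot(inherits(ref, "movement_dataset"), inherits(cmp, "movement_dataset"))
  if (!identical(ref$joint_names, cmp$joint_names))
    stop_jc("reference and comparison datasets must share joint names and order")
  n <- n_joints(ref)
  if (is.null(m)) m <- if (!is.null(task_dof)) min(task_dof + 1L, n) else n
  ref_c <- ensure_centered(ref)
  cmp_c <- ensure_centered(cmp)
  frame_ref <- fit_pca(ref_c, m = m)
  projected <- reproject(cmp_c, frame_ref)
  frame_cmp <- fit_pca(projected, m = m)
  jrw <- joint_reprojection_weights(frame_ref, frame_cmp)
  delta <- jrw$cmp_weights - jrw$ref_weights
  weighted <- if (isTRUE(weight_by_evr)) delta * as.vector(frame_ref$evr) else NULL
  structure(list(delta = delta, weighted_delta = weighted, jrw = jrw,
                 frame_ref = frame_ref, frame_cmp = frame_cmp,
                 m = m, joint_names = ref$joint_names,
                 ref_name = ref$name, cmp_name = cmp$name),
            class = "jcvpca_result")
}

#' @export
print.jcvpca_result <- function(x, digits = 3, ...) {
  cat(sprintf("<jcvpca_result> '%s' vs reference '%s' (m = %d)\n",
              x$cmp_name, x$ref_name, x$m))
  cat("delta (positive = joint more used in the comparison dataset):\n")
  print(round(x$delta, digits))
  if (!is.null(x$weighted_delta)) {
    cat("delta weighted by reference explained-variance ratio:\n")
    print(round(x$weighted_delta, digits))
  }
  invisible(x)
}

#' Bar plot of JcvPCA contribution changes
#'
#' @param x a `jcvpca_result`.
#' @param pc which component row to plot (default 1).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.jcvpca_result <- function(x, pc = 1, ...) {
  graphics::barplot(x$delta[pc, ], ylim = c(-1, 1),
                    ylab = sprintf("contribution change (PC%d)", pc),
                    main = sprintf("JcvPCA: %s vs %s", x$cmp_name, x$ref_name),
                    ...)
}

#' Bootstrap stability of a reference PCA frame
#'
#' Refits the PCA on datasets whose repetitions are resampled with
#' replacement and reports the maximum row-wise eigenvector deviation (after
#' sign alignment) from the full-data frame. Small values indicate the
#' repetition count is sufficient for a stable frame.
#'
#' @param ds a [movement_dataset()] with at least 2 repetitions.
#' @param m components to retain.
#' @param n_boot number of bootstrap resamples.
#' @param seed optional integer seed.
#' @return list with `max_deviation` (scalar), `per_boot` (vector of maximum
#'   absolute eigenvector coefficient deviations per resample).
#' @export
pca_stability <- function(ds, m = NULL, n_boot = 50L, seed = NULL) {
  stopifnot(inherits(ds, "movement_dataset"))
  if (n_repetitions(ds) < 2L)
    stop_jc("bootstrap stability needs at least 2 repetitions")
  if (!is.null(seed)) set.seed(seed)
  base <- fit_pca(ensure_centered(ds), m = m)
  dev <- vapply(seq_len(n_boot), function(b) {
    idx <- sample(n_repetitions(ds), replace = TRUE)
    fb <- suppressWarnings(fit_pca(ensure_centered(subset_repetitions(ds, idx)),
                                   m = base$m))
    d <- 0
    for (u in seq_len(base$m)) {
      v1 <- base$eigvecs[u, ]; v2 <- fb$eigvecs[u, ]
      if (sum(v1 * v2) < 0) v2 <- -v2       # sign-align before comparing
      d <- max(d, max(abs(v1 - v2)))
    }
    d
  }, numeric(1))
  list(max_deviation = max(dev), per_boot = dev)
}
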