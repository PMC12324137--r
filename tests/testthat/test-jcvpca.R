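test_that("PCA of whole-period two-sine data matches the closed-form eigenpairs", {
  pair <- exact_sine_pair()
  frame <- fit_pca(center_dataset(pair$A))
  oracle <- eig2x2(sine_cov(shift = 1))        # [[0.5, cos 1], [cos 1, 2]]
  # discrete sampling over whole periods is exact up to the 1/(N-1) factor
  expect_equal(unname(frame$eigvals), oracle$values, tolerance = 1e-3)
  expect_equal(unname(frame$eigvecs), oracle$vectors, tolerance = 1e-3)
  expect_equal(oracle$values, c(2.1743, 0.3257), tolerance = 1e-4)
})

test_that("uncorrelated joints give axis-aligned PCs with variance-ratio EVR", {
  n <- 8000L
  t <- (seq_len(n) - 1) / n
  # sin and cos of the same frequency are orthogonal over whole periods;
  # amplitudes chosen for variances 2 and 0.5
  rep1 <- movement_repetition(cbind(j1 = 2 * sin(2 * pi * t),
                                    j2 = cos(2 * pi * t)))
  ds <- center_dataset(movement_dataset(list(rep1), angle_unit = "rad"))
  frame <- fit_pca(ds)
  expect_equal(unname(frame$evr), c(0.8, 0.2), tolerance = 1e-3)
  expect_equal(abs(unname(frame$eigvecs)), diag(2), tolerance = 1e-3)
})

test_that("duplicated joints give rank-1 data with all variance on PC1", {
  x <- sin(seq(0, 10, 0.05))
  rep1 <- movement_repetition(cbind(a = x, b = x))
  frame <- fit_pca(center_dataset(movement_dataset(list(rep1))))
  expect_equal(unname(frame$evr), c(1, 0), tolerance = 1e-12)
})

test_that("fit_pca validates inputs and warns on small samples", {
  ds <- random_dataset(n_joints = 2L, n_reps = 1L, n_samples = 30L)
  expect_error(fit_pca(ds), "centered")
  cds <- center_dataset(ds)
  expect_error(fit_pca(cds, m = 3), "joints")
  small <- center_dataset(movement_dataset(list(movement_repetition(
    matrix(rnorm(8), 4, 2), joint_names = c("a", "b")))))
  expect_warning(fit_pca(small), "recommended")
})

test_that("self-projection yields the identity frame and preserves variance", {
  ds <- center_dataset(random_dataset(n_joints = 3L, seed = 21))
  frame <- fit_pca(ds)
  proj <- reproject(ds, frame)
  refit <- fit_pca(proj)
  expect_equal(unname(refit$eigvecs), diag(3), tolerance = 1e-9)
  expect_equal(sum(diag(stats::cov(dataset_samples(proj)))),
               sum(diag(stats::cov(dataset_samples(ds)))), tolerance = 1e-9)
})

test_that("reprojection refuses mismatched joints and uncentered data", {
  ds <- center_dataset(random_dataset(n_joints = 2L, seed = 2))
  frame <- fit_pca(ds)
  other <- center_dataset(random_dataset(n_joints = 2L, seed = 3))
  other$joint_names <- rev(other$joint_names)
  expect_error(reproject(other, frame), "joint names")
  expect_error(reproject(random_dataset(n_joints = 2L, seed = 2), frame),
               "centered")
})

test_that("projected covariance of dataset B in frame A matches the matrix product", {
  pair <- exact_sine_pair()
  frame <- fit_pca(center_dataset(pair$A))
  proj <- reproject(center_dataset(pair$B), frame)
  emp <- dataset_cov(proj)
  R <- eig2x2(sine_cov(1))$vectors
  analytic <- R %*% sine_cov(pi / 2) %*% t(R)
  expect_equal(unname(emp), analytic, tolerance = 1e-3)
  expect_equal(abs(analytic),
               matrix(c(1.8587, 0.4384, 0.4384, 0.6414), 2), tolerance = 1e-4)
})

test_that("JRW expresses comparison PCs in the reference joint space", {
  pair <- exact_sine_pair()
  res <- jcvpca(pair$A, pair$B)
  # dataset B is uncorrelated with variances (0.5, 2): its first PC is
  # theta2 alone, whatever the intermediate frame
  expect_equal(unname(res$jrw$cmp_weights[1, ]), c(0, 1), tolerance = 1e-2)
  # signed rows of both weight matrices are unit norm
  expect_equal(unname(rowSums(res$jrw$signed_cmp^2)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(rowSums(res$jrw$signed_ref^2)), c(1, 1), tolerance = 1e-9)
  # frame compared with itself reproduces the reference weights
  f <- fit_pca(center_dataset(pair$A))
  self_proj <- fit_pca(reproject(center_dataset(pair$A), f))
  jrw_self <- joint_reprojection_weights(f, self_proj)
  expect_equal(jrw_self$cmp_weights, jrw_self$ref_weights, tolerance = 1e-9)
})

test_that("jcvpca of a dataset with itself is identically zero", {
  for (seed in 1:3) {
    ds <- random_dataset(n_joints = 3L, seed = seed)
    res <- jcvpca(ds, ds)
    expect_equal(max(abs(res$delta)), 0, tolerance = 1e-9)
  }
})

test_that("jcvpca deltas stay in [-1, 1] and preserve the comparison spectrum", {
  for (seed in 4:6) {
    ref <- random_dataset(n_joints = 3L, seed = seed)
    cmp <- random_dataset(n_joints = 3L, seed = seed + 100)
    res <- jcvpca(ref, cmp)
    expect_true(all(res$delta >= -1 & res$delta <= 1))
    # orthonormal change of basis preserves the eigenvalues of the re-PCA
    direct <- fit_pca(center_dataset(cmp))
    expect_equal(unname(res$frame_cmp$eigvals), unname(direct$eigvals),
                 tolerance = 1e-9)
  }
})

test_that("jcvpca is asymmetric when comparing within a retained subspace", {
  # with all n components retained the comparison weights reduce to the
  # comparison dataset's own eigenvectors, which makes the metric exactly
  # antisymmetric; retaining m < n components (the recommended task_dof + 1
  # usage) projects into a subspace of the reference frame, and the choice
  # of reference then matters
  ref <- random_dataset(n_joints = 3L, seed = 31)
  cmp <- random_dataset(n_joints = 3L, seed = 32)
  full_ab <- jcvpca(ref, cmp)$delta
  full_ba <- jcvpca(cmp, ref)$delta
  expect_equal(full_ab, -full_ba, tolerance = 1e-9)
  ab <- jcvpca(ref, cmp, m = 2L)$delta
  ba <- jcvpca(cmp, ref, m = 2L)$delta
  expect_gt(max(abs(ab + ba)), 1e-3)
})

test_that("the SVD pipeline reproduces the closed-form covariance oracle", {
  for (seed in 7:11) {
    ref <- random_dataset(n_joints = 2L, n_reps = 2L, seed = seed)
    cmp <- random_dataset(n_joints = 2L, n_reps = 2L, seed = seed + 50)
    expect_equal(unname(jcvpca(ref, cmp)$delta),
                 jcvpca_oracle_2joint(ref, cmp), tolerance = 1e-8)
  }
})

test_that("swapping the joint columns flips the frame by 90 degrees", {
  pair <- exact_sine_pair()
  swapped_rep <- pair$A$repetitions[[1]]
  swapped_rep$angles <- swapped_rep$angles[, c(2, 1)]
  colnames(swapped_rep$angles) <- c("theta1", "theta2")
  swapped <- movement_dataset(list(swapped_rep), name = "A_swapped",
                              angle_unit = "rad")
  res <- jcvpca(pair$A, swapped)
  ref_w <- res$jrw$ref_weights
  cmp_w <- res$jrw$cmp_weights
  # PC1 weights exchange between the two joints
  expect_equal(unname(cmp_w[1, ]), unname(ref_w[1, c(2, 1)]), tolerance = 1e-6)
  expect_equal(unname(cmp_w[2, ]), unname(ref_w[2, c(2, 1)]), tolerance = 1e-6)
})

test_that("explained-variance weighting scales rows by the reference EVR", {
  ref <- random_dataset(n_joints = 3L, seed = 41)
  cmp <- random_dataset(n_joints = 3L, seed = 42)
  res <- jcvpca(ref, cmp, weight_by_evr = TRUE)
  expect_equal(res$weighted_delta,
               res$delta * as.vector(res$frame_ref$evr))
  expect_true(all(abs(res$weighted_delta) <= abs(res$delta) + 1e-12))
})

test_that("task_dof defaults m to one more than the task's degrees of freedom", {
  ds <- random_dataset(n_joints = 3L, seed = 51)
  res <- jcvpca(ds, ds, task_dof = 1L)
  expect_equal(res$m, 2L)
  expect_equal(dim(res$delta), c(2L, 3L))
})

test_that("bootstrap PCA stability is tight on abundant clean data", {
  ds <- random_dataset(n_joints = 2L, n_reps = 8L, n_samples = 200L, seed = 61)
  st <- pca_stability(ds, n_boot = 20L, seed = 1L)
  expect_lt(st$max_deviation, 0.2)
  expect_length(st$per_boot, 20L)
})
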