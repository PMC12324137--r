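# Fixtures built in code, shared across test files.

# Random multi-repetition dataset with correlated joints.
random_dataset <- function(n_joints = 2L, n_reps = 3L, n_samples = 60L,
                           seed = 1L, name = "random", with_time = TRUE) {
  set.seed(seed)
  mix <- matrix(stats::rnorm(n_joints^2), n_joints)
  reps <- lapply(seq_len(n_reps), function(i) {
    latent <- matrix(stats::rnorm(n_samples * n_joints), n_samples)
    movement_repetition(latent %*% mix,
                        time = if (with_time) seq(0, 1, length.out = n_samples),
                        joint_names = paste0("j", seq_len(n_joints)),
                        meta = list(repetition = i))
  })
  movement_dataset(reps, name = name, angle_unit = "deg")
}

# Two-sine dataset pair sampled over exact whole periods WITHOUT the
# duplicated endpoint, so discrete sinusoid moments match the analytic
# covariance up to the 1/(N-1) factor.
exact_sine_pair <- function(n = 4000L, periods = 4L, shift_a = 1,
                            shift_b = pi / 2, ratio = 2) {
  t <- (seq_len(n) - 1) / n * periods           # frequency 1 Hz
  one <- function(shift) {
    movement_repetition(cbind(theta1 = sin(2 * pi * t),
                              theta2 = ratio * sin(2 * pi * t + shift)),
                        time = t)
  }
  list(A = movement_dataset(list(one(shift_a)), name = "A", angle_unit = "rad"),
       B = movement_dataset(list(one(shift_b)), name = "B", angle_unit = "rad"))
}

# Closed-form eigendecomposition of a symmetric 2x2 matrix; rows of $vectors
# are eigenvectors ordered by decreasing eigenvalue, sign convention:
# largest-magnitude coefficient positive. Independent oracle for the
# SVD-based PCA path.
eig2x2 <- function(C) {
  tr <- C[1, 1] + C[2, 2]
  det <- C[1, 1] * C[2, 2] - C[1, 2] * C[2, 1]
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  vals <- c(tr / 2 + disc, tr / 2 - disc)
  vecs <- matrix(0, 2, 2)
  for (i in 1:2) {
    v <- if (abs(C[1, 2]) > 1e-14) {
      c(C[1, 2], vals[i] - C[1, 1])
    } else if (C[1, 1] >= C[2, 2]) {
      if (i == 1) c(1, 0) else c(0, 1)
    } else {
      if (i == 1) c(0, 1) else c(1, 0)
    }
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    vecs[i, ] <- v
  }
  list(values = vals, vectors = vecs)
}

# Sample covariance (1/(N-1)) of a dataset's centered concatenated samples.
dataset_cov <- function(ds) {
  X <- dataset_samples(center_dataset(ds))
  crossprod(X) / (nrow(X) - 1)
}

# Full JcvPCA for 2 joints via the explicit-covariance closed-form route:
# an independent oracle for the SVD/reprojection pipeline.
jcvpca_oracle_2joint <- function(ref, cmp) {
  CA <- dataset_cov(ref)
  CB <- dataset_cov(cmp)
  ea <- eig2x2(CA)
  R <- ea$vectors
  Cproj <- R %*% CB %*% t(R)
  eb <- eig2x2(Cproj)
  b <- eb$vectors %*% R
  abs(b) - abs(R)
}

# Analytic covariance of the two-sine pair with base amplitude a and ratio k:
# var(theta1) = a^2/2, var(theta2) = k^2 a^2 / 2, cov = k a^2 cos(shift) / 2.
sine_cov <- function(shift, a = 1, k = 2) {
  matrix(c(a^2 / 2, k * a^2 * cos(shift) / 2,
           k * a^2 * cos(shift) / 2, k^2 * a^2 / 2), 2, 2)
}

# Analysis conventions used for simulated reaching (encoder-like) data:
# low-pass filter before differentiation, noise guard at the generator's
# peak-to-peak noise band.
reach_crp_args <- function() list(noise_range = 2, smooth = TRUE, cutoff_hz = 5)

# Thin accessors for internal helpers exercised by property tests.
wrap_pi_test <- function(x) jointcoord:::wrap_pi(x)
rep_crp_test <- function(repn, pair = c(1L, 2L)) jointcoord:::rep_crp(repn, pair)
new_curve_test <- function(grid, values) {
  jointcoord:::new_crp_curve(grid = grid, values = values,
                             pair = c("a", "b"), axis = "percent")
}
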