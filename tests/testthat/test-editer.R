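rand_cplx <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

test_that("a noiseless convolved line recovers its kernel exactly", {
  set.seed(101)
  n <- 128
  w <- 3L
  d <- rand_cplx(n)
  h <- rand_cplx(2 * w + 1)
  primary <- as.vector(mrconsole:::editer_conv_matrix(d, w) %*% h)
  sol <- estimate_kernels(primary, d, editer_config(kernel_half_width = w))
  expect_lt(max(Mod(sol$kernels[, 1] - h)) / max(Mod(h)), 1e-8)
  expect_lt(sqrt(sum(Mod(sol$residual)^2) / sum(Mod(primary)^2)), 1e-10)
})

test_that("two detectors with independent signals are both recovered", {
  set.seed(102)
  n <- 192
  w <- 2L
  d1 <- rand_cplx(n); d2 <- rand_cplx(n)
  h1 <- rand_cplx(2 * w + 1); h2 <- rand_cplx(2 * w + 1)
  primary <- as.vector(mrconsole:::editer_conv_matrix(d1, w) %*% h1 +
                       mrconsole:::editer_conv_matrix(d2, w) %*% h2)
  sol <- estimate_kernels(primary, cbind(d1, d2),
                          editer_config(kernel_half_width = w))
  expect_lt(max(Mod(sol$kernels[, 1] - h1)), 1e-8)
  expect_lt(max(Mod(sol$kernels[, 2] - h2)), 1e-8)
})

test_that("all-zero detectors give zero kernels and an untouched residual", {
  set.seed(103)
  primary <- rand_cplx(64)
  sol <- estimate_kernels(primary, rep(0i, 64), editer_config())
  expect_true(all(sol$kernels == 0))
  expect_equal(sol$residual, primary)
})

test_that("rank-deficient systems error and advise regularization", {
  set.seed(109)
  d <- rand_cplx(128)
  # two identical detectors: their convolution columns coincide exactly
  expect_error(estimate_kernels(2 * d, cbind(d, d), editer_config()),
               "regularization")
  # narrowband interference is near-collinear; ridge keeps it solvable
  tau <- (0:127) / 128
  tone <- exp(2i * pi * 5 * tau)
  sol <- estimate_kernels(2 * tone, tone,
                          editer_config(solver_regularization = 1e-6))
  expect_lt(sqrt(sum(Mod(unlist(sol$residual))^2) / sum(Mod(2 * tone)^2)), 0.01)
})

test_that("the least-squares solution matches a brute-force pseudoinverse", {
  set.seed(104)
  n <- 96
  w <- 2L
  d <- rand_cplx(n)
  primary <- rand_cplx(n)               # generic primary, not in the span
  A <- mrconsole:::editer_conv_matrix(d, w)
  h_brute <- solve(Conj(t(A)) %*% A, Conj(t(A)) %*% primary)
  sol <- estimate_kernels(primary, d, editer_config(kernel_half_width = w))
  expect_equal(as.vector(sol$kernels), as.vector(h_brute), tolerance = 1e-8)
})

test_that("grouping merges stationary kernels and splits regime changes", {
  set.seed(105)
  k0 <- rand_cplx(7)
  stationary <- do.call(rbind, replicate(10, rbind(k0), simplify = FALSE))
  expect_identical(unique(group_lines(stationary,
                                      editer_config(max_group_size = 32))), 1L)

  noisy <- do.call(rbind, lapply(1:10, function(i) rbind(rand_cplx(7))))
  expect_identical(group_lines(noisy, editer_config(group_correlation_threshold = 1)),
                   1:10)

  k1 <- rand_cplx(7)
  switch_mid <- rbind(stationary[1:5, ],
                      do.call(rbind, replicate(5, rbind(k1), simplify = FALSE)))
  grp <- group_lines(switch_mid, editer_config(group_correlation_threshold = 0.9,
                                               max_group_size = 32))
  expect_identical(grp, rep(1:2, each = 5))
})

test_that("EDITER is the identity on interference-free data", {
  set.seed(106)
  P <- array(rand_cplx(2 * 16 * 32), dim = c(2, 1, 16, 32))
  D <- array(0i, dim = c(2, 2, 16, 32))
  out <- apply_editer(P, D)
  expect_identical(out, P)
})

test_that("joint group re-solve beats the averaged per-line kernels", {
  set.seed(107)
  n <- 64; w <- 2L; lines <- 6L
  h_true <- rand_cplx(2 * w + 1)
  dets <- lapply(seq_len(lines), function(i) rand_cplx(n))
  prims <- lapply(dets, function(d)
    as.vector(mrconsole:::editer_conv_matrix(d, w) %*% h_true) +
      0.3 * rand_cplx(n))
  per_line <- lapply(seq_len(lines), function(i)
    estimate_kernels(prims[[i]], dets[[i]], editer_config(kernel_half_width = w)))
  h_avg <- Reduce(`+`, lapply(per_line, function(s) s$kernels[, 1])) / lines
  rss_avg <- sum(vapply(seq_len(lines), function(i) {
    pred <- as.vector(mrconsole:::editer_conv_matrix(dets[[i]], w) %*% h_avg)
    sum(Mod(prims[[i]] - pred)^2)
  }, numeric(1)))
  joint <- mrconsole:::editer_solve(prims, lapply(dets, cbind), w, 0)
  rss_joint <- sum(vapply(joint$residual, function(r) sum(Mod(r)^2), numeric(1)))
  expect_lte(rss_joint, rss_avg + 1e-9)
})

test_that("known-kernel tone interference is removed to below 1 percent", {
  # noiseless, no MR signal: the residual energy after correction is
  # bounded by the least-squares fit quality
  set.seed(108)
  n_enc <- 12L; n_read <- 48L
  tau <- (seq_len(n_read) - 1) / n_read
  P <- array(0i, dim = c(1, 1, n_enc, n_read))
  D <- array(0i, dim = c(1, 1, n_enc, n_read))
  k <- complex(real = 0.8, imaginary = -0.4)
  for (e in seq_len(n_enc)) {
    tone <- 50 * exp(2i * pi * 3.3 * tau + 2i * pi * 0.13 * e)
    D[1, 1, e, ] <- tone
    P[1, 1, e, ] <- k * tone
  }
  out <- apply_editer(P, D, editer_config(kernel_half_width = 1,
                                          solver_regularization = 1e-8))
  expect_lt(sum(Mod(out)^2) / sum(Mod(P)^2), 0.01)
})
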