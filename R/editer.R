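#' EDITER configuration
#'
#' Settings for convolutional external-sensor interference removal: the
#' temporal half-width of the detector-to-primary transfer kernels, the
#' normalized kernel correlation above which chronologically adjacent
#' k-space lines are merged into one jointly solved group, the maximum group
#' size, and an optional ridge penalty for ill-conditioned solves.
#'
#' @param kernel_half_width kernel half width in taps (kernel length is
#'   `2 * kernel_half_width + 1`).
#' @param group_correlation_threshold in `[0, 1]`; a line joins the current
#'   group when its kernel's normalized inner product with the group mean is
#'   at least this value.
#' @param max_group_size maximum number of lines per group.
#' @param solver_regularization unitless ridge penalty, `>= 0`, expressed
#'   relative to the squared largest singular value of the convolution
#'   operator (so it is invariant to the interference scale). Narrowband
#'   interference makes the tap directions nearly collinear; a small value
#'   (e.g. 0.01) stabilizes the kernels in that regime.
#' @return A list of class `editer_config`.
#' @export
editer_config <- function(kernel_half_width = 3L,
                          group_correlation_threshold = 0.5,
                          max_group_size = 16L,
                          solver_regularization = 0) {
  stopifnot(kernel_half_width >= 0,
            group_correlation_threshold >= 0, group_correlation_threshold <= 1,
            max_group_size >= 1, solver_regularization >= 0)
  structure(list(kernel_half_width = as.integer(kernel_half_width),
                 group_correlation_threshold = group_correlation_threshold,
                 max_group_size = max_group_size,
                 solver_regularization = solver_regularization),
            class = "editer_config")
}

# Columns of the (centred, zero-padded) convolution operator of a detector
# line: column k applies tap shift k - w - 1, shifts running -w..w.
editer_conv_matrix <- function(d, w) {
  n <- length(d)
  taps <- 2L * w + 1L
  A <- matrix(0i, nrow = n, ncol = taps)
  for (k in seq_len(taps)) {
    s <- k - w - 1L
    src <- seq_len(n) - s
    ok <- src >= 1L & src <= n
    A[ok, k] <- d[src[ok]]
  }
  A
}

# Joint complex least squares over one or several lines sharing a kernel
# set: primary ~ sum_d conv(detector_d, kernel_d). `primaries` is a list of
# complex vectors, `det_mats` a list of matching samples-x-detectors
# matrices; the per-line convolution operators are stacked so no
# convolution bleeds across line boundaries.
editer_solve <- function(primaries, det_mats, w, lambda) {
  if (!is.list(primaries)) { primaries <- list(primaries); det_mats <- list(det_mats) }
  n_det <- ncol(det_mats[[1]])
  taps <- 2L * w + 1L
  A <- do.call(rbind, lapply(det_mats, function(dm)
    do.call(cbind, lapply(seq_len(n_det), function(d)
      editer_conv_matrix(dm[, d], w)))))
  p <- unlist(primaries)
  nz <- colSums(Mod(A)) > 0
  h <- rep(0i, ncol(A))
  if (any(nz)) {
    sv <- svd(A[, nz, drop = FALSE])
    dtol <- max(sv$d) * 1e-10
    if (lambda == 0 && any(sv$d <= dtol))
      stopf(paste0("EDITER system is rank deficient (detector lines are ",
                   "linearly dependent); set solver_regularization > 0"))
    # ridge is relative to the squared largest singular value (unitless)
    gain <- sv$d / (sv$d^2 + lambda * max(sv$d)^2)
    gain[sv$d <= dtol] <- 0
    h[nz] <- sv$v %*% (gain * (Conj(t(sv$u)) %*% p))
  }
  pred <- as.vector(A %*% h)
  lens <- lengths(primaries)
  idx <- split(seq_along(p), rep(seq_along(lens), lens))
  list(kernels = matrix(h, nrow = taps),        # taps x detectors
       predicted = lapply(idx, function(i) pred[i]),
       residual = lapply(idx, function(i) (p - pred)[i]))
}

#' Estimate detector-to-primary transfer kernels
#'
#' Joint least-squares fit of `primary ~ sum_d conv(detector_d, kernel_d)`
#' over all detectors simultaneously, with optional ridge regularization.
#' Kernels are complex FIR taps of length `2 * kernel_half_width + 1`.
#' A rank-deficient system (e.g. linearly dependent detector lines) is an
#' error unless `solver_regularization > 0`; all-zero detector lines yield
#' zero kernels and a residual equal to the primary.
#'
#' @param primary_line complex vector (one readout line of the MR channel).
#' @param detector_lines complex matrix (samples x detectors) or a list of
#'   equal-length complex vectors.
#' @param cfg an [editer_config()].
#' @return List with `kernels` (taps x detectors complex matrix),
#'   `predicted` and `residual` vectors.
#' @export
estimate_kernels <- function(primary_line, detector_lines,
                             cfg = editer_config()) {
  if (is.list(detector_lines)) detector_lines <- do.call(cbind, detector_lines)
  if (!is.matrix(detector_lines)) detector_lines <- cbind(detector_lines)
  n <- length(primary_line)
  if (nrow(detector_lines) != n)
    stopf("primary and detector lines must have equal length")
  w <- cfg$kernel_half_width
  if (n <= (2L * w + 1L) * ncol(detector_lines))
    stopf("line length %d too short for %d detectors with %d taps",
          n, ncol(detector_lines), 2L * w + 1L)
  sol <- editer_solve(primary_line, detector_lines, w,
                      cfg$solver_regularization)
  list(kernels = sol$kernels, predicted = sol$predicted[[1]],
       residual = sol$residual[[1]])
}

#' Group k-space lines by kernel similarity
#'
#' Greedy chronological grouping: a line joins the current group when the
#' normalized inner product between its kernel vector and the group's mean
#' kernel is at least the configured threshold and the group is not full;
#' otherwise it starts a new group. Groups are intended for a joint
#' re-solve ([apply_editer()]), which stabilizes the kernel estimates while
#' the interference coupling is stationary and splits the estimate where
#' the coupling changes mid-scan.
#'
#' @param kernels complex matrix, one row per line (all detector kernels of
#'   the line concatenated).
#' @param cfg an [editer_config()].
#' @return Integer vector of group ids, one per line.
#' @export
group_lines <- function(kernels, cfg = editer_config()) {
  if (!is.matrix(kernels)) kernels <- rbind(kernels)
  n <- nrow(kernels)
  groups <- integer(n)
  gid <- 0L
  g_sum <- NULL
  g_n <- 0L
  for (i in seq_len(n)) {
    ki <- kernels[i, ]
    ni <- sqrt(sum(Mod(ki)^2))
    sim <- -1
    if (gid > 0L && g_n < cfg$max_group_size) {
      g_mean <- g_sum / g_n
      nm <- sqrt(sum(Mod(g_mean)^2))
      if (ni > 0 && nm > 0)
        sim <- Mod(sum(ki * Conj(g_mean))) / (ni * nm)
    }
    if (sim >= cfg$group_correlation_threshold) {
      groups[i] <- gid
      g_sum <- g_sum + ki
      g_n <- g_n + 1L
    } else {
      gid <- gid + 1L
      groups[i] <- gid
      g_sum <- ki
      g_n <- 1L
    }
  }
  groups
}

#' Remove external interference from k-space (EDITER)
#'
#' For every k-space line of the primary (MR) channel, transfer kernels from
#' each detector channel are estimated by least squares; lines with similar
#' kernels are grouped ([group_lines()]) and each group is re-solved jointly
#' with one kernel set per group; the predicted interference is subtracted
#' line by line. With all-zero detector channels the output is identical to
#' the input.
#'
#' @param kspace_primary `kspace_data` with a single (MR) coil, or a complex
#'   array `[averages, 1, encodings, readout]`.
#' @param kspace_detectors `kspace_data` or array with the detector
#'   channels, time-aligned with the primary (same gates).
#' @param cfg an [editer_config()].
#' @return Corrected object of the same class as `kspace_primary`; the
#'   per-line group assignment is attached as attribute `editer_groups`.
#' @export
apply_editer <- function(kspace_primary, kspace_detectors,
                         cfg = editer_config()) {
  prim_is_ks <- inherits(kspace_primary, "kspace_data")
  P <- if (prim_is_ks) kspace_primary$data else kspace_primary
  D <- if (inherits(kspace_detectors, "kspace_data")) kspace_detectors$data
       else kspace_detectors
  if (length(dim(P)) != 4L || length(dim(D)) != 4L)
    stopf("expected [averages, coils, encodings, readout] arrays")
  if (!all(dim(P)[c(1, 3, 4)] == dim(D)[c(1, 3, 4)]))
    stopf("primary and detector k-space shapes do not match")
  if (dim(P)[2] != 1L)
    stopf("primary k-space must hold exactly one (MR) channel")
  if (all(D == 0)) return(kspace_primary)

  n_avg <- dim(P)[1]; n_enc <- dim(P)[3]
  n_det <- dim(D)[2]
  w <- cfg$kernel_half_width
  out <- P
  groups_all <- matrix(NA_integer_, n_avg, n_enc)
  for (a in seq_len(n_avg)) {
    det_of <- function(e) t(matrix(D[a, , e, ], nrow = n_det))
    per_line <- lapply(seq_len(n_enc), function(e)
      estimate_kernels(P[a, 1, e, ], det_of(e), cfg))
    K <- do.call(rbind, lapply(per_line, function(s) as.vector(s$kernels)))
    grp <- group_lines(K, cfg)
    groups_all[a, ] <- grp
    for (g in unique(grp)) {
      lines <- which(grp == g)
      if (length(lines) == 1L) {
        out[a, 1, lines, ] <- per_line[[lines]]$residual
      } else {
        sol <- editer_solve(lapply(lines, function(e) P[a, 1, e, ]),
                            lapply(lines, det_of), w,
                            cfg$solver_regularization)
        for (k in seq_along(lines))
          out[a, 1, lines[k], ] <- sol$residual[[k]]
      }
    }
  }
  if (prim_is_ks) {
    kspace_primary$data <- out
    attr(kspace_primary, "editer_groups") <- groups_all
    kspace_primary
  } else structure(out, editer_groups = groups_all)
}
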