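#' Fourier reconstruction of fully sampled Cartesian k-space
#'
#' Averages are combined by mean before the transform; each coil is
#' reconstructed with a centred, orthonormal inverse discrete Fourier
#' transform over all encoded dimensions (so total k-space energy equals
#' total image energy). Multi-coil magnitudes are combined by
#' root-sum-of-squares. Non-full sampling (any unfilled k-space entry) is an
#' error — no gridding or partial-Fourier handling is attempted.
#'
#' @param kspace a `kspace_data` object (see [sort_kspace()]), or a complex
#'   array `[averages, coils, encodings, readout]`.
#' @param matrix_pe for 3D data, length-2 integer `(PE1, PE2)` to unflatten
#'   the encoding dimension; `NULL` treats encodings as a single dimension.
#' @param fov field of view in m per image axis (readout first), for voxel
#'   size metadata.
#' @return An object of class `mr_image` with `magnitude` (array, image
#'   axes readout x PE1 (x PE2)), `complexdata` (per-coil complex array),
#'   `fov` and `voxel_size` in mm.
#' @export
fft_recon <- function(kspace, matrix_pe = NULL, fov = NULL) {
  K <- if (inherits(kspace, "kspace_data")) kspace$data else kspace
  if (length(dim(K)) != 4L)
    stopf("expected a [averages, coils, encodings, readout] array")
  if (anyNA(K))
    stopf("k-space is not fully sampled; Fourier reconstruction requires full Cartesian data")
  d <- dim(K)
  n_coil <- d[2]; n_enc <- d[3]; n_read <- d[4]
  if (d[1] > 1L) {
    Km <- array(0i, dim = c(1L, d[2], d[3], d[4]))
    Km[1, , , ] <- colMeans(K, dims = 1)
    K <- Km
  }
  dims_img <- if (is.null(matrix_pe)) c(n_read, n_enc)
              else c(n_read, matrix_pe[1], matrix_pe[2])
  if (prod(dims_img) != n_read * n_enc)
    stopf("matrix_pe %s incompatible with %d encodings",
          paste(matrix_pe, collapse = "x"), n_enc)
  imgs <- array(0i, dim = c(n_coil, dims_img))
  for (c_i in seq_len(n_coil)) {
    # readout along dim 1, PE1 dim 2, PE2 dim 3
    kc <- t(matrix(K[1, c_i, , ], nrow = n_enc))
    if (!is.null(matrix_pe)) dim(kc) <- c(n_read, matrix_pe[1], matrix_pe[2])
    ic <- centered_ifft(kc)
    if (n_coil == 1L && is.null(matrix_pe)) imgs[1, , ] <- ic
    else {
      idx <- slice.index(imgs, 1) == c_i
      imgs[idx] <- ic
    }
  }
  mag <- sqrt(apply(Mod(imgs)^2, seq_along(dims_img) + 1L, sum))
  voxel <- if (!is.null(fov)) fov[seq_along(dims_img)] / dims_img * 1000 else NULL
  structure(list(magnitude = mag, complexdata = imgs, fov = fov,
                 voxel_size = voxel), class = "mr_image")
}

#' @export
print.mr_image <- function(x, ...) {
  cat(sprintf("<mr_image> %s voxels%s\n",
              paste(dim(x$magnitude), collapse = " x "),
              if (!is.null(x$voxel_size))
                sprintf(", %s mm", paste(signif(x$voxel_size, 3), collapse = " x "))
              else ""))
  invisible(x)
}

#' NEMA-style SNR estimate from a magnitude image
#'
#' Mean of the signal region divided by the background noise standard
#' deviation corrected for the Rayleigh distribution of single-channel
#' magnitude noise: `SNR = mean(signal) / (sd(noise) / correction)` with the
#' conventional correction constant 0.66.
#'
#' @param image an `mr_image` or a numeric magnitude array.
#' @param signal_roi,noise_roi logical masks (or index vectors) into the
#'   magnitude array; must be disjoint and non-empty, the noise region in
#'   signal-free background.
#' @param correction Rayleigh correction constant.
#' @return SNR as a unitless scalar.
#' @export
snr_nema <- function(image, signal_roi, noise_roi, correction = 0.66) {
  mag <- if (inherits(image, "mr_image")) image$magnitude else image
  sig <- mag[signal_roi]
  noi <- mag[noise_roi]
  if (!length(sig) || !length(noi))
    stopf("signal and noise regions must be non-empty")
  if (is.logical(signal_roi) && is.logical(noise_roi) &&
      any(signal_roi & noise_roi))
    stopf("signal and noise regions must be disjoint")
  mean(sig) / (sd(noi) / correction)
}
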