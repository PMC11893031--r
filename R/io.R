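# Persistence: Pulseq + JSON metadata bundles, compiled-waveform bundles,
# and ISMRMRD-style raw data export.

params_to_list <- function(params) {
  lapply(unclass(params), function(v) as.numeric(v))
}

params_from_list <- function(lst) {
  do.call(acq_params, lapply(lst, function(v)
    if (length(v) > 1) as.numeric(v) else v))
}

#' Save a sequence, parameters and metadata as a bundle
#'
#' The sequence is stored as a Pulseq v1.4 file (`<path>.seq`) and all
#' acquisition parameters and free-form metadata in a joint JSON file
#' (`<path>.json`) that also records the parameter fingerprint, so a reload
#' can be validated against the parameter set it was saved with.
#'
#' @param seq a [seq_def()].
#' @param params an [acq_params()].
#' @param metadata named list of experiment metadata.
#' @param path output path stem (without extension).
#' @return `path`, invisibly.
#' @seealso [load_bundle()]
#' @export
save_bundle <- function(seq, params, metadata = list(), path) {
  stopifnot(inherits(seq, "seq_def"), inherits(params, "acq_params"))
  write_pulseq(seq, paste0(path, ".seq"))
  side <- list(
    format = "mrconsole-bundle",
    parameters = params_to_list(params),
    fingerprint = fingerprint(params),
    metadata = metadata
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a sequence/parameter bundle
#'
#' Reads `<path>.seq` and `<path>.json`, reconstructs the
#' [acq_params()] exactly and verifies the stored fingerprint; a tampered
#' sidecar is a validation error.
#'
#' @param path path stem used with [save_bundle()].
#' @return List with `seq`, `params`, `metadata`, `fingerprint`.
#' @export
load_bundle <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(side$format) || side$format != "mrconsole-bundle")
    stopf("%s.json is not an acquisition bundle sidecar", path)
  params <- params_from_list(side$parameters)
  if (!identical(fingerprint(params), side$fingerprint))
    stopf("bundle fingerprint mismatch: the JSON sidecar was modified or corrupted")
  list(seq = read_pulseq(paste0(path, ".seq")), params = params,
       metadata = side$metadata, fingerprint = side$fingerprint)
}

#' Write a compiled sequence to a waveform bundle
#'
#' Binary little-endian int16 frames (`<path>.bin`, interleaved channel
#' order RF, Gx, Gy, Gz) plus a JSON sidecar (`<path>.json`) with the sample
#' rate, digital bit map, gate list, block sample counts and parameter
#' fingerprint. The complex RF envelope is stored in the sidecar so virtual
#' backends reload losslessly.
#'
#' @param unrolled an `unrolled_seq`.
#' @param path output path stem.
#' @return `path`, invisibly.
#' @export
write_unrolled <- function(unrolled, path) {
  stopifnot(inherits(unrolled, "unrolled_seq"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(unlist(unrolled$frames, use.names = FALSE), con, size = 2L,
           endian = "little")
  side <- list(
    format = "mrconsole-unrolled",
    sample_rate = unrolled$sample_rate,
    total_samples = unrolled$total_samples,
    bit_map = as.list(unrolled$bit_map),
    gate_start = as.integer(unrolled$gates[, "start"]),
    gate_stop = as.integer(unrolled$gates[, "stop"]),
    block_samples = unrolled$block_samples,
    fingerprint = unrolled$fingerprint,
    full_scale = unrolled$full_scale,
    rf_envelope_re = Re(unrolled$rf_envelope),
    rf_envelope_im = Im(unrolled$rf_envelope)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a compiled waveform bundle
#'
#' @param path path stem used with [write_unrolled()].
#' @return An `unrolled_seq`.
#' @export
read_unrolled <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(side$format) || side$format != "mrconsole-unrolled")
    stopf("%s.json is not a waveform bundle sidecar", path)
  n16 <- 4L * side$total_samples
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  codes <- readBin(con, what = "integer", n = n16, size = 2L, signed = TRUE,
                   endian = "little")
  if (length(codes) != n16) stopf("waveform binary is truncated")
  block_samples <- as.integer(side$block_samples)
  frames <- split(codes, rep(seq_along(block_samples), 4L * block_samples))
  frames <- lapply(unname(frames), as.integer)
  gates <- cbind(start = as.integer(side$gate_start),
                 stop = as.integer(side$gate_stop))
  structure(list(
    frames = frames,
    bit_map = unlist(side$bit_map),
    sample_rate = side$sample_rate,
    total_samples = as.integer(side$total_samples),
    gates = gates,
    fingerprint = side$fingerprint,
    rf_envelope = complex(real = side$rf_envelope_re,
                          imaginary = side$rf_envelope_im),
    block_samples = block_samples,
    full_scale = side$full_scale
  ), class = "unrolled_seq")
}

#' Export acquisitions with an ISMRMRD-style header
#'
#' Writes a directory `path` holding `header.xml` — an ISMRMRD raw-data XML
#' header (experimental conditions, encoding spaces, receiver channel
#' count) — and `data.bin`, the complex samples as little-endian IEEE
#' doubles (real/imaginary interleaved, dimensions recorded in the header).
#' Doubles (rather than the standard's float32) keep the round trip
#' bit-exact. The complex samples and the encoding metadata survive a
#' round trip unchanged; see [import_ismrmrd_style()].
#'
#' @param kspace a `kspace_data` object or complex array
#'   `[averages, coils, encodings, readout]`.
#' @param params an [acq_params()].
#' @param path output directory (created; must not already contain data).
#' @param matrix_size optional integer length-3 encoded matrix size.
#' @param fov optional numeric length-3 field of view in m.
#' @return `path`, invisibly.
#' @export
export_ismrmrd_style <- function(kspace, params, path, matrix_size = NULL,
                                 fov = NULL) {
  K <- if (inherits(kspace, "kspace_data")) kspace$data else kspace
  if (length(dim(K)) != 4L)
    stopf("expected a [averages, coils, encodings, readout] array")
  d <- dim(K)
  if (is.null(matrix_size)) matrix_size <- c(d[4], d[3], 1L)
  if (is.null(fov)) fov <- c(0.24, 0.2, 0.21)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  doc <- xml2::xml_new_root("ismrmrdHeader")
  exp_c <- xml2::xml_add_child(doc, "experimentalConditions")
  xml2::xml_add_child(exp_c, "H1resonanceFrequency_Hz",
                      sprintf("%.17g", params$larmor_frequency))
  sysinfo <- xml2::xml_add_child(doc, "acquisitionSystemInformation")
  xml2::xml_add_child(sysinfo, "receiverChannels",
                      as.character(params$num_rx_channels))
  enc <- xml2::xml_add_child(doc, "encoding")
  for (space in c("encodedSpace", "reconSpace")) {
    sp <- xml2::xml_add_child(enc, space)
    ms <- xml2::xml_add_child(sp, "matrixSize")
    for (i in 1:3)
      xml2::xml_add_child(ms, c("x", "y", "z")[i], as.character(matrix_size[i]))
    fv <- xml2::xml_add_child(sp, "fieldOfView_mm")
    for (i in 1:3)
      xml2::xml_add_child(fv, c("x", "y", "z")[i], sprintf("%.17g", fov[i] * 1000))
  }
  xml2::xml_add_child(enc, "trajectory", "cartesian")
  user <- xml2::xml_add_child(doc, "userParameters")
  up <- xml2::xml_add_child(user, "userParameterString")
  xml2::xml_add_child(up, "name", "dataDimensions")
  xml2::xml_add_child(up, "value", paste(d, collapse = "x"))
  up2 <- xml2::xml_add_child(user, "userParameterDouble")
  xml2::xml_add_child(up2, "name", "receiveBandwidth_Hz")
  xml2::xml_add_child(up2, "value", sprintf("%.17g", params$receive_bandwidth))
  xml2::write_xml(doc, file.path(path, "header.xml"))

  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  v <- as.vector(K)
  writeBin(as.vector(rbind(Re(v), Im(v))), con, size = 8L, endian = "little")
  invisible(path)
}

#' Import an ISMRMRD-style export
#'
#' @param path directory written by [export_ismrmrd_style()].
#' @return List with `data` (complex array), `larmor_frequency`,
#'   `receive_bandwidth`, `matrix_size`, `fov` (m), `receiver_channels`.
#' @export
import_ismrmrd_style <- function(path) {
  hd <- xml2::read_xml(file.path(path, "header.xml"))
  if (xml2::xml_name(hd) != "ismrmrdHeader")
    stopf("%s/header.xml is not an ISMRMRD-style header", path)
  num <- function(xp) as.numeric(xml2::xml_text(xml2::xml_find_first(hd, xp)))
  dims <- as.integer(strsplit(xml2::xml_text(xml2::xml_find_first(
    hd, ".//userParameterString[name='dataDimensions']/value")), "x")[[1]])
  n <- prod(dims)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = 2L * n, size = 8L, endian = "little")
  if (length(raw) != 2L * n) stopf("data.bin is truncated")
  data <- array(complex(real = raw[c(TRUE, FALSE)],
                        imaginary = raw[c(FALSE, TRUE)]), dim = dims)
  ms <- vapply(c("x", "y", "z"), function(ax)
    num(sprintf(".//encoding/encodedSpace/matrixSize/%s", ax)), numeric(1))
  fv <- vapply(c("x", "y", "z"), function(ax)
    num(sprintf(".//encoding/encodedSpace/fieldOfView_mm/%s", ax)), numeric(1))
  list(data = data,
       larmor_frequency = num(".//experimentalConditions/H1resonanceFrequency_Hz"),
       receive_bandwidth = num(".//userParameterDouble[name='receiveBandwidth_Hz']/value"),
       matrix_size = as.integer(ms), fov = unname(fv) / 1000,
       receiver_channels = as.integer(num(".//acquisitionSystemInformation/receiverChannels")))
}
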