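# Pulseq v1.4 text format I/O.
#
# The writer emits uncompressed shapes; the reader additionally understands
# the compressed (derivative run-length) shape encoding so externally
# generated files load as well. Gradients are kHz/m in memory and Hz/m on
# file, per the Pulseq convention.

fmt_num <- function(x) sprintf("%.9g", x)

#' Write a sequence to a Pulseq v1.4 file
#'
#' @param seq a [seq_def()] object.
#' @param path output file path (conventionally `.seq`).
#' @return `path`, invisibly.
#' @seealso [read_pulseq()]
#' @export
write_pulseq <- function(seq, path) {
  stopifnot(inherits(seq, "seq_def"))
  defs <- seq$definitions
  rf_raster <- defs$RadiofrequencyRasterTime
  blk_raster <- defs$BlockDurationRaster

  shapes <- list()        # id -> numeric vector
  shape_sig <- character()
  get_shape_id <- function(v) {
    sig <- paste(sprintf("%.9g", v), collapse = ",")
    hit <- match(sig, shape_sig)
    if (!is.na(hit)) return(hit)
    shapes[[length(shapes) + 1L]] <<- v
    shape_sig[length(shapes)] <<- sig
    length(shapes)
  }

  rf_rows <- character(); rf_sig <- character()
  trap_rows <- character(); grad_rows <- character(); g_sig <- character()
  adc_rows <- character(); adc_sig <- character()

  get_rf_id <- function(rf) {
    if (is.null(rf$envelope)) {
      n <- max(1L, as.integer(round(rf$duration / rf_raster)))
      mag <- rep(1, n); phase <- rep(0, n); amp <- rf$amplitude
    } else {
      amp <- max(Mod(rf$envelope))
      if (amp == 0) amp <- 1
      mag <- Mod(rf$envelope) / amp
      phase <- (Arg(rf$envelope) / (2 * pi)) %% 1
    }
    mag_id <- get_shape_id(mag)
    phase_id <- get_shape_id(phase)
    row <- sprintf("%s %d %d 0 %.0f %s %s", fmt_num(amp), mag_id, phase_id,
                   round(rf$delay * 1e6), fmt_num(rf$freq_offset),
                   fmt_num(rf$phase_offset))
    hit <- match(row, rf_sig)
    if (!is.na(hit)) return(hit)
    rf_sig[length(rf_sig) + 1L] <<- row
    rf_rows[length(rf_rows) + 1L] <<- sprintf("%d %s", length(rf_sig), row)
    length(rf_sig)
  }

  get_grad_id <- function(g) {
    if (g$type == "trap") {
      row <- sprintf("%s %.0f %.0f %.0f %.0f", fmt_num(g$amplitude * 1e3),
                     round(g$rise * 1e6), round(g$flat * 1e6),
                     round(g$fall * 1e6), round(g$delay * 1e6))
      sig <- paste0("T", row)
    } else {
      amp <- max(abs(g$samples))
      if (amp == 0) amp <- 1
      sid <- get_shape_id(g$samples / amp)
      row <- sprintf("%s %d 0 %.0f", fmt_num(amp * 1e3), sid,
                     round(g$delay * 1e6))
      sig <- paste0("G", row)
    }
    hit <- match(sig, g_sig)
    if (!is.na(hit)) return(hit)
    g_sig[length(g_sig) + 1L] <<- sig
    id <- length(g_sig)
    if (g$type == "trap") trap_rows[length(trap_rows) + 1L] <<- sprintf("%d %s", id, row)
    else grad_rows[length(grad_rows) + 1L] <<- sprintf("%d %s", id, row)
    id
  }

  get_adc_id <- function(a) {
    row <- sprintf("%d %s %.0f 0 0", a$num, fmt_num(a$dwell * 1e9),
                   round(a$delay * 1e6))
    hit <- match(row, adc_sig)
    if (!is.na(hit)) return(hit)
    adc_sig[length(adc_sig) + 1L] <<- row
    adc_rows[length(adc_rows) + 1L] <<- sprintf("%d %s", length(adc_sig), row)
    length(adc_sig)
  }

  blk_rows <- vapply(seq_along(seq$blocks), function(i) {
    b <- seq$blocks[[i]]
    rf_id <- if (is.null(b$rf)) 0L else get_rf_id(b$rf)
    g_ids <- vapply(b$grad, function(g) if (is.null(g)) 0L else get_grad_id(g),
                    integer(1))
    adc_id <- if (is.null(b$adc)) 0L else get_adc_id(b$adc)
    dur <- round(b$duration / blk_raster)
    if (abs(b$duration / blk_raster - dur) > 1e-6)
      stopf("block %d duration %.9g s is not a multiple of the block raster %.3g s",
            i, b$duration, blk_raster)
    sprintf("%d %d %d %d %d %d %d 0", i, dur, rf_id, g_ids[1], g_ids[2],
            g_ids[3], adc_id)
  }, character(1))

  lines <- c(
    "# Pulseq sequence file",
    "# Created by mrconsole",
    "", "[VERSION]", "major 1", "minor 4", "revision 0",
    "", "[DEFINITIONS]",
    sprintf("AdcRasterTime %s", fmt_num(defs$AdcRasterTime)),
    sprintf("BlockDurationRaster %s", fmt_num(blk_raster)),
    sprintf("GradientRasterTime %s", fmt_num(defs$GradientRasterTime)),
    sprintf("RadiofrequencyRasterTime %s", fmt_num(rf_raster)),
    sprintf("TotalDuration %s", fmt_num(sequence_duration(seq))),
    "", "[BLOCKS]",
    "# NUM DUR RF GX GY GZ ADC EXT",
    blk_rows)
  if (length(rf_rows))
    lines <- c(lines, "", "[RF]",
               "# id amplitude mag_id phase_id time_id delay freq phase", rf_rows)
  if (length(grad_rows))
    lines <- c(lines, "", "[GRADIENTS]",
               "# id amplitude shape_id time_id delay", grad_rows)
  if (length(trap_rows))
    lines <- c(lines, "", "[TRAP]",
               "# id amplitude rise flat fall delay", trap_rows)
  if (length(adc_rows))
    lines <- c(lines, "", "[ADC]",
               "# id num dwell delay freq phase", adc_rows)
  if (length(shapes)) {
    shp <- unlist(lapply(seq_along(shapes), function(i) c(
      "", sprintf("shape_id %d", i),
      sprintf("num_samples %d", length(shapes[[i]])),
      fmt_num(shapes[[i]]))))
    lines <- c(lines, "", "[SHAPES]", shp)
  }
  writeLines(lines, path)
  invisible(path)
}

# Decompress a Pulseq shape: values are first-derivative samples with
# run-length encoding (two equal consecutive values are followed by the
# number of additional repeats).
decompress_shape <- function(vals, num_samples) {
  deriv <- numeric(num_samples)
  n <- 0L; i <- 1L
  while (i <= length(vals)) {
    if (i < length(vals) && vals[i + 1L] == vals[i]) {
      if (i + 2L > length(vals)) stopf("malformed compressed shape")
      rep_n <- vals[i + 2L] + 2
      deriv[n + seq_len(rep_n)] <- vals[i]
      n <- n + rep_n
      i <- i + 3L
    } else {
      n <- n + 1L
      deriv[n] <- vals[i]
      i <- i + 1L
    }
  }
  if (n != num_samples)
    stopf("compressed shape expands to %d samples, declared %d", n, num_samples)
  cumsum(deriv)
}

split_sections <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  idx <- grep("^\\[.*\\]$", lines)
  if (!length(idx)) stopf("not a Pulseq file: no sections found")
  out <- list()
  for (k in seq_along(idx)) {
    name <- toupper(gsub("\\[|\\]", "", lines[idx[k]]))
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(lines)
    body <- if (idx[k] + 1L <= to) lines[(idx[k] + 1L):to] else character()
    out[[name]] <- body
  }
  out
}

parse_table <- function(body) {
  if (!length(body)) return(NULL)
  do.call(rbind, lapply(body, function(l) as.numeric(strsplit(l, "\\s+")[[1]])))
}

#' Load a Pulseq v1.4 sequence file
#'
#' Parses the text format and materializes every block with its events
#' resolved against the shape and event tables. Raster times are taken from
#' the `[DEFINITIONS]` section. Extension blocks are not supported and raise
#' a parse error naming the offending block.
#'
#' @param path path to a `.seq` file.
#' @return A [seq_def()] object.
#' @export
read_pulseq <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sec <- split_sections(readLines(path, warn = FALSE))
  if (is.null(sec$BLOCKS)) stopf("malformed Pulseq file: missing [BLOCKS] section")

  defs <- list()
  for (l in sec$DEFINITIONS %||% character()) {
    kv <- strsplit(l, "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(kv[-1]))
    defs[[kv[1]]] <- if (any(is.na(val))) paste(kv[-1], collapse = " ") else val
  }
  rf_raster <- defs$RadiofrequencyRasterTime %||% 1e-6
  blk_raster <- defs$BlockDurationRaster %||% 1e-5
  grad_raster <- defs$GradientRasterTime %||% 1e-5

  # shapes
  shapes <- list()
  body <- sec$SHAPES %||% character()
  i <- 1L
  while (i <= length(body)) {
    m <- regmatches(body[i], regexec("^shape_id\\s+(\\d+)$", body[i]))[[1]]
    if (length(m) != 2) stopf("malformed [SHAPES] section near '%s'", body[i])
    id <- as.integer(m[2])
    mn <- regmatches(body[i + 1L], regexec("^num_samples\\s+(\\d+)$", body[i + 1L]))[[1]]
    if (length(mn) != 2) stopf("shape %d: missing num_samples", id)
    num <- as.integer(mn[2])
    j <- i + 2L
    vals <- numeric(0)
    while (j <= length(body) && !grepl("^shape_id", body[j])) {
      vals <- c(vals, as.numeric(strsplit(body[j], "\\s+")[[1]]))
      j <- j + 1L
    }
    shapes[[id]] <- if (length(vals) == num) vals else decompress_shape(vals, num)
    i <- j
  }

  rf_tab <- parse_table(sec$RF)
  trap_tab <- parse_table(sec$TRAP)
  grad_tab <- parse_table(sec$GRADIENTS)
  adc_tab <- parse_table(sec$ADC)
  blk_tab <- parse_table(sec$BLOCKS)
  if (is.null(blk_tab) || ncol(blk_tab) < 7)
    stopf("malformed [BLOCKS] section")

  lookup <- function(tab, id, what, block) {
    if (id == 0) return(NULL)
    row <- which(tab[, 1] == id)
    if (is.null(tab) || !length(row))
      stopf("block %d references unknown %s event %d", block, what, id)
    tab[row[1], ]
  }

  blocks <- vector("list", nrow(blk_tab))
  for (k in seq_len(nrow(blk_tab))) {
    r <- blk_tab[k, ]
    if (length(r) >= 8 && r[8] != 0)
      stopf("block %d uses an unsupported extension block", k)
    dur <- r[2] * blk_raster

    rf <- NULL
    if (r[3] != 0) {
      rr <- lookup(rf_tab, r[3], "RF", k)
      mag <- shapes[[rr[3]]]
      if (is.null(mag)) stopf("block %d: RF references unknown shape %d", k, rr[3])
      phase <- if (rr[4] != 0) shapes[[rr[4]]] else rep(0, length(mag))
      if (length(rr) >= 5 && rr[5] != 0)
        stopf("block %d: RF time shapes are not supported", k)
      env <- rr[2] * mag * exp(2i * pi * phase)
      rf <- rf_event(amplitude = rr[2], delay = rr[6] * 1e-6,
                     freq_offset = rr[7], phase_offset = rr[8],
                     envelope = env, raster = rf_raster, duration = NULL)
    }

    mk_grad <- function(id) {
      if (id == 0) return(NULL)
      if (!is.null(trap_tab) && any(trap_tab[, 1] == id)) {
        tr <- trap_tab[which(trap_tab[, 1] == id)[1], ]
        trap_event(amplitude = tr[2] / 1e3, rise = tr[3] * 1e-6,
                   flat = tr[4] * 1e-6, fall = tr[5] * 1e-6,
                   delay = tr[6] * 1e-6)
      } else if (!is.null(grad_tab) && any(grad_tab[, 1] == id)) {
        gr <- grad_tab[which(grad_tab[, 1] == id)[1], ]
        shp <- shapes[[gr[3]]]
        if (is.null(shp)) stopf("block %d: gradient references unknown shape %d", k, gr[3])
        arb_event(samples = gr[2] / 1e3 * shp, raster = grad_raster,
                  delay = gr[5] * 1e-6)
      } else stopf("block %d references unknown gradient event %d", k, id)
    }

    adc <- NULL
    if (r[7] != 0) {
      ar <- lookup(adc_tab, r[7], "ADC", k)
      adc <- adc_event(num = ar[2], dwell = ar[3] * 1e-9, delay = ar[4] * 1e-6)
    }

    blocks[[k]] <- seq_block(dur, rf = rf, gx = mk_grad(r[4]),
                             gy = mk_grad(r[5]), gz = mk_grad(r[6]), adc = adc)
  }
  seq_def(blocks = blocks, definitions = defs)
}

#' Load a sequence file (alias)
#'
#' @inheritParams read_pulseq
#' @return A [seq_def()] object.
#' @export
load_sequence <- function(path) read_pulseq(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
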