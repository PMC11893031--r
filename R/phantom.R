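#' Construct an isochromat phantom
#'
#' Deterministic (grid-based) isochromat ensembles for the virtual scanner.
#' `"point"` places a single isochromat at the origin; `"sphere"` fills a
#' sphere of diameter `extent` with a regular grid of about `n_spins`
#' isochromats of unit magnitude; `"shepp2d"` samples the classic
#' Shepp-Logan head phantom (10 superposed ellipses) on a grid in the z = 0
#' plane, scaled to width `extent`, keeping points of positive intensity.
#'
#' @param kind `"point"`, `"sphere"` or `"shepp2d"`.
#' @param n_spins target number of isochromats (exact placement is grid
#'   based, so the realized count can differ slightly).
#' @param extent object diameter / width in m.
#' @param t2 transverse relaxation time in s (scalar, applied to all spins).
#' @param t1 longitudinal relaxation time in s; governs recovery between
#'   excitations in multi-shot sequences. Low-field tissue values are a few
#'   hundred milliseconds.
#' @param off_resonance off-resonance in Hz; scalar, or one value per spin.
#' @return An object of class `phantom` with fields `pos` (n x 3 matrix, m),
#'   `magnitude`, `t2`, `t1` and `off_resonance` (length-n vectors).
#' @examples
#' ph <- make_phantom("sphere", n_spins = 500, extent = 0.07)
#' nrow(ph$pos)
#' @export
make_phantom <- function(kind = c("point", "sphere", "shepp2d"),
                         n_spins = 1000, extent = 0.07, t2 = 0.1, t1 = 0.3,
                         off_resonance = 0) {
  kind <- match.arg(kind)
  stopifnot(n_spins >= 1, extent > 0, t2 > 0, t1 > 0)
  if (kind == "point") {
    pos <- matrix(0, 1, 3)
    mag <- 1
  } else if (kind == "sphere") {
    n_side <- max(1L, round((n_spins * 6 / pi)^(1 / 3)))
    g <- (seq_len(n_side) - (n_side + 1) / 2) / n_side * extent
    pos <- as.matrix(expand.grid(x = g, y = g, z = g))
    keep <- rowSums(pos^2) <= (extent / 2)^2 + 1e-12
    pos <- pos[keep, , drop = FALSE]
    mag <- rep(1, nrow(pos))
  } else {
    n_side <- max(2L, ceiling(sqrt(n_spins / 0.55)))
    g <- (seq_len(n_side) - (n_side + 1) / 2) / n_side * extent
    gr <- expand.grid(x = g, y = g)
    val <- shepp_logan_intensity(gr$x / (extent / 2), gr$y / (extent / 2))
    keep <- val > 0
    pos <- cbind(gr$x[keep], gr$y[keep], 0)
    mag <- val[keep]
  }
  n <- nrow(pos)
  structure(list(
    pos = unname(as.matrix(pos)),
    magnitude = mag,
    t2 = rep_len(t2, n),
    t1 = rep_len(t1, n),
    off_resonance = rep_len(off_resonance, n),
    kind = kind
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %d isochromats, T2 %.3g s\n",
              x$kind, nrow(x$pos), x$t2[1]))
  invisible(x)
}

# Shepp-Logan ellipse table: intensity, semi-axes a/b, centre x0/y0, angle.
shepp_logan_intensity <- function(x, y) {
  tab <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.01, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.01, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.01, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.01, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.01, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.01, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE)
  val <- numeric(length(x))
  for (r in seq_len(nrow(tab))) {
    phi <- tab[r, 6] * pi / 180
    xr <- (x - tab[r, 4]) * cos(phi) + (y - tab[r, 5]) * sin(phi)
    yr <- -(x - tab[r, 4]) * sin(phi) + (y - tab[r, 5]) * cos(phi)
    inside <- (xr / tab[r, 2])^2 + (yr / tab[r, 3])^2 <= 1
    val[inside] <- val[inside] + tab[r, 1]
  }
  val
}
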