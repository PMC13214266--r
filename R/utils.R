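# Low-level image helpers shared across the preprocessing and simulation
# stages. Convolution is FFT-based with reflective padding so that hotspots
# near the field edge are not wrapped around.

.padReflect <- function(img, pr, pc) {
  nr <- nrow(img); nc <- ncol(img)
  if (pr >= nr || pc >= nc)
    stop("padding exceeds image size")
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  if (pr == 0L) ri <- seq_len(nr)
  if (pc == 0L) ci <- seq_len(nc)
  img[ri, ci, drop = FALSE]
}

.circShift <- function(m, s1, s2) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1L - s1) %% n1) + 1L
  j <- ((seq_len(n2) - 1L - s2) %% n2) + 1L
  m[i, j, drop = FALSE]
}

# 2-D convolution, reflective boundary, kernel center at
# ((kr+1)%/%2, (kc+1)%/%2). Exact for delta kernels.
.convolve2d <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- kr %/% 2L; pc <- kc %/% 2L
  padded <- .padReflect(img, pr, pc)
  big <- matrix(0, nrow(padded), ncol(padded))
  big[seq_len(kr), seq_len(kc)] <- kernel
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  big <- .circShift(big, -(cr - 1L), -(cc - 1L))
  out <- Re(stats::fft(stats::fft(padded) * stats::fft(big), inverse = TRUE)) /
    length(big)
  out[(pr + 1L):(pr + nrow(img)), (pc + 1L):(pc + ncol(img)), drop = FALSE]
}

# Bilinear sub-pixel shift with replicated edges: output(i, j) samples the
# input at (i - dy, j - dx), i.e. content moves by (+dy, +dx).
.shiftImage <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  yi <- pmin(pmax(seq_len(nr) - dy, 1), nr)
  xi <- pmin(pmax(seq_len(nc) - dx, 1), nc)
  y0 <- pmin(floor(yi), nr - 1L); x0 <- pmin(floor(xi), nc - 1L)
  wy <- yi - y0; wx <- xi - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0 + 1L, x0, drop = FALSE]
  c_ <- img[y0, x0 + 1L, drop = FALSE]; d <- img[y0 + 1L, x0 + 1L, drop = FALSE]
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * WY * (1 - WX) + c_ * (1 - WY) * WX +
    d * WY * WX
}

#' Build a normalized isotropic 2-D Gaussian point spread function
#'
#' @param sigma Gaussian SD in micrometers.
#' @param pixelSize micrometers per pixel.
#' @param radiusPx half-width of the kernel in pixels; defaults to
#'   \code{ceiling(4 * sigma / pixelSize)}.
#' @return Square matrix summing to 1; a single 1 when \code{sigma = 0}.
#' @examples
#' psf <- gaussianPSF(0.25, 0.1625)
#' sum(psf)
#' @export
gaussianPSF <- function(sigma, pixelSize, radiusPx = NULL) {
  stopifnot(sigma >= 0, pixelSize > 0)
  if (sigma == 0) return(matrix(1, 1, 1))
  sPx <- sigma / pixelSize
  if (is.null(radiusPx)) radiusPx <- max(1L, ceiling(4 * sPx))
  ax <- (-radiusPx):radiusPx
  g <- exp(-ax^2 / (2 * sPx^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian temporal / spatial smoothing kernel (1-D), unit sum.
.gauss1d <- function(sigma, radius = ceiling(3 * sigma)) {
  ax <- (-radius):radius
  g <- exp(-ax^2 / (2 * sigma^2))
  g / sum(g)
}

.asStack <- function(x) {
  if (is(x, "FluorescenceMovie")) movieData(x) else x
}

# Deterministic per-task seed derived from a base seed; stays well below
# 2^31 for R's 32-bit integers.
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483587)
}
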