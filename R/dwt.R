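# 312-D discrete-wavelet-transform block. Each of the six physicochemical
# tracks of the PC matrix is decomposed by a 4-level DWT cascade; each level
# contributes the (max, min, mean, population sd) of its detail band, the
# same four statistics of its approximation band, and the first five
# approximation coefficients (zero-padded when the band is shorter), i.e.
# 13 values per level, 52 per track, 312 in total.
#
# The single-level transform uses symmetric boundary extension (the signal
# is reflected by filterLength - 1 samples on both sides) followed by
# convolution with the orthonormal decomposition filters and dyadic
# downsampling; the output length is floor((n + filterLength - 1) / 2).

.WAVELETS <- list(
  haar = list(
    lo = c(0.7071067811865476, 0.7071067811865476),
    hi = c(-0.7071067811865476, 0.7071067811865476)
  ),
  # Daubechies 4-tap-pair (8 coefficients) orthonormal filters
  db4 = list(
    lo = c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
           -0.02798376941698385,  0.6308807679295904,
            0.7148465705525415,   0.23037781330885523),
    hi = c(-0.23037781330885523,  0.7148465705525415,
           -0.6308807679295904,  -0.02798376941698385,
            0.18703481171888114,  0.030841381835986965,
           -0.032883011666982945, -0.010597401784997278)
  )
)

# one analysis step: symmetric extension, convolve, downsample
.dwtStep <- function(x, wavelet = "haar") {
  filt <- .WAVELETS[[wavelet]]
  if (is.null(filt)) stop("unknown wavelet '", wavelet,
                          "'; available: ", paste(names(.WAVELETS),
                                                  collapse = ", "))
  n <- length(x)
  L <- length(filt$lo)
  pad <- L - 1L
  idx <- c(rev(seq_len(min(pad, n))),
           seq_len(n),
           n + 1L - seq_len(min(pad, n)))
  # whole-sample reflection may be shorter than pad for tiny signals;
  # repeat edges until long enough
  while (length(idx) < n + 2L * pad)
    idx <- c(idx[1], idx, idx[length(idx)])
  ext <- x[idx]
  outLen <- (n + L - 1L) %/% 2L
  take <- seq(L + 1L, by = 2L, length.out = outLen)
  conv <- function(f) {
    full <- stats::convolve(ext, rev(f), type = "open")
    full[take]
  }
  list(approx = conv(filt$lo), detail = conv(filt$hi))
}

.bandStats <- function(b) c(max = max(b), min = min(b),
                            mean = mean(b), sd = .popSd(b))

.DWT_SLOTS <- c("d_max", "d_min", "d_mean", "d_sd",
                "a_max", "a_min", "a_mean", "a_sd",
                paste0("a", 1:5))

#' Per-level wavelet band features of a signal
#'
#' Runs the analysis cascade: level t splits the level t-1 approximation
#' (level 0 = the input) into a detail (high-frequency) and an approximation
#' (low-frequency) band. Each level yields 13 features: the four band
#' statistics of the detail band, the same of the approximation band, and
#' the first 5 approximation coefficients (zero-padded on the right when
#' the band has fewer than 5).
#'
#' @param signal numeric vector, length >= 1.
#' @param levels number of decomposition levels (default 4). Short signals
#'   are handled by boundary extension; no minimum dyadic length is imposed.
#' @param wavelet \code{"haar"} (default) or \code{"db4"}.
#' @return numeric matrix, \code{levels} rows x 13 named columns
#'   (\code{d_max..d_sd}, \code{a_max..a_sd}, \code{a1..a5}).
#' @examples
#' dwtColumnFeatures(rep(1, 40))["1", 1:4]   # constant input: zero details
#' @export
dwtColumnFeatures <- function(signal, levels = 4L, wavelet = "haar") {
  if (length(signal) < 1L) stop("signal must be non-empty")
  if (!all(is.finite(signal))) stop("signal must be finite")
  out <- matrix(NA_real_, nrow = levels, ncol = 13L,
                dimnames = list(seq_len(levels), .DWT_SLOTS))
  approx <- as.numeric(signal)
  for (t in seq_len(levels)) {
    step <- .dwtStep(approx, wavelet)
    head5 <- step$approx[1:5]
    head5[is.na(head5)] <- 0
    out[t, ] <- c(.bandStats(step$detail), .bandStats(step$approx), head5)
    approx <- step$approx
  }
  out
}

#' DWT features of a physicochemical property matrix
#'
#' Applies [dwtColumnFeatures()] to each of the six property tracks of a PC
#' matrix (Twist ... Rise, in that fixed order) and concatenates, level
#' 1 to 4 within each track: 6 x 4 x 13 = 312 features.
#'
#' @param pc property matrix from [pcMatrix()].
#' @param levels,wavelet passed to [dwtColumnFeatures()].
#' @return named numeric vector of length \code{6 * levels * 13}
#'   (312 at the default 4 levels), names \code{dwt.<prop>.L<t>.<slot>}.
#' @export
dwtFeatures <- function(pc, levels = 4L, wavelet = "haar") {
  stopifnot(is.matrix(pc), ncol(pc) == 6L)
  props <- colnames(pc)
  if (is.null(props)) props <- PROPERTY_NAMES
  out <- numeric(0)
  for (p in seq_len(6L)) {
    m <- dwtColumnFeatures(pc[, p], levels = levels, wavelet = wavelet)
    v <- as.vector(t(m))
    names(v) <- paste("dwt", props[p],
                      paste0("L", rep(seq_len(levels), each = 13L)),
                      rep(.DWT_SLOTS, levels), sep = ".")
    out <- c(out, v)
  }
  out
}
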