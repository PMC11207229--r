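# Compact Canny edge detector: gaussian smoothing, Sobel gradients,
# non-maximum suppression along the quantized gradient direction, and
# two-threshold hysteresis. Thresholds are given as quantiles of the nonzero
# gradient magnitude so they adapt to the local contrast of the patch.

conv3_rep <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w == 0) next
    rs <- pmin(pmax(seq_len(H) + dr, 1L), H)
    cs <- pmin(pmax(seq_len(W) + dc, 1L), W)
    out <- out + w * m[rs, cs]
  }
  out
}

#' Canny edge detection on a grayscale image patch
#'
#' @param img numeric matrix (intensities on any scale).
#' @param sigma gaussian smoothing in pixels.
#' @param low_q,high_q hysteresis thresholds as quantiles of the nonzero
#'   gradient magnitude.
#' @return binary matrix of edge pixels.
#' @export
canny <- function(img, sigma = 1.0, low_q = 0.5, high_q = 0.9) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_config("img must be a numeric matrix")
  sm <- gauss_blur(img, sigma)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)          # d/dx (columns)
  ky <- t(kx)                                                   # d/dy (rows)
  gx <- conv3_rep(sm, kx); gy <- conv3_rep(sm, ky)
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(matrix(0, nrow(img), ncol(img)))

  # quantize gradient direction to 4 bins and suppress non-maxima
  ang <- atan2(gy, gx) %% pi
  bin <- (round(ang / (pi / 4)) %% 4) + 1L
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))      # bins 1..4
  keep <- matrix(FALSE, nrow(img), ncol(img))
  for (b in 1:4) {
    n1 <- shift_mat(mag, off[[b]][1], off[[b]][2], fill = 0)
    n2 <- shift_mat(mag, -off[[b]][1], -off[[b]][2], fill = 0)
    keep <- keep | (bin == b & mag >= n1 & mag >= n2)
  }
  nms <- mag * keep

  pos <- nms[nms > 0]
  if (length(pos) == 0) return(matrix(0, nrow(img), ncol(img)))
  lo <- stats::quantile(pos, low_q, names = FALSE)
  hi <- stats::quantile(pos, high_q, names = FALSE)
  strong <- nms >= hi
  weak <- nms >= lo
  repeat {
    grown <- dilate8(strong) & weak
    if (all(grown == strong)) break
    strong <- grown
  }
  strong * 1
}
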