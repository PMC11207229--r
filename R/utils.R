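# internal helpers shared across modules

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !(is.numeric(mask) || is.logical(mask)))
    stop_config("%s must be a numeric or logical matrix", arg)
  m <- mask
  storage.mode(m) <- "double"
  if (!all(m %in% c(0, 1)))
    stop_config("%s must be binary (values 0/1)", arg)
  m
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop_config("%s must have identical dimensions (%s vs %s)", what,
                paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# 8-neighbour binary dilation (logical matrix in/out)
dilate8 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mat(m, dr, dc, fill = FALSE)
  }
  out
}

# separable gaussian blur with replicate padding; sigma in pixels
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1d <- function(m) { # along rows (dim 1)
    H <- nrow(m)
    idx <- outer(seq_len(H), -r:r, "+")
    idx[idx < 1] <- 1L; idx[idx > H] <- H
    out <- matrix(0, H, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(img))))
}
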