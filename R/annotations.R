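#' Indices of sparsely annotated slices
#'
#' Sparse annotation labels every `(s_int + 1)`-th slice of a stack, starting
#' from the first slice: with an interval of `s_int` unannotated slices between
#' consecutive annotated ones, a 160-slice case at `s_int = 3` yields 40
#' annotated slices.
#'
#' @param n_slices number of slices in the stack.
#' @param s_int nonnegative integer, number of unannotated slices between
#'   consecutive annotated slices (`0` = dense annotation).
#' @return increasing integer vector of 1-based slice indices.
#' @examples
#' select_sparse_slices(10, 3)  # 1 5 9
#' @export
select_sparse_slices <- function(n_slices, s_int) {
  if (n_slices < 1) stop_config("n_slices must be >= 1")
  if (s_int < 0) stop_config("s_int must be nonnegative")
  as.integer(seq.int(1L, n_slices, by = as.integer(s_int) + 1L))
}

#' Edge label of a segmentation mask
#'
#' A pixel is an edge pixel iff it is foreground and at least one of its 8
#' neighbours is background; neighbours outside the image count as background,
#' so a region touching the image border has an edge there. Background pixels
#' are never edge pixels, hence the edge set is a subset of the mask.
#'
#' @param mask binary matrix.
#' @return binary matrix of the same size.
#' @examples
#' edge_from_mask(matrix(1, 5, 5))  # 1-pixel border ring
#' @export
edge_from_mask <- function(mask) {
  m <- check_binary_mask(mask)
  interior <- matrix(TRUE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    interior <- interior & shift_mat(m, dr, dc, fill = 0) == 1
  }
  (m == 1 & !interior) * 1
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined to agree
#' perfectly (`1`), which keeps the score meaningful on slices without tissue.
#'
#' @param a,b binary matrices of identical size.
#' @return a number in `[0, 1]`.
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' dice(a, a)  # 1
#' @export
dice <- function(a, b) {
  a <- check_binary_mask(a, "a"); b <- check_binary_mask(b, "b")
  check_same_shape(a, b, "masks")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}
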