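LOG_EPS <- 1e-7    # probability clip before any logarithm
DICE_EPS <- 1e-6   # soft-dice smoothing

clip01 <- function(p) pmin(pmax(p, LOG_EPS), 1 - LOG_EPS)

#' Area (segmentation) loss: binary cross-entropy plus soft Dice
#'
#' `mean BCE + 1 - (2 sum(G*Q) + eps) / (sum(G) + sum(Q) + eps)`. The
#' cross-entropy is the standard negated log-likelihood, averaged over pixels
#' (summed forms only rescale gradients); predictions are clipped away from 0/1
#' before the logarithm. The symmetric eps smoothing makes the Dice term 0 when
#' both label and prediction are empty. The same function serves true sparse
#' labels and pseudo-labels.
#'
#' @param label binary matrix G (or pseudo-label P).
#' @param pred_seg probability matrix Q (or T) in `[0,1]`.
#' @return nonnegative scalar loss.
#' @export
area_loss <- function(label, pred_seg) {
  g <- check_binary_mask(label, "label")
  check_same_shape(g, pred_seg, "label/prediction")
  q <- clip01(pred_seg)
  bce <- -mean(g * log(q) + (1 - g) * log(1 - q))
  dice_term <- 1 - (2 * sum(g * pred_seg) + DICE_EPS) /
    (sum(g) + sum(pred_seg) + DICE_EPS)
  bce + dice_term
}

#' Edge loss: weighted binary cross-entropy
#'
#' The edge-positive term is weighted by `w0 = sum(E)/(W*H)` (the fraction of
#' edge pixels) and the background term by `w1 = 1 - w0`, then averaged over
#' pixels. Note this assigns the small weight to the rare positive class;
#' `swap_weights = TRUE` exchanges `w0`/`w1` for conventional class balancing.
#' The same form serves pseudo-edge labels.
#'
#' @param edge_label binary matrix E (or pseudo-edge F).
#' @param pred_edge probability matrix S (or C) in `[0,1]`.
#' @param swap_weights exchange the two class weights.
#' @return nonnegative scalar loss.
#' @export
weighted_edge_loss <- function(edge_label, pred_edge, swap_weights = FALSE) {
  e <- check_binary_mask(edge_label, "edge_label")
  check_same_shape(e, pred_edge, "edge label/prediction")
  s <- clip01(pred_edge)
  w0 <- sum(e) / length(e)
  w1 <- 1 - w0
  if (swap_weights) { tmp <- w0; w0 <- w1; w1 <- tmp }
  -sum(w0 * e * log(s) + w1 * (1 - e) * log(1 - s)) / length(e)
}

#' Joint-training schedule state
#'
#' @param e_thres positive integer: round at which supervision becomes purely
#'   the true sparse labels.
#' @param e_total total number of training rounds.
#' @param e_cur current round (0-based; round 0 is fully pseudo-supervised).
#' @return object of class `joint_schedule`.
#' @export
joint_schedule <- function(e_thres, e_total = e_thres, e_cur = 0L) {
  if (e_thres < 1) stop_config("e_thres must be >= 1")
  if (e_cur < 0) stop_config("e_cur must be nonnegative")
  structure(list(e_thres = e_thres, e_total = e_total, e_cur = e_cur),
            class = "joint_schedule")
}

#' Pseudo-/true-label weights of the joint loss
#'
#' `alpha = max((e_thres - e_cur)/e_thres, 0)` weights the pseudo-label loss,
#' `beta = min(e_cur/e_thres, 1)` the true sparse-label loss; they sum to 1
#' while `e_cur <= e_thres`, after which supervision is purely true labels.
#'
#' @param s a [joint_schedule()] (or list with `e_thres`, `e_cur`).
#' @return named numeric `c(alpha = , beta = )`.
#' @export
schedule_weights <- function(s) {
  if (s$e_cur < 0) stop_config("e_cur must be nonnegative")
  c(alpha = max((s$e_thres - s$e_cur) / s$e_thres, 0),
    beta = min(s$e_cur / s$e_thres, 1))
}

#' Joint loss combining pseudo- and true-label supervision
#'
#' `alpha * (loss_pl + lp_edge) + beta * (l_area + l_edge)` with the weights
#' from [schedule_weights()].
#'
#' @param loss_pl pseudo-segmentation-label loss.
#' @param lp_edge pseudo-edge-label loss.
#' @param l_area true sparse-label area loss.
#' @param l_edge true edge-label loss.
#' @param s a [joint_schedule()].
#' @return scalar loss.
#' @export
joint_loss <- function(loss_pl, lp_edge, l_area, l_edge, s) {
  w <- schedule_weights(s)
  unname(w["alpha"] * (loss_pl + lp_edge) + w["beta"] * (l_area + l_edge))
}
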