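#' Adjacent-slice agreement scores for one case
#'
#' For an ordered stack of per-slice masks, the score of an interior slice is
#' the mean of its Dice overlap with the previous and the next slice; the first
#' and last slices use their single neighbour. Slices whose predictions
#' disagree with their anatomical neighbours get low scores and are the best
#' candidates for manual correction. A single-slice case is given score 0
#' (always selected).
#'
#' @param preds ordered list of binary masks (predictions, or labels where
#'   available).
#' @return numeric vector of per-slice scores in `[0, 1]`.
#' @export
adjacent_dice_scores <- function(preds) {
  n <- length(preds)
  if (n == 0) return(numeric(0))
  if (n == 1) return(0)
  d <- vapply(seq_len(n - 1), function(i) dice(preds[[i]], preds[[i + 1]]), 0)
  c(d[1],
    if (n > 2) (d[seq_len(n - 2)] + d[1 + seq_len(n - 2)]) / 2,
    d[n - 1])
}

#' Select slices whose agreement score falls below the threshold
#'
#' @param scores per-slice scores from [adjacent_dice_scores()].
#' @param dice_ts selection threshold; slices with `score < dice_ts` are
#'   selected.
#' @return integer indices of selected slices.
#' @export
select_slices <- function(scores, dice_ts) which(scores < dice_ts)

#' Simulated sparse correction by the annotating doctor
#'
#' From the selected slice indices (in increasing order), every
#' `(interval + 1)`-th is kept for correction; the kept slices' predictions are
#' replaced by the ground-truth masks (the simulated doctor corrects
#' perfectly).
#'
#' @param selected integer indices of slices selected for correction.
#' @param gt_masks per-slice ground-truth masks of the case.
#' @param interval nonnegative integer: selected slices skipped between
#'   consecutive corrections (0 = correct all selected).
#' @return list with `corrected` (indices actually corrected) and `masks`
#'   (their ground-truth masks).
#' @export
oracle_correct <- function(selected, gt_masks, interval = 0L) {
  if (interval < 0) stop_config("interval must be nonnegative")
  sel <- sort(selected)
  if (length(sel) == 0) return(list(corrected = integer(0), masks = list()))
  kept <- sel[seq(1L, length(sel), by = as.integer(interval) + 1L)]
  list(corrected = kept, masks = gt_masks[kept])
}

#' Schedule for the iterative annotation loop
#'
#' The selection threshold rises linearly from `dice_ts_start` to 1 over
#' `n_rounds`; the correction interval steps down by 1 per round from
#' `correction_interval_start` and must reach 0 before the last round, else the
#' loop could never annotate everything (a configuration error).
#'
#' @param dice_ts_start starting threshold in `[0, 1]`.
#' @param n_rounds number of annotation rounds.
#' @param correction_interval_start starting sparse-correction interval.
#' @return object of class `iasal_schedule` with vectors `dice_ts` and
#'   `interval`.
#' @export
iasal_schedule <- function(dice_ts_start = 0.7, n_rounds = 5L,
                           correction_interval_start = 3L) {
  n_rounds <- as.integer(n_rounds)
  if (n_rounds < 1) stop_config("n_rounds must be >= 1")
  dice_ts <- if (n_rounds == 1) 1 else seq(dice_ts_start, 1, length.out = n_rounds)
  interval <- pmax(correction_interval_start - (seq_len(n_rounds) - 1L), 0L)
  if (interval[n_rounds] != 0 || dice_ts[n_rounds] < 1)
    stop_config("non-terminating schedule: the final round must have interval 0 and dice_ts 1")
  structure(list(dice_ts = dice_ts, interval = interval, n_rounds = n_rounds),
            class = "iasal_schedule")
}

new_annotation_state <- function(volumes, sparse_idx) {
  status <- lapply(seq_along(volumes), function(v) {
    st <- rep("bbox_only", length(volumes[[v]]$slices))
    st[sparse_idx[[v]]] <- "seg_labeled"
    st
  })
  list(status = status, round_index = 0L,
       ss = sum(lengths(sparse_idx)),
       sbb = sum(vapply(status, function(s) sum(s == "bbox_only"), 0L)))
}

#' Iterative model updating and annotation with active-learning selection
#'
#' Repeats: predict all slices; score each slice by its adjacent-slice Dice
#' (using true labels where a slice is already annotated); select unannotated
#' slices below the round's threshold (active mode) or the next unannotated
#' slices in stack order (sequential baseline); sparsely correct them with the
#' simulated doctor; retrain each tissue's network on all annotated slices
#' (pure true-label supervision). In the last scheduled round every remaining
#' unannotated slice is corrected, so the loop always terminates fully
#' annotated.
#'
#' @param model a fitted [swssl()] model (the pre-annotation model).
#' @param volumes the volumes being annotated (ground truth is the simulated
#'   doctor's correction source).
#' @param schedule an [iasal_schedule()].
#' @param config a [train_config()] for the per-round retraining.
#' @param selection `"active"` (adjacent-Dice selection) or `"sequential"`
#'   (dense in-order baseline).
#' @param budget_per_round optional integer vector: corrections per round,
#'   overriding threshold/interval-driven counts (used for equal-budget
#'   comparisons; in active mode the lowest-scoring slices are taken).
#' @param test_volumes optional held-out volumes for per-round test Dice.
#' @param retrain_rounds training rounds per annotation round.
#' @param warm_start retrain from the current parameters (default) or from a
#'   fresh initialization each round.
#' @return object of class `iasal_result`: final model, annotation state,
#'   per-round metrics data frame, and corrected counts.
#' @export
run_iasal <- function(model, volumes, schedule = iasal_schedule(),
                      config = model$config,
                      selection = c("active", "sequential"),
                      budget_per_round = NULL, test_volumes = NULL,
                      retrain_rounds = config$max_rounds, warm_start = TRUE) {
  selection <- match.arg(selection)
  sparse_idx <- lapply(volumes, function(v)
    select_sparse_slices(length(v$slices), model$s_int))
  state <- new_annotation_state(volumes, sparse_idx)
  metrics <- NULL; corrected_per_round <- integer(0)
  cfg <- config; cfg$max_rounds <- as.integer(retrain_rounds)

  for (r in seq_len(schedule$n_rounds)) {
    state$round_index <- r
    # score every case, then select slices to correct
    picked <- vector("list", length(volumes))
    case_scores <- vector("list", length(volumes))
    if (selection == "active") {
      for (v in seq_along(volumes)) {
        vol <- volumes[[v]]
        per_tis <- lapply(model$tissues, function(tis) {
          stack <- lapply(seq_along(vol$slices), function(i) {
            if (state$status[[v]][i] != "bbox_only") vol$masks[[tis]][[i]]
            else (net_forward(model$nets[[tis]], vol$slices[[i]])$seg_prob >= 0.5) * 1
          })
          adjacent_dice_scores(stack)
        })
        case_scores[[v]] <- Reduce(`+`, per_tis) / length(per_tis)
      }
    }
    if (is.null(budget_per_round)) {
      # schedule-driven: per-case threshold selection + sparse correction
      for (v in seq_along(volumes)) {
        unlab <- which(state$status[[v]] == "bbox_only")
        if (length(unlab) == 0) next
        if (selection == "active") {
          sel <- intersect(select_slices(case_scores[[v]], schedule$dice_ts[r]),
                           unlab)
          if (r == schedule$n_rounds) sel <- unlab
          picked[[v]] <- oracle_correct(sel, volumes[[v]]$masks[[model$tissues[1]]],
                                        schedule$interval[r])$corrected
        } else {
          picked[[v]] <- unlab
        }
      }
    } else {
      # fixed total budget per round: rank globally (active) or take the
      # first unannotated slices in case/slice order (sequential baseline)
      b <- budget_per_round[r]
      cand <- do.call(rbind, lapply(seq_along(volumes), function(v) {
        unlab <- which(state$status[[v]] == "bbox_only")
        if (length(unlab) == 0) return(NULL)
        data.frame(v = v, i = unlab,
                   score = if (selection == "active") case_scores[[v]][unlab]
                           else seq_along(unlab))
      }))
      if (!is.null(cand)) {
        ord <- if (selection == "active") order(cand$score, cand$v, cand$i)
               else order(cand$v, cand$i)
        take <- cand[ord[seq_len(min(b, nrow(cand)))], ]
        for (v in unique(take$v)) picked[[v]] <- sort(take$i[take$v == v])
      }
    }
    n_corr <- sum(lengths(picked))
    corrected_per_round <- c(corrected_per_round, n_corr)
    for (v in seq_along(volumes))
      state$status[[v]][picked[[v]]] <- "corrected"
    state$ss <- state$ss + n_corr
    state$sbb <- sum(vapply(state$status, function(s) sum(s == "bbox_only"), 0L))

    # retrain on all annotated slices (true labels only)
    labeled_idx <- lapply(state$status, function(s) which(s != "bbox_only"))
    for (tis in model$tissues) {
      smp <- volume_samples(volumes, tis, labeled_idx)
      net <- if (warm_start) model$nets[[tis]]
             else backbone_init(model$backbone, seed = cfg$seed)
      model$nets[[tis]] <- train_stage_sparse(net, smp, cfg, val = NULL)
      attr(model$nets[[tis]], "history") <- NULL
    }

    td <- if (is.null(test_volumes)) NULL else evaluate_model(model, test_volumes)
    row <- data.frame(round = r, dice_ts = schedule$dice_ts[r],
                      interval = schedule$interval[r], n_corrected = n_corr,
                      ss = state$ss, sbb = state$sbb,
                      seq_workload = equivalent_workload(state$ss, state$sbb))
    if (!is.null(td))
      for (tis in names(td)) row[[paste0("test_dice_", tis)]] <- td[[tis]]
    metrics <- rbind(metrics, row)
    if (all(vapply(state$status, function(s) all(s != "bbox_only"), TRUE))) break
  }
  structure(list(model = model, state = state, metrics = metrics,
                 corrected_per_round = corrected_per_round,
                 selection = selection),
            class = "iasal_result")
}

#' @export
print.iasal_result <- function(x, ...) {
  cat(sprintf("iterative annotation (%s selection): %d rounds, %d slices corrected\n",
              x$selection, nrow(x$metrics), sum(x$corrected_per_round)))
  cat(sprintf("  final workload: Ss = %d, Sbb = %d, Seq = %d\n",
              x$state$ss, x$state$sbb,
              equivalent_workload(x$state$ss, x$state$sbb)))
  invisible(x)
}

#' @export
summary.iasal_result <- function(object, ...) {
  print(object)
  print(object$metrics)
  invisible(object)
}

#' Plot per-round test Dice of an annotation run
#'
#' @param x an `iasal_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.iasal_result <- function(x, ...) {
  cols <- grep("^test_dice_", names(x$metrics), value = TRUE)
  if (length(cols) == 0) {
    graphics::plot(x$metrics$round, x$metrics$n_corrected, type = "b",
                   xlab = "round", ylab = "slices corrected", ...)
  } else {
    graphics::matplot(x$metrics$round, as.matrix(x$metrics[cols]), type = "b",
                      pch = 1, xlab = "round", ylab = "test Dice", ...)
    graphics::legend("bottomright", legend = sub("^test_dice_", "", cols),
                     col = seq_along(cols), lty = seq_along(cols), bty = "n")
  }
  invisible(x)
}

#' Equivalent segmentation annotation workload
#'
#' Converts bounding-box annotation effort into segmentation-annotation units:
#' drawing a full segmentation mask takes about 15 times as long as drawing a
#' box, so `Seq = Ss + floor(Sbb / 15)` (reported as an integer; the exact
#' rational value is attached as attribute `exact`).
#'
#' @param ss number of segmentation-annotated slices.
#' @param sbb number of bounding-box-annotated slices.
#' @return integer workload, with attribute `exact`.
#' @examples
#' equivalent_workload(320, 10800)  # 1040
#' @export
equivalent_workload <- function(ss, sbb) {
  if (ss < 0 || sbb < 0) stop_config("counts must be nonnegative")
  out <- as.integer(ss + sbb %/% 15)
  attr(out, "exact") <- ss + sbb / 15
  out
}
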