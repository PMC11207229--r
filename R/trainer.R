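#' Training configuration
#'
#' Defaults follow common practice for Adam-trained segmentation networks:
#' learning rate 5e-4, weight decay 1e-4, first-moment decay (momentum) 0.9,
#' batch size 8, early stopping with patience 20 monitored on validation Dice.
#' `max_rounds` is the per-stage round (epoch) budget; the desk-scale default
#' is 50 (the full-scale setting would be 1000).
#'
#' @param learning_rate,weight_decay,beta1 Adam settings.
#' @param batch_size gradient-accumulation batch size (slices).
#' @param max_rounds maximum training rounds (epochs) per stage.
#' @param early_stop_patience rounds without validation-Dice improvement
#'   before stopping (only active when a validation set is supplied).
#' @param refine_cycles pseudo-label self-refinement repetitions in the
#'   bounding-box stage (0 = train on raw region-grown labels only).
#' @param e_thres round at which joint-training supervision becomes purely the
#'   true sparse labels; defaults to `ceiling(max_rounds / 2)`.
#' @param sparse_rounds,bbox_rounds,joint_rounds optional per-stage round
#'   budgets for [swssl()]; default to `max_rounds`. The bounding-box stage
#'   trains repeatedly (once per refinement cycle), so a smaller budget there
#'   balances the stages' optimization effort.
#' @param seed RNG seed controlling initialization and slice order.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 1e-4,
                         beta1 = 0.9, batch_size = 8L, max_rounds = 50L,
                         early_stop_patience = 20L, refine_cycles = 3L,
                         e_thres = NULL, sparse_rounds = NULL,
                         bbox_rounds = NULL, joint_rounds = NULL, seed = 1L) {
  if (is.null(e_thres)) e_thres <- max(1L, ceiling(max_rounds / 2))
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, batch_size = as.integer(batch_size),
                 max_rounds = as.integer(max_rounds),
                 early_stop_patience = as.integer(early_stop_patience),
                 refine_cycles = as.integer(refine_cycles),
                 e_thres = as.integer(e_thres),
                 sparse_rounds = as.integer(sparse_rounds %||% max_rounds),
                 bbox_rounds = as.integer(bbox_rounds %||% max_rounds),
                 joint_rounds = as.integer(joint_rounds %||% max_rounds),
                 seed = as.integer(seed)),
            class = "train_config")
}

# one pass over `samples` (list of list(image, mask, edge or NULL)), with
# gradient accumulation; returns updated net/optimizer state and mean loss
run_round <- function(net, state, samples, cfg, edge_frozen, weight = 1) {
  if (weight == 0) return(list(net = net, state = state, mean_loss = 0))
  tot <- 0; acc <- NULL; nb <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    lg <- loss_and_grads(net, s$image, s$mask, s$edge,
                         edge_frozen = edge_frozen || is.null(s$edge),
                         weight = weight)
    tot <- tot + lg$loss
    acc <- add_grads(acc, lg$grads); nb <- nb + 1L
    if (nb == cfg$batch_size || i == length(samples)) {
      st <- adam_step(net, scale_grads(acc, 1 / nb), state,
                      lr = cfg$learning_rate, beta1 = cfg$beta1,
                      weight_decay = cfg$weight_decay)
      net <- st$net; state <- st$state; acc <- NULL; nb <- 0L
    }
  }
  list(net = net, state = state, mean_loss = tot / length(samples))
}

# mean Dice of binarized predictions over validation samples
samples_val_dice <- function(net, val) {
  if (is.null(val) || length(val) == 0) return(NA_real_)
  mean(vapply(val, function(s) {
    p <- net_forward(net, s$image)$seg_prob
    dice((p >= 0.5) * 1, s$mask)
  }, 0))
}

attach_edges <- function(samples) {
  lapply(samples, function(s) { s$edge <- edge_from_mask(s$mask); s })
}

#' Stage A: train on sparse segmentation labels with the edge-aware loss
#'
#' Minimizes the area loss plus the weighted edge loss on the sparsely
#' annotated slices; edge labels are derived from the masks by
#' [edge_from_mask()]. With a validation set, the best-validation checkpoint is
#' returned and early stopping applies.
#'
#' @param net a `swsal_net`.
#' @param samples list of `list(image =, mask =)` training slices.
#' @param cfg a [train_config()].
#' @param val optional validation samples in the same form.
#' @return the trained network, with a `history` attribute (data frame of
#'   round, loss, val_dice).
#' @export
train_stage_sparse <- function(net, samples, cfg = train_config(), val = NULL) {
  if (length(samples) == 0) stop_config("empty training set")
  samples <- attach_edges(samples)
  state <- adam_init(net$params)
  best <- list(net = net, dice = samples_val_dice(net, val))
  hist <- NULL; bad <- 0L
  for (r in seq_len(cfg$max_rounds)) {
    rr <- run_round(net, state, samples, cfg, edge_frozen = FALSE)
    net <- rr$net; state <- rr$state
    vd <- samples_val_dice(net, val)
    hist <- rbind(hist, data.frame(round = r, loss = rr$mean_loss, val_dice = vd))
    if (!is.na(vd)) {
      if (is.na(best$dice) || vd > best$dice) { best <- list(net = net, dice = vd); bad <- 0L }
      else bad <- bad + 1L
      if (bad >= cfg$early_stop_patience) break
    }
  }
  out <- if (!is.na(best$dice)) best$net else net
  attr(out, "history") <- hist
  out
}

#' Stage B: train on pseudo-labels with self-refinement (edge head frozen)
#'
#' Trains with the pseudo-label area loss only; the edge head neither
#' contributes a loss term nor receives gradients, and no gradient flows
#' through its features into the segmentation head. The network is first
#' trained on the raw region-grown labels; each of the `refine_cycles`
#' refinement cycles then replaces every slice's pseudo-label by the binarized
#' (threshold 0.5) network prediction and retrains. A pseudo-label that was
#' originally empty stays empty. `refine_cycles = 0` trains on the raw labels
#' and leaves them unchanged (the no-refinement baseline).
#'
#' @param net a `swsal_net`.
#' @param samples list of `list(image =, mask =)` pseudo-labelled slices.
#' @param cfg a [train_config()].
#' @param val optional validation samples (true masks).
#' @return list with `net` (trained network) and `samples` (the slices with
#'   final refined pseudo-labels), plus a `history` data frame.
#' @export
train_stage_bbox <- function(net, samples, cfg = train_config(), val = NULL) {
  if (length(samples) == 0 || all(vapply(samples, function(s) sum(s$mask) == 0, TRUE)))
    stop_config("all pseudo-labels are empty; nothing to train on")
  originally_empty <- vapply(samples, function(s) sum(s$mask) == 0, TRUE)
  edge_before <- net$params[c("edge1", "edge2")]
  hist <- NULL
  fit_once <- function(net, samples, cycle) {
    state <- adam_init(net$params)
    best <- list(net = net, dice = samples_val_dice(net, val))
    bad <- 0L
    for (r in seq_len(cfg$max_rounds)) {
      rr <- run_round(net, state, samples, cfg, edge_frozen = TRUE)
      net <- rr$net; state <- rr$state
      vd <- samples_val_dice(net, val)
      hist <<- rbind(hist, data.frame(cycle = cycle, round = r,
                                      loss = rr$mean_loss, val_dice = vd))
      if (!is.na(vd)) {
        if (is.na(best$dice) || vd > best$dice) { best <- list(net = net, dice = vd); bad <- 0L }
        else bad <- bad + 1L
        if (bad >= cfg$early_stop_patience) break
      }
    }
    if (!is.na(best$dice)) best$net else net
  }
  net <- fit_once(net, lapply(samples, function(s) { s$edge <- NULL; s }), 0L)
  if (cfg$refine_cycles > 0) {
    for (cyc in seq_len(cfg$refine_cycles)) {
      for (i in seq_along(samples)) {
        if (originally_empty[i]) next
        p <- net_forward(net, samples[[i]]$image)$seg_prob
        samples[[i]]$mask <- (p >= 0.5) * 1
      }
      net <- fit_once(net, lapply(samples, function(s) { s$edge <- NULL; s }), cyc)
    }
  }
  stopifnot(identical(net$params$edge1, edge_before$edge1),
            identical(net$params$edge2, edge_before$edge2))
  out <- list(net = net, samples = samples)
  attr(out, "history") <- hist
  out
}

#' Stage C: scheduled joint training on pseudo- and true sparse labels
#'
#' Each round runs one pass over the pseudo-labelled slices (weight `alpha`)
#' and one over the sparsely labelled slices (weight `beta`), with the weights
#' from [schedule_weights()]: training starts fully pseudo-supervised and
#' shifts linearly to pure true-label supervision by round `e_thres`.
#' Pseudo-edge labels are derived from the (refined) pseudo-masks; the edge
#' head trains in this stage.
#'
#' @param net a `swsal_net`.
#' @param sparse_samples,pseudo_samples lists of `list(image =, mask =)`.
#' @param cfg a [train_config()] (uses `e_thres` and `max_rounds`).
#' @param val optional validation samples.
#' @return the trained network with a `history` attribute.
#' @export
train_joint <- function(net, sparse_samples, pseudo_samples,
                        cfg = train_config(), val = NULL) {
  if (length(sparse_samples) == 0 || length(pseudo_samples) == 0)
    stop_config("both label sets must be nonempty")
  if (cfg$e_thres > cfg$max_rounds)
    warning("e_thres exceeds max_rounds: the schedule never reaches pure sparse supervision")
  sparse_samples <- attach_edges(sparse_samples)
  pseudo_samples <- attach_edges(pseudo_samples)
  state <- adam_init(net$params)
  best <- list(net = net, dice = samples_val_dice(net, val))
  hist <- NULL; bad <- 0L
  for (r in seq_len(cfg$max_rounds)) {
    s <- joint_schedule(cfg$e_thres, cfg$max_rounds, e_cur = r - 1L)
    w <- schedule_weights(s)
    rp <- run_round(net, state, pseudo_samples, cfg, edge_frozen = FALSE,
                    weight = w["alpha"])
    net <- rp$net; state <- rp$state
    rg <- run_round(net, state, sparse_samples, cfg, edge_frozen = FALSE,
                    weight = w["beta"])
    net <- rg$net; state <- rg$state
    vd <- samples_val_dice(net, val)
    hist <- rbind(hist, data.frame(round = r, alpha = unname(w["alpha"]),
                                   beta = unname(w["beta"]),
                                   loss_pseudo = rp$mean_loss,
                                   loss_sparse = rg$mean_loss, val_dice = vd))
    if (!is.na(vd)) {
      if (is.na(best$dice) || vd > best$dice) { best <- list(net = net, dice = vd); bad <- 0L }
      else bad <- bad + 1L
      if (bad >= cfg$early_stop_patience) break
    }
  }
  out <- if (!is.na(best$dice)) best$net else net
  attr(out, "history") <- hist
  out
}

# build per-tissue training samples from volumes at the given slice indices
volume_samples <- function(volumes, tissue, slice_idx = NULL, masks = NULL) {
  out <- list()
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    idx <- if (is.null(slice_idx)) seq_along(vol$slices) else slice_idx[[v]]
    src <- if (is.null(masks)) vol$masks[[tissue]] else masks[[v]][[tissue]]
    for (i in idx)
      out[[length(out) + 1L]] <- list(image = vol$slices[[i]], mask = src[[i]],
                                      case = v, slice = i)
  }
  out
}

#' Fit the full semi-weakly supervised segmentation model
#'
#' The three-stage pipeline, per tissue: (A) train on the sparse segmentation
#' labels with the edge-aware loss; (B) grow pseudo-labels from the bounding
#' boxes of the remaining slices and train on them with self-refinement (edge
#' head frozen); (C) scheduled joint training on both label sets. Each stage
#' warm-starts from the previous one.
#'
#' @param volumes training volumes (see [generate_phantom()]).
#' @param s_int sparse annotation interval (unannotated slices between
#'   annotated ones).
#' @param val_volumes optional fully annotated validation volumes (early
#'   stopping and checkpoint selection).
#' @param config a [train_config()].
#' @param backbone a [backbone_config()].
#' @param tissues tissue names to fit (default: the volumes' tissues).
#' @param stages which stages to run: subset of `c("sparse", "bbox", "joint")`.
#'   `"sparse"` alone is the sparse-only baseline; `"bbox"` alone the
#'   weakly-supervised baseline.
#' @return object of class `swssl_model`: per-tissue trained networks, stage
#'   histories, refined pseudo-labels, and workload counters (`ss` sparse
#'   slices, `sbb` box-annotated slices).
#' @export
swssl <- function(volumes, s_int = 3L, val_volumes = NULL,
                  config = train_config(), backbone = backbone_config(),
                  tissues = NULL,
                  stages = c("sparse", "bbox", "joint")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(tissues)) tissues <- volumes[[1]]$tissue_names
  n_slices <- vapply(volumes, function(v) length(v$slices), 0L)
  sparse_idx <- lapply(n_slices, select_sparse_slices, s_int = s_int)
  other_idx <- lapply(seq_along(volumes), function(v)
    setdiff(seq_len(n_slices[v]), sparse_idx[[v]]))
  nets <- list(); histories <- list(); refined <- list()
  for (tis in tissues) {
    set.seed(config$seed)
    kind <- if (grepl("cart", tis)) "cartilage" else "bone"
    net <- backbone_init(backbone, seed = config$seed)
    val <- if (is.null(val_volumes)) NULL else volume_samples(val_volumes, tis)
    hist <- list()
    sparse_smp <- volume_samples(volumes, tis, sparse_idx)
    pseudo_smp <- NULL
    if (any(c("bbox", "joint") %in% stages)) {
      gp <- grow_params(kind)
      pseudo_smp <- list()
      for (v in seq_along(volumes)) {
        vol <- volumes[[v]]
        pl <- pseudo_labels_for_volume(vol, boxes = vol$boxes[tis],
                                       params = stats::setNames(list(gp), tis))
        for (i in other_idx[[v]])
          pseudo_smp[[length(pseudo_smp) + 1L]] <-
            list(image = vol$slices[[i]], mask = pl$masks[[tis]][[i]],
                 case = v, slice = i)
      }
    }
    stage_cfg <- function(rounds) { cfg <- config; cfg$max_rounds <- rounds; cfg }
    if ("sparse" %in% stages) {
      net <- train_stage_sparse(net, sparse_smp, stage_cfg(config$sparse_rounds), val)
      hist$sparse <- attr(net, "history"); attr(net, "history") <- NULL
    }
    if ("bbox" %in% stages) {
      sb <- train_stage_bbox(net, pseudo_smp, stage_cfg(config$bbox_rounds), val)
      net <- sb$net; pseudo_smp <- sb$samples
      hist$bbox <- attr(sb, "history")
    }
    if ("joint" %in% stages) {
      # joint training re-initializes the network parameters; the earlier
      # stages' contribution enters through the refined pseudo-labels
      net <- backbone_init(backbone, seed = config$seed)
      net <- train_joint(net, sparse_smp, pseudo_smp, stage_cfg(config$joint_rounds), val)
      hist$joint <- attr(net, "history"); attr(net, "history") <- NULL
    }
    nets[[tis]] <- net; histories[[tis]] <- hist
    refined[[tis]] <- pseudo_smp
  }
  ss <- if ("sparse" %in% stages) sum(lengths(sparse_idx)) else 0L
  sbb <- if (any(c("bbox", "joint") %in% stages)) sum(lengths(other_idx)) else 0L
  structure(list(nets = nets, tissues = tissues, s_int = s_int,
                 config = config, backbone = backbone, stages = stages,
                 histories = histories, refined_pseudo = refined,
                 sparse_idx = sparse_idx, ss = ss, sbb = sbb),
            class = "swssl_model")
}

#' Predict per-tissue masks for a volume
#'
#' @param object an `swssl_model`.
#' @param newdata a volume (or list of slices).
#' @param threshold binarization threshold for masks.
#' @param ... unused.
#' @return list with `prob[[tissue]][[slice]]` and `mask[[tissue]][[slice]]`.
#' @export
predict.swssl_model <- function(object, newdata, threshold = 0.5, ...) {
  slices <- if (!is.null(newdata$slices)) newdata$slices else newdata
  prob <- list(); mask <- list()
  for (tis in object$tissues) {
    pr <- lapply(slices, function(s) net_forward(object$nets[[tis]], s)$seg_prob)
    prob[[tis]] <- pr
    mask[[tis]] <- lapply(pr, function(p) (p >= threshold) * 1)
  }
  list(prob = prob, mask = mask)
}

#' Mean test Dice of a fitted model on annotated volumes
#'
#' @param model an `swssl_model`.
#' @param volumes annotated volumes.
#' @return named numeric, mean Dice per tissue.
#' @export
evaluate_model <- function(model, volumes) {
  out <- stats::setNames(numeric(length(model$tissues)), model$tissues)
  for (tis in model$tissues) {
    ds <- unlist(lapply(volumes, function(v) {
      pr <- predict.swssl_model(model, v)
      vapply(seq_along(v$slices), function(i)
        dice(pr$mask[[tis]][[i]], v$masks[[tis]][[i]]), 0)
    }))
    out[tis] <- mean(ds)
  }
  out
}

#' @export
print.swssl_model <- function(x, ...) {
  cat("semi-weakly supervised segmentation model\n")
  cat(sprintf("  tissues: %s\n", paste(x$tissues, collapse = ", ")))
  cat(sprintf("  stages run: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  sparse interval: %d (Ss = %d slices); box-annotated Sbb = %d slices\n",
              x$s_int, x$ss, x$sbb))
  cat(sprintf("  equivalent annotation workload: %d slices\n",
              equivalent_workload(x$ss, x$sbb)))
  invisible(x)
}

#' @export
summary.swssl_model <- function(object, ...) {
  print(object)
  for (tis in object$tissues) {
    h <- object$histories[[tis]]
    for (st in names(h)) {
      hh <- h[[st]]
      vd <- hh$val_dice[nrow(hh)]
      cat(sprintf("  [%s/%s] %d rounds, final loss %.4f%s\n", tis, st, nrow(hh),
                  hh$loss[nrow(hh)] %||% hh$loss_sparse[nrow(hh)],
                  if (is.na(vd)) "" else sprintf(", final val Dice %.3f", vd)))
    }
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot training histories of a fitted model
#'
#' @param x an `swssl_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.swssl_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$tissues)))
  on.exit(graphics::par(op))
  for (tis in x$tissues) {
    h <- x$histories[[tis]]
    losses <- unlist(lapply(h, function(hh)
      if (!is.null(hh$loss)) hh$loss else hh$loss_sparse + hh$loss_pseudo))
    graphics::plot(seq_along(losses), losses, type = "l", xlab = "round",
                   ylab = "training loss", main = tis, ...)
  }
  invisible(x)
}
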