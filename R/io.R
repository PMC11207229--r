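# Volumes are stored as NIfTI (one file per case per role: image plus one
# binary mask per tissue) or as per-slice PNG; bounding boxes as JSON. In the
# on-disk JSON dialect slice indices and box coordinates are 0-based (the
# common convention of image tooling); the R API is 1-based throughout and
# conversion happens at the file boundary.

slices_to_array <- function(slices) {
  H <- nrow(slices[[1]]); W <- ncol(slices[[1]])
  array(unlist(slices), c(H, W, length(slices)))
}

array_to_slices <- function(a) lapply(seq_len(dim(a)[3]), function(i) a[, , i])

#' Write a volume to disk
#'
#' NIfTI format writes `<case>_image.nii.gz` and `<case>_mask_<tissue>.nii.gz`
#' into `dir`; PNG format writes 16-bit grayscale `<case>_slice####.png` files
#' (quantized, hence lossy for float intensities) plus per-tissue mask PNGs.
#' Boxes are written to `<case>_boxes.json` in the 0-based JSON dialect
#' `{case: {slice: {tissue: [rmin, cmin, rmax, cmax]}}}`.
#'
#' @param volume a volume (see [generate_phantom()]).
#' @param dir output directory (created if missing).
#' @param format `"nifti"` or `"png"`.
#' @return the directory, invisibly.
#' @export
write_volume <- function(volume, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- volume$case_id
  if (format == "nifti") {
    RNifti::writeNifti(RNifti::asNifti(slices_to_array(volume$slices)),
                       file.path(dir, paste0(id, "_image.nii.gz")))
    for (tis in names(volume$masks))
      RNifti::writeNifti(RNifti::asNifti(slices_to_array(volume$masks[[tis]])),
                         file.path(dir, paste0(id, "_mask_", tis, ".nii.gz")))
  } else {
    for (i in seq_along(volume$slices)) {
      png::writePNG(pmin(pmax(volume$slices[[i]], 0), 1),
                    file.path(dir, sprintf("%s_slice%04d.png", id, i - 1)))
      for (tis in names(volume$masks))
        png::writePNG(volume$masks[[tis]][[i]],
                      file.path(dir, sprintf("%s_mask_%s_slice%04d.png", id, tis, i - 1)))
    }
  }
  if (!is.null(volume$boxes))
    write_boxes(stats::setNames(list(volume$boxes), id),
                file.path(dir, paste0(id, "_boxes.json")))
  invisible(dir)
}

normalize_mask_values <- function(m) {
  u <- sort(unique(as.vector(m)))
  if (all(u %in% c(0, 1))) return(m)
  if (all(u %in% c(0, 255))) {
    warning("mask values {0,255} normalized to {0,1}")
    return(m / 255)
  }
  stop_config("mask is not binary (values found: %s)",
              paste(utils::head(u, 5), collapse = ", "))
}

#' Read a volume from disk
#'
#' Reads the files written by [write_volume()]. Masks with values `{0, 255}`
#' are normalized to `{0, 1}` with a warning; any other non-binary mask is a
#' format error. Boxes are read from `<case>_boxes.json` when present,
#' otherwise recomputed from the masks.
#'
#' @param dir directory containing the case files.
#' @param case_id the case identifier.
#' @param format `"nifti"` or `"png"`.
#' @return a volume list.
#' @export
read_volume <- function(dir, case_id, format = c("nifti", "png")) {
  format <- match.arg(format)
  if (format == "nifti") {
    img_path <- file.path(dir, paste0(case_id, "_image.nii.gz"))
    if (!file.exists(img_path)) stop_config("no such volume: %s", img_path)
    slices <- array_to_slices(unclass(as.array(RNifti::readNifti(img_path))))
    mask_files <- list.files(dir, sprintf("^%s_mask_.*\\.nii(\\.gz)?$", case_id),
                             full.names = TRUE)
    tissues <- sub(sprintf("^%s_mask_(.*)\\.nii(\\.gz)?$", case_id), "\\1",
                   basename(mask_files))
    masks <- stats::setNames(lapply(mask_files, function(f) {
      lapply(array_to_slices(unclass(as.array(RNifti::readNifti(f)))),
             normalize_mask_values)
    }), tissues)
  } else {
    sf <- sort(list.files(dir, sprintf("^%s_slice[0-9]+\\.png$", case_id),
                          full.names = TRUE))
    if (length(sf) == 0) stop_config("no PNG slices for case %s in %s", case_id, dir)
    slices <- lapply(sf, function(f) png::readPNG(f))
    dims <- vapply(slices, dim, c(0, 0))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop_config("slice shape mismatch within case %s", case_id)
    mf <- list.files(dir, sprintf("^%s_mask_.*_slice[0-9]+\\.png$", case_id),
                     full.names = TRUE)
    tissues <- unique(sub(sprintf("^%s_mask_(.*)_slice[0-9]+\\.png$", case_id),
                          "\\1", basename(mf)))
    masks <- stats::setNames(lapply(tissues, function(tis) {
      fs <- sort(grep(sprintf("_mask_%s_slice", tis), mf, value = TRUE))
      lapply(fs, function(f) normalize_mask_values(round(png::readPNG(f))))
    }), tissues)
  }
  bpath <- file.path(dir, paste0(case_id, "_boxes.json"))
  boxes <- if (file.exists(bpath)) read_boxes(bpath)[[case_id]]
           else lapply(masks, function(ms) lapply(ms, tight_bbox))
  structure(list(case_id = case_id, slices = slices, masks = masks,
                 boxes = boxes, tissue_names = names(masks)),
            class = "swsal_volume")
}

#' Write / read bounding boxes as JSON
#'
#' On disk, slice indices and coordinates are 0-based; in R they are 1-based.
#' The JSON layout is `{case: {slice: {tissue: [rmin, cmin, rmax, cmax]}}}`.
#'
#' @param boxes named list: `boxes[[case]][[tissue]][[slice]]`.
#' @param path JSON file path.
#' @export
write_boxes <- function(boxes, path) {
  out <- lapply(boxes, function(per_case) {
    n <- max(vapply(per_case, length, 0L))
    slices <- list()
    for (i in seq_len(n)) {
      entry <- list()
      for (tis in names(per_case)) {
        b <- per_case[[tis]][[i]]
        if (!is.null(b)) entry[[tis]] <- as.integer(b - 1L)
      }
      if (length(entry)) slices[[as.character(i - 1L)]] <- entry
    }
    slices
  })
  writeLines(jsonlite::toJSON(out, auto_unbox = FALSE), path)
  invisible(path)
}

#' @rdname write_boxes
#' @param n_slices slice count per case (to place trailing empty slices);
#'   inferred from the largest stored index when `NULL`.
#' @export
read_boxes <- function(path, n_slices = NULL) {
  raw <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)
  lapply(raw, function(per_case) {
    idx <- as.integer(names(per_case)) + 1L
    n <- if (is.null(n_slices)) max(idx) else n_slices
    tissues <- unique(unlist(lapply(per_case, names)))
    out <- stats::setNames(lapply(tissues, function(tis) {
      ms <- vector("list", n)
      for (k in seq_along(per_case)) {
        b <- per_case[[k]][[tis]]
        if (!is.null(b)) ms[[idx[k]]] <- as.integer(unlist(b)) + 1L
      }
      ms
    }), tissues)
    out
  })
}

#' Run a full experiment from a YAML configuration
#'
#' Executes generate -> pretrain (three-stage fit) -> iterate (annotation
#' loop) -> evaluate, writing per-round metric CSVs, checkpoints and a run
#' manifest (JSON) that records the configuration snapshot, seed and package
#' version so the run can be repeated bit-identically.
#'
#' The YAML may contain sections `phantom` (arguments of [phantom_config()]),
#' `split` (`n_train`, `n_val`, `n_test`), `train` (arguments of
#' [train_config()] plus `s_int`, `base_channels`, `depth`) and `iasal`
#' (arguments of [iasal_schedule()] plus `retrain_rounds`).
#'
#' @param config_path YAML file.
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_experiment <- function(config_path, out_dir) {
  cfg <- yaml::read_yaml(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pc <- do.call(phantom_config, cfg$phantom %||% list())
  sp <- cfg$split %||% list(n_train = 3, n_val = 1, n_test = 1)
  pc$n_cases <- sp$n_train + sp$n_val + sp$n_test
  vols <- generate_phantom(pc)
  train_v <- vols[seq_len(sp$n_train)]
  val_v <- vols[sp$n_train + seq_len(sp$n_val)]
  test_v <- vols[sp$n_train + sp$n_val + seq_len(sp$n_test)]

  tr <- cfg$train %||% list()
  s_int <- tr$s_int %||% 3L
  bk <- backbone_config(tr$base_channels %||% 8L, tr$depth %||% 3L)
  tc <- do.call(train_config, tr[intersect(names(tr), names(formals(train_config)))])
  model <- swssl(train_v, s_int = s_int, val_volumes = val_v,
                 config = tc, backbone = bk)
  pre_dice <- evaluate_model(model, test_v)

  ia <- cfg$iasal %||% list()
  sched <- do.call(iasal_schedule,
                   ia[intersect(names(ia), names(formals(iasal_schedule)))])
  res <- run_iasal(model, train_v, sched, tc, test_volumes = test_v,
                   retrain_rounds = ia$retrain_rounds %||% tc$max_rounds)

  utils::write.csv(res$metrics, file.path(out_dir, "iasal_metrics.csv"),
                   row.names = FALSE)
  final_dice <- evaluate_model(res$model, test_v)
  eval_df <- data.frame(stage = c(rep("pretrain", length(pre_dice)),
                                  rep("final", length(final_dice))),
                        tissue = c(names(pre_dice), names(final_dice)),
                        test_dice = c(unname(pre_dice), unname(final_dice)))
  utils::write.csv(eval_df, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  ckpts <- character(0)
  for (tis in res$model$tissues) {
    p <- file.path(out_dir, paste0("net_", tis, ".json"))
    save_checkpoint(res$model$nets[[tis]], p)
    ckpts[tis] <- p
  }
  manifest <- list(package_version = as.character(utils::packageVersion("swsal")),
                   seed = tc$seed, config = cfg,
                   checkpoints = as.list(ckpts),
                   metrics = c("iasal_metrics.csv", "evaluation.csv"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Sparse-interval sweep (annotation-interval ablation)
#'
#' Trains the sparse-only model at several annotation intervals under a fixed
#' per-case slice budget and reports the mean test Dice per tissue, one row
#' per interval.
#'
#' @param train_volumes,test_volumes phantom volumes.
#' @param s_ints intervals to sweep.
#' @param budget_per_case labelled slices per case (the first `budget` slices
#'   of the sparse grid; fewer if the stack is exhausted).
#' @param config a [train_config()].
#' @param backbone a [backbone_config()].
#' @return data frame with columns `s_int`, `n_labeled`, one Dice column per
#'   tissue.
#' @export
sweep_sparse_interval <- function(train_volumes, test_volumes,
                                  s_ints = c(0, 1, 3, 5), budget_per_case = 4L,
                                  config = train_config(),
                                  backbone = backbone_config()) {
  rows <- NULL
  for (s in s_ints) {
    n_slices <- vapply(train_volumes, function(v) length(v$slices), 0L)
    idx <- lapply(n_slices, function(n)
      utils::head(select_sparse_slices(n, s), budget_per_case))
    tissues <- train_volumes[[1]]$tissue_names
    d <- stats::setNames(numeric(length(tissues)), tissues)
    for (tis in tissues) {
      net <- backbone_init(backbone, seed = config$seed)
      net <- train_stage_sparse(net, volume_samples(train_volumes, tis, idx),
                                config)
      ds <- unlist(lapply(test_volumes, function(v)
        vapply(seq_along(v$slices), function(i)
          dice((net_forward(net, v$slices[[i]])$seg_prob >= 0.5) * 1,
               v$masks[[tis]][[i]]), 0)))
      d[tis] <- mean(ds)
    }
    rows <- rbind(rows, data.frame(s_int = s, n_labeled = sum(lengths(idx)),
                                   t(d)))
  }
  rows
}

#' Save / load a fitted semi-weakly supervised model
#'
#' Writes one checkpoint per tissue plus a JSON metadata file, enough to
#' reconstruct the model for prediction, evaluation, or the annotation loop.
#'
#' @param model an `swssl_model`.
#' @param dir directory to write into (created if missing).
#' @return `save_model` the directory, `load_model` the model, invisibly /
#'   visibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tis in model$tissues)
    save_checkpoint(model$nets[[tis]], file.path(dir, paste0("net_", tis, ".json")))
  meta <- list(tissues = model$tissues, s_int = model$s_int,
               stages = model$stages, ss = model$ss, sbb = model$sbb,
               config = unclass(model$config),
               backbone = unclass(model$backbone))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"), simplifyVector = TRUE)
  nets <- stats::setNames(lapply(meta$tissues, function(tis)
    load_checkpoint(file.path(dir, paste0("net_", tis, ".json")))), meta$tissues)
  cfg <- do.call(train_config,
                 meta$config[intersect(names(meta$config),
                                       names(formals(train_config)))])
  bk <- backbone_config(meta$backbone$base_channels, meta$backbone$depth,
                        meta$backbone$edge_weight_swap)
  structure(list(nets = nets, tissues = meta$tissues, s_int = meta$s_int,
                 config = cfg, backbone = bk, stages = meta$stages,
                 histories = list(), refined_pseudo = list(),
                 sparse_idx = NULL, ss = meta$ss, sbb = meta$sbb),
            class = "swssl_model")
}

#' List the case identifiers stored in a volume directory
#'
#' @param dir directory of NIfTI volumes written by [write_volume()].
#' @return character vector of case ids.
#' @export
list_cases <- function(dir) {
  sub("_image\\.nii(\\.gz)?$", "",
      basename(list.files(dir, "_image\\.nii(\\.gz)?$")))
}
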