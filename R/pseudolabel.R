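#' Region-growing parameters for one tissue kind
#'
#' Pseudo-segmentation labels are grown from a seed inside the bounding box
#' until the grown area reaches a tissue-specific fraction of the box area:
#' 0.8 for the compact bone tissue (an ellipse-like region fills most of its
#' box) and 0.6 for the thin cartilage tissue. Growth admits 8-connected
#' neighbours whose intensity is within a tolerance of the running region mean;
#' when no neighbour qualifies, the tolerance is relaxed by `tolerance_step`, so
#' the stop rule always terminates.
#'
#' @param tissue_kind `"bone"` or `"cartilage"`.
#' @param area_ratio_stop stop when region area >= this fraction of the box
#'   area; default 0.8 (bone) / 0.6 (cartilage).
#' @param intensity_tolerance_init initial intensity tolerance.
#' @param tolerance_step tolerance increment when growth stalls.
#' @param max_iterations cap on grow/relax iterations.
#' @param canny_sigma,canny_low_q,canny_high_q Canny settings for the
#'   cartilage seed rule (see [canny()]).
#' @return object of class `grow_params`.
#' @export
grow_params <- function(tissue_kind = c("bone", "cartilage"),
                        area_ratio_stop = NULL,
                        intensity_tolerance_init = 0.05,
                        tolerance_step = 0.02,
                        max_iterations = 500L,
                        canny_sigma = 1.0, canny_low_q = 0.5,
                        canny_high_q = 0.9) {
  tissue_kind <- match.arg(tissue_kind)
  if (is.null(area_ratio_stop))
    area_ratio_stop <- if (tissue_kind == "bone") 0.8 else 0.6
  if (area_ratio_stop <= 0 || area_ratio_stop > 1)
    stop_config("area_ratio_stop must be in (0, 1]")
  structure(list(tissue_kind = tissue_kind, area_ratio_stop = area_ratio_stop,
                 intensity_tolerance_init = intensity_tolerance_init,
                 tolerance_step = tolerance_step,
                 max_iterations = as.integer(max_iterations),
                 canny_sigma = canny_sigma, canny_low_q = canny_low_q,
                 canny_high_q = canny_high_q),
            class = "grow_params")
}

check_box <- function(box, H, W) {
  if (length(box) != 4) stop_config("box must be c(rmin, cmin, rmax, cmax)")
  if (box[1] > box[3] || box[2] > box[4] ||
      box[1] < 1 || box[2] < 1 || box[3] > H || box[4] > W)
    stop_config("box out of image bounds or inverted")
  as.integer(box)
}

#' Seed pixel for region growing inside a bounding box
#'
#' Bone tissue is compact, so the integer centre of the box is the seed.
#' Cartilage is a thin band: Canny edges are detected inside the box, the
#' vertical (longitudinal) extent between the top-most and bottom-most edge
#' response of each column is measured, and the seed is the vertical midpoint
#' of the column with the largest extent. If Canny finds no edge in the box,
#' the box centre is used and a warning is emitted.
#'
#' @param image numeric matrix.
#' @param box integer vector `c(rmin, cmin, rmax, cmax)`, 1-based inclusive.
#' @param kind `"bone"` or `"cartilage"`.
#' @param params a [grow_params()] (Canny settings); defaults per `kind`.
#' @return integer `c(row, col)`, guaranteed to lie inside the box.
#' @export
select_seed <- function(image, box, kind = c("bone", "cartilage"),
                        params = grow_params(kind)) {
  kind <- match.arg(kind)
  box <- check_box(box, nrow(image), ncol(image))
  center <- c((box[1] + box[3]) %/% 2L, (box[2] + box[4]) %/% 2L)
  if (kind == "bone") return(center)
  sub <- image[box[1]:box[3], box[2]:box[4], drop = FALSE]
  ed <- canny(sub, sigma = params$canny_sigma,
              low_q = params$canny_low_q, high_q = params$canny_high_q)
  if (sum(ed) == 0) {
    warning("no Canny edges inside cartilage box; falling back to box centre")
    return(center)
  }
  extent <- rep(-1L, ncol(ed)); mid <- rep(NA_integer_, ncol(ed))
  for (j in seq_len(ncol(ed))) {
    rs <- which(ed[, j] == 1)
    if (length(rs) == 0) next
    extent[j] <- max(rs) - min(rs)
    mid[j] <- (min(rs) + max(rs)) %/% 2L
  }
  jbest <- which.max(extent)
  c(box[1] - 1L + mid[jbest], box[2] - 1L + jbest)
}

#' Grow a pseudo-segmentation mask from a seed inside a bounding box
#'
#' The region starts at the seed and repeatedly admits 8-connected boundary
#' pixels (restricted to the box) whose intensity differs from the running
#' region mean by at most the current tolerance; when no pixel qualifies the
#' tolerance is incremented. Growth stops once the region area reaches
#' `area_ratio_stop` times the box area, or after `max_iterations` iterations
#' (then the largest region reached is returned and flagged low-confidence).
#'
#' @param image numeric matrix.
#' @param seed integer `c(row, col)` inside the box.
#' @param box integer `c(rmin, cmin, rmax, cmax)`, 1-based inclusive.
#' @param params a [grow_params()].
#' @return binary matrix of the image size, with attribute `low_confidence`
#'   (logical).
#' @export
region_grow <- function(image, seed, box, params) {
  H <- nrow(image); W <- ncol(image)
  box <- check_box(box, H, W)
  if (seed[1] < box[1] || seed[1] > box[3] || seed[2] < box[2] || seed[2] > box[4])
    stop_config("seed must lie inside the box")
  sub <- image[box[1]:box[3], box[2]:box[4], drop = FALSE]
  h <- nrow(sub); w <- ncol(sub)
  target <- params$area_ratio_stop * h * w
  region <- matrix(FALSE, h, w)
  region[seed[1] - box[1] + 1L, seed[2] - box[2] + 1L] <- TRUE
  tol <- params$intensity_tolerance_init
  iter <- 0L; low_conf <- FALSE
  while (sum(region) < target) {
    iter <- iter + 1L
    if (iter > params$max_iterations) { low_conf <- TRUE; break }
    frontier <- dilate8(region) & !region
    m <- mean(sub[region])
    admit <- frontier & abs(sub - m) <= tol
    if (any(admit)) region <- region | admit else tol <- tol + params$tolerance_step
  }
  out <- matrix(0, H, W)
  out[box[1]:box[3], box[2]:box[4]] <- region * 1
  attr(out, "low_confidence") <- low_conf
  out
}

#' Pseudo-segmentation labels for a whole volume from its bounding boxes
#'
#' Applies seed selection and region growing per slice and per tissue. Slices
#' without a box for a tissue get an empty mask. Per-slice failures are
#' recorded as flags; the volume is never aborted.
#'
#' @param volume a volume as produced by [generate_phantom()] or
#'   [read_volume()].
#' @param boxes per-tissue, per-slice boxes, `boxes[[tissue]][[slice]]` being
#'   `c(rmin, cmin, rmax, cmax)` or `NULL`; defaults to `volume$boxes`.
#' @param params named list of [grow_params()] per tissue; defaults per kind.
#' @return list with elements `masks` (`masks[[tissue]][[slice]]`, binary
#'   matrices) and `flags` (data frame of per-slice `low_confidence` /
#'   `seed_fallback` flags).
#' @export
pseudo_labels_for_volume <- function(volume, boxes = volume$boxes,
                                     params = NULL) {
  tissues <- names(boxes)
  if (is.null(params))
    params <- stats::setNames(lapply(tissues, function(t)
      grow_params(if (grepl("cart", t)) "cartilage" else "bone")), tissues)
  n <- length(volume$slices)
  H <- nrow(volume$slices[[1]]); W <- ncol(volume$slices[[1]])
  masks <- list(); flags <- NULL
  for (t in tissues) {
    ms <- vector("list", n)
    for (i in seq_len(n)) {
      b <- boxes[[t]][[i]]
      if (is.null(b)) { ms[[i]] <- matrix(0, H, W); next }
      kind <- params[[t]]$tissue_kind
      fallback <- FALSE
      seed <- withCallingHandlers(
        select_seed(volume$slices[[i]], b, kind, params[[t]]),
        warning = function(w) { fallback <<- TRUE; invokeRestart("muffleWarning") })
      pm <- region_grow(volume$slices[[i]], seed, b, params[[t]])
      if (isTRUE(attr(pm, "low_confidence")) || fallback)
        flags <- rbind(flags, data.frame(case_id = volume$case_id, tissue = t,
                                         slice = i,
                                         low_confidence = isTRUE(attr(pm, "low_confidence")),
                                         seed_fallback = fallback))
      attr(pm, "low_confidence") <- NULL
      ms[[i]] <- pm
    }
    masks[[t]] <- ms
  }
  list(masks = masks, flags = flags)
}

#' Write pseudo-labels and their confidence report to disk
#'
#' Masks go to NIfTI (one file per tissue, suffix `_pseudo_<tissue>`) or PNG;
#' the per-slice flags (low-confidence growth, seed fallback) go to a JSON
#' report next to them.
#'
#' @param volume the volume the labels belong to.
#' @param pseudo result of [pseudo_labels_for_volume()].
#' @param dir output directory.
#' @param format `"nifti"` or `"png"`.
#' @return the directory, invisibly.
#' @export
write_pseudo_labels <- function(volume, pseudo, dir,
                                format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- volume$case_id
  for (tis in names(pseudo$masks)) {
    if (format == "nifti") {
      RNifti::writeNifti(RNifti::asNifti(slices_to_array(pseudo$masks[[tis]])),
                         file.path(dir, paste0(id, "_pseudo_", tis, ".nii.gz")))
    } else {
      for (i in seq_along(pseudo$masks[[tis]]))
        png::writePNG(pseudo$masks[[tis]][[i]],
                      file.path(dir, sprintf("%s_pseudo_%s_slice%04d.png",
                                             id, tis, i - 1)))
    }
  }
  report <- if (is.null(pseudo$flags)) list() else pseudo$flags
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, paste0(id, "_pseudo_confidence.json")))
  invisible(dir)
}
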