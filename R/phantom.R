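#' Configuration for the synthetic two-tissue phantom generator
#'
#' The phantom emulates the structure of sagittal knee MRI stacks used for
#' semi-automatic annotation experiments: each case is an ordered stack of 2D
#' slices in which a compact, bright "bone"-like tissue and a thin, elongated
#' "cartilage"-like tissue deform smoothly from slice to slice, so adjacent
#' slices are anatomically similar and that similarity decays with slice
#' distance.
#'
#' @param n_cases number of cases (volumes) to generate.
#' @param slices_per_case number of 2D slices per case.
#' @param height,width slice size in pixels.
#' @param inter_slice_drift nonnegative scale (pixels) of the random-walk
#'   deformation between adjacent slices. `0` makes all ground-truth masks of a
#'   case identical.
#' @param noise_sigma standard deviation of additive gaussian intensity noise
#'   on the nominal `[0,1]` intensity scale.
#' @param rng_seed integer seed; the same seed reproduces the phantom
#'   bit-identically.
#' @param thickness_range length-2 numeric, minimum and maximum thickness in
#'   pixels of the cartilage crescent (thickest at the middle of its arc).
#' @param blur_sigma gaussian blur (pixels) applied to the intensity image to
#'   mimic partial-volume softening of tissue edges; masks are never blurred.
#' @param bias_amplitude amplitude of a smooth low-frequency intensity bias
#'   field, mimicking MRI coil inhomogeneity.
#'
#' @return an object of class `phantom_config`.
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(n_cases = 5L, slices_per_case = 32L,
                           height = 96L, width = 96L,
                           inter_slice_drift = 0.5, noise_sigma = 0.08,
                           rng_seed = 1L, thickness_range = c(2, 6),
                           blur_sigma = 0.7, bias_amplitude = 0.1) {
  if (n_cases < 1 || slices_per_case < 1)
    stop_config("n_cases and slices_per_case must be positive")
  if (height <= 0 || width <= 0)
    stop_config("height and width must be positive")
  if (inter_slice_drift < 0 || noise_sigma < 0)
    stop_config("inter_slice_drift and noise_sigma must be nonnegative")
  if (length(thickness_range) != 2 || any(thickness_range <= 0) ||
      thickness_range[1] > thickness_range[2])
    stop_config("thickness_range must be increasing and positive")
  structure(list(n_cases = as.integer(n_cases),
                 slices_per_case = as.integer(slices_per_case),
                 height = as.integer(height), width = as.integer(width),
                 inter_slice_drift = inter_slice_drift,
                 noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed),
                 thickness_range = thickness_range,
                 blur_sigma = blur_sigma, bias_amplitude = bias_amplitude),
            class = "phantom_config")
}

# wrap an angle difference into (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# boundary radius of the bone as a function of polar angle
bone_radius <- function(theta, R, a2, phi2, a3, phi3) {
  R * (1 + a2 * cos(2 * (theta - phi2)) + a3 * cos(3 * (theta - phi3)))
}

generate_case <- function(cfg, case_id) {
  H <- cfg$height; W <- cfg$width
  mind <- min(H, W)
  drift <- cfg$inter_slice_drift
  n <- cfg$slices_per_case

  # case-level anatomy
  cy0 <- H / 2 + stats::runif(1, -0.05, 0.05) * H
  cx0 <- W / 2 + stats::runif(1, -0.05, 0.05) * W
  R0 <- stats::runif(1, 0.18, 0.23) * mind
  a2 <- stats::runif(1, 0.05, 0.15); phi2 <- stats::runif(1, 0, 2 * pi)
  a3 <- stats::runif(1, 0.02, 0.08); phi3 <- stats::runif(1, 0, 2 * pi)
  th0 <- pi / 2 + stats::runif(1, -0.3, 0.3)   # cartilage arc centre (top of bone)
  hw <- stats::runif(1, 0.9, 1.2)              # arc half-width (radians)
  tmin <- cfg$thickness_range[1]; tmax <- cfg$thickness_range[2]

  # smooth per-slice random walks, scaled by drift
  walk <- function(step_sd) if (n == 1) 0 else cumsum(c(0, stats::rnorm(n - 1, sd = step_sd)))
  cy <- cy0 + walk(drift); cx <- cx0 + walk(drift)
  Rr <- R0 * exp(walk(0.01 * drift))
  ph2 <- phi2 + walk(0.02 * drift)
  th0s <- th0 + walk(0.01 * drift)

  # bias field (fixed per case)
  fy <- stats::runif(1, 0.5, 1.5); fx <- stats::runif(1, 0.5, 1.5)
  psi <- stats::runif(1, 0, 2 * pi)
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  bias <- cfg$bias_amplitude * sin(2 * pi * (fy * yy / H + fx * xx / W) + psi)

  slices <- vector("list", n)
  bone_masks <- vector("list", n); cart_masks <- vector("list", n)
  for (i in seq_len(n)) {
    dy <- yy - cy[i]; dx <- xx - cx[i]
    r <- sqrt(dy^2 + dx^2)
    theta <- atan2(-dy, dx)  # math convention: y axis points up
    rb <- bone_radius(theta, Rr[i], a2, ph2[i], a3, phi3)
    bone <- (r <= rb) * 1
    dth <- ang_diff(theta, th0s[i])
    tt <- tmin + (tmax - tmin) * cos(pmin(abs(dth) / hw, 1) * pi / 2)^2
    gap <- 1
    cart <- (r > rb + gap & r <= rb + gap + tt & abs(dth) <= hw) * 1

    img <- 0.15 + 0.60 * bone + 0.30 * cart
    img <- img + stats::rnorm(1, sd = 0.02)          # per-slice brightness jitter
    img <- img + bias
    img <- gauss_blur(img, cfg$blur_sigma)
    if (cfg$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = cfg$noise_sigma), H, W)

    slices[[i]] <- img
    bone_masks[[i]] <- bone
    cart_masks[[i]] <- cart
  }

  # per-case 0-1 standardization
  lo <- min(vapply(slices, min, 0)); hi <- max(vapply(slices, max, 0))
  slices <- lapply(slices, function(s) {
    if (hi > lo) (s - lo) / (hi - lo) else s * 0
  })

  masks <- list(bone = bone_masks, cartilage = cart_masks)
  boxes <- lapply(masks, function(ms) lapply(ms, tight_bbox))
  structure(list(case_id = case_id, slices = slices, masks = masks,
                 boxes = boxes, tissue_names = c("bone", "cartilage")),
            class = "swsal_volume")
}

#' Generate a batch of synthetic phantom volumes
#'
#' Each volume contains per-slice intensity images standardized to `[0,1]` per
#' case, per-slice/per-tissue ground-truth binary masks, and the tight
#' axis-aligned bounding box of every nonempty mask. The bone tissue is a single
#' connected, star-convex region; the cartilage tissue is a thin crescent
#' hugging an arc of the bone boundary, thickest at the middle of the arc.
#'
#' @param config a [phantom_config()].
#' @return a list of volumes; each volume is a list with elements `case_id`,
#'   `slices` (list of matrices), `masks` (`masks[[tissue]][[slice]]`), `boxes`
#'   (`boxes[[tissue]][[slice]]`, `NULL` where the mask is empty) and
#'   `tissue_names`.
#' @examples
#' vols <- generate_phantom(phantom_config(n_cases = 1, slices_per_case = 4,
#'                                         height = 48, width = 48, rng_seed = 7))
#' dim(vols[[1]]$slices[[1]])
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config"))
    config <- do.call(phantom_config, as.list(config))
  set.seed(config$rng_seed)
  lapply(seq_len(config$n_cases),
         function(k) generate_case(config, sprintf("case%03d", k)))
}

#' Tight axis-aligned bounding box of a binary mask
#'
#' @param mask binary matrix.
#' @return integer vector `c(rmin, cmin, rmax, cmax)` (1-based, inclusive), or
#'   `NULL` when the mask has no foreground pixel.
#' @examples
#' m <- matrix(0, 5, 5); m[2, 3] <- 1
#' tight_bbox(m)  # 2 3 2 3
#' @export
tight_bbox <- function(mask) {
  m <- check_binary_mask(mask)
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  as.integer(c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2])))
}
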