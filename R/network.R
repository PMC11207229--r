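# Small dual-head U-Net-style backbone: a shared encoder-decoder trunk at full
# resolution feeds (a) an edge head and (b) a segmentation head whose input is
# the trunk concatenated with the edge head's last feature map, so edge
# features guide the segmentation ("edge guidance"). Forward/backward and Adam
# are written directly against BLAS matrix products (im2col convolutions);
# everything is deterministic given the seed.

#' Backbone configuration
#'
#' @param base_channels channels of the first encoder level; level `l` uses
#'   `base_channels * 2^(l-1)`.
#' @param depth number of encoder levels (resolution halves `depth - 1` times;
#'   inputs are zero-padded internally to a compatible size and cropped back).
#' @param edge_weight_swap exchange the two class weights of the edge loss
#'   (see [weighted_edge_loss()]).
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(base_channels = 8L, depth = 3L,
                            edge_weight_swap = FALSE) {
  if (base_channels < 1 || depth < 2) stop_config("base_channels >= 1, depth >= 2 required")
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 edge_weight_swap = isTRUE(edge_weight_swap)),
            class = "backbone_config")
}

im2col3 <- function(x) im2col3_cpp(x, dim(x)[1], dim(x)[2], dim(x)[3])

col2im3 <- function(dcols, H, W, C) col2im3_cpp(dcols, H, W, C)

meanpool2 <- function(a) {
  H <- dim(a)[1]; W <- dim(a)[2]
  (a[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
   a[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
   a[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
   a[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
}

up2 <- function(a) {
  h <- dim(a)[1]; w <- dim(a)[2]
  a[rep(seq_len(h), each = 2), rep(seq_len(w), each = 2), , drop = FALSE]
}

sum2 <- function(a) meanpool2(a) * 4     # backward of up2
mean_back <- function(g) up2(g) / 4      # backward of meanpool2

conv_fwd <- function(x, W, b) {
  cols <- im2col3(x)
  z <- cols %*% W
  z <- z + rep(b, each = nrow(z))
  list(z = array(z, c(dim(x)[1], dim(x)[2], length(b))), cols = cols)
}

relu <- function(z) { z[z < 0] <- 0; z }
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a dual-head backbone
#'
#' He-initialized weights; reproducible from `seed`.
#'
#' @param config a [backbone_config()].
#' @param seed integer RNG seed.
#' @return object of class `swsal_net`.
#' @export
backbone_init <- function(config = backbone_config(), seed = 1L) {
  set.seed(seed)
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1)
  he <- function(fan_in, n_out) {
    list(W = matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out),
         b = rep(0, n_out))
  }
  p <- list()
  for (l in seq_len(config$depth)) {
    cin <- if (l == 1) 1 else ch[l - 1]
    p[[paste0("enc", l)]] <- he(9 * cin, ch[l])
  }
  for (l in seq_len(config$depth - 1))
    p[[paste0("dec", l)]] <- he(9 * (ch[l + 1] + ch[l]), ch[l])
  p$edge1 <- he(9 * ch[1], ch[1])
  p$edge2 <- he(ch[1], 1)
  p$seg1 <- he(9 * 2 * ch[1], ch[1])
  p$seg2 <- he(ch[1], 1)
  structure(list(config = config, params = p, channels = ch),
            class = "swsal_net")
}

pad_to <- function(img, mult) {
  H <- nrow(img); W <- ncol(img)
  Hp <- ceiling(H / mult) * mult; Wp <- ceiling(W / mult) * mult
  if (Hp == H && Wp == W) return(list(img = img, H = H, W = W))
  out <- matrix(0, Hp, Wp); out[seq_len(H), seq_len(W)] <- img
  list(img = out, H = H, W = W)
}

#' Forward pass of the dual-head backbone
#'
#' @param net a [backbone_init()] network.
#' @param image numeric matrix (intensities, ideally in `[0,1]`).
#' @param want_cache keep intermediate activations for backpropagation.
#' @return list with `seg_prob` and `edge_prob` (matrices of the input size,
#'   values in `[0,1]`) and, if requested, `cache`.
#' @export
net_forward <- function(net, image, want_cache = FALSE) {
  if (!is.matrix(image)) stop_config("image must be a 2D matrix")
  cfg <- net$config; p <- net$params
  mult <- 2^(cfg$depth - 1)
  pd <- pad_to(image, mult)
  x <- array(pd$img, c(dim(pd$img), 1))
  enc_a <- vector("list", cfg$depth)
  enc_cols <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    cv <- conv_fwd(x, p[[paste0("enc", l)]]$W, p[[paste0("enc", l)]]$b)
    enc_a[[l]] <- relu(cv$z); enc_cols[[l]] <- cv$cols
    if (l < cfg$depth) x <- meanpool2(enc_a[[l]])
  }
  d <- enc_a[[cfg$depth]]
  dec_a <- vector("list", cfg$depth - 1)
  dec_cols <- vector("list", cfg$depth - 1)
  for (l in rev(seq_len(cfg$depth - 1))) {
    cat_in <- array(c(up2(d), enc_a[[l]]),
                    c(dim(enc_a[[l]])[1], dim(enc_a[[l]])[2],
                      net$channels[l + 1] + net$channels[l]))
    cv <- conv_fwd(cat_in, p[[paste0("dec", l)]]$W, p[[paste0("dec", l)]]$b)
    dec_a[[l]] <- relu(cv$z); dec_cols[[l]] <- cv$cols
    d <- dec_a[[l]]
  }
  trunk <- d
  ce <- conv_fwd(trunk, p$edge1$W, p$edge1$b)
  fe <- relu(ce$z)
  fe_flat <- matrix(fe, prod(dim(fe)[1:2]), dim(fe)[3])
  edge_logit <- fe_flat %*% p$edge2$W + p$edge2$b
  seg_in <- array(c(trunk, fe), c(dim(trunk)[1], dim(trunk)[2], 2 * net$channels[1]))
  cs <- conv_fwd(seg_in, p$seg1$W, p$seg1$b)
  fs <- relu(cs$z)
  fs_flat <- matrix(fs, prod(dim(fs)[1:2]), dim(fs)[3])
  seg_logit <- fs_flat %*% p$seg2$W + p$seg2$b
  Hp <- dim(trunk)[1]; Wp <- dim(trunk)[2]
  seg_prob <- matrix(sigmoid(seg_logit), Hp, Wp)[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
  edge_prob <- matrix(sigmoid(edge_logit), Hp, Wp)[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
  out <- list(seg_prob = seg_prob, edge_prob = edge_prob)
  if (want_cache)
    out$cache <- list(enc_a = enc_a, enc_cols = enc_cols, dec_a = dec_a,
                      dec_cols = dec_cols, trunk = trunk, fe = fe,
                      fe_flat = fe_flat, seg_in = seg_in, fs = fs,
                      fs_flat = fs_flat, cols_edge1 = ce$cols,
                      cols_seg1 = cs$cols, Hp = Hp, Wp = Wp,
                      H = pd$H, W = pd$W)
  out
}

# Backpropagate gradients of the loss w.r.t. the two logit maps (matrices of
# the original image size). Returns a named list of parameter gradients.
# With edge_frozen = TRUE the edge head acts as a fixed feature extractor: no
# edge-parameter gradients, and no gradient flows through the edge features.
net_backward <- function(net, cache, d_seg_logit, d_edge_logit = NULL,
                         edge_frozen = FALSE) {
  cfg <- net$config; p <- net$params; ch <- net$channels
  Hp <- cache$Hp; Wp <- cache$Wp
  embed <- function(g) {
    out <- matrix(0, Hp, Wp)
    if (!is.null(g)) out[seq_len(cache$H), seq_len(cache$W)] <- g
    out
  }
  g <- list()
  # seg head
  dzs <- as.vector(embed(d_seg_logit))
  g$seg2 <- list(W = crossprod(cache$fs_flat, dzs), b = sum(dzs))
  dfs <- matrix(dzs, ncol = 1) %*% t(p$seg2$W)
  dfs[cache$fs_flat <= 0] <- 0
  g$seg1 <- list(W = crossprod(cache$cols_seg1, dfs), b = colSums(dfs))
  dseg_in <- col2im3(dfs %*% t(p$seg1$W), Hp, Wp, 2 * ch[1])
  dtrunk <- dseg_in[, , seq_len(ch[1]), drop = FALSE]
  dfe_seg <- dseg_in[, , ch[1] + seq_len(ch[1]), drop = FALSE]
  # edge head
  if (!edge_frozen) {
    dze <- as.vector(embed(d_edge_logit))
    g$edge2 <- list(W = crossprod(cache$fe_flat, dze), b = sum(dze))
    dfe <- matrix(dze, ncol = 1) %*% t(p$edge2$W) +
      matrix(dfe_seg, Hp * Wp, ch[1])
    dfe[cache$fe_flat <= 0] <- 0
    g$edge1 <- list(W = crossprod(cache$cols_edge1, dfe), b = colSums(dfe))
    dtrunk <- dtrunk + col2im3(dfe %*% t(p$edge1$W), Hp, Wp, ch[1])
  }
  # decoder
  gd <- dtrunk
  dskip <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth - 1)) {
    act <- cache$dec_a[[l]]
    dz <- matrix(gd, prod(dim(act)[1:2]), dim(act)[3])
    dz[matrix(act, nrow(dz), ncol(dz)) <= 0] <- 0
    g[[paste0("dec", l)]] <- list(W = crossprod(cache$dec_cols[[l]], dz),
                                  b = colSums(dz))
    dcat <- col2im3(dz %*% t(p[[paste0("dec", l)]]$W),
                    dim(act)[1], dim(act)[2], ch[l + 1] + ch[l])
    du <- dcat[, , seq_len(ch[l + 1]), drop = FALSE]
    dskip[[l]] <- dcat[, , ch[l + 1] + seq_len(ch[l]), drop = FALSE]
    gd <- sum2(du)
  }
  # encoder
  ga <- gd  # gradient w.r.t. enc_a[[depth]] (decoder input at the bottom)
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) ga <- ga + dskip[[l]]
    act <- cache$enc_a[[l]]
    dz <- matrix(ga, prod(dim(act)[1:2]), dim(act)[3])
    dz[matrix(act, nrow(dz), ncol(dz)) <= 0] <- 0
    g[[paste0("enc", l)]] <- list(W = crossprod(cache$enc_cols[[l]], dz),
                                  b = colSums(dz))
    if (l > 1) {
      dx <- col2im3(dz %*% t(p[[paste0("enc", l)]]$W),
                    dim(act)[1], dim(act)[2],
                    if (l == 1) 1 else ch[l - 1])
      ga <- mean_back(dx)
    }
  }
  g
}

# loss + parameter gradients for one slice under the configured supervision;
# `weight` scales both (used by the joint schedule)
loss_and_grads <- function(net, image, seg_label, edge_label = NULL,
                           edge_frozen = is.null(edge_label), weight = 1,
                           swap_weights = net$config$edge_weight_swap) {
  fw <- net_forward(net, image, want_cache = TRUE)
  q <- fw$seg_prob; gmask <- seg_label
  N <- length(q)
  qc <- clip01(q)
  l_area <- area_loss(gmask, q)
  D <- sum(gmask) + sum(q) + DICE_EPS
  S <- sum(gmask * q)
  d_dice_dp <- (2 * S + DICE_EPS) / D^2 - 2 * gmask / D
  dz_seg <- (qc - gmask) / N + d_dice_dp * q * (1 - q)
  l_edge <- 0; dz_edge <- NULL
  if (!is.null(edge_label) && !edge_frozen) {
    s <- fw$edge_prob
    l_edge <- weighted_edge_loss(edge_label, s, swap_weights)
    w0 <- sum(edge_label) / N; w1 <- 1 - w0
    if (swap_weights) { tmp <- w0; w0 <- w1; w1 <- tmp }
    dz_edge <- (-w0 * edge_label * (1 - s) + w1 * (1 - edge_label) * s) / N
  }
  grads <- net_backward(net, fw$cache, dz_seg * weight,
                        if (is.null(dz_edge)) NULL else dz_edge * weight,
                        edge_frozen = edge_frozen)
  list(loss = l_area + l_edge, l_area = l_area, l_edge = l_edge,
       grads = grads, weight = weight)
}

adam_init <- function(params) {
  zero <- function(x) { x$W[] <- 0; x$b[] <- 0; x }
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0)
}

scale_grads <- function(g, f) lapply(g, function(x) list(W = x$W * f, b = x$b * f))

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]]
    else a[[nm]] <- list(W = a[[nm]]$W + b[[nm]]$W, b = a[[nm]]$b + b[[nm]]$b)
  }
  a
}

adam_step <- function(net, grads, state, lr = 5e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 1e-4) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (part in c("W", "b")) {
      gr <- grads[[nm]][[part]]
      if (part == "W" && weight_decay > 0)
        gr <- gr + weight_decay * net$params[[nm]][[part]]
      state$m[[nm]][[part]] <- beta1 * state$m[[nm]][[part]] + (1 - beta1) * gr
      state$v[[nm]][[part]] <- beta2 * state$v[[nm]][[part]] + (1 - beta2) * gr^2
      mh <- state$m[[nm]][[part]] / bc1
      vh <- state$v[[nm]][[part]] / bc2
      net$params[[nm]][[part]] <- net$params[[nm]][[part]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(net = net, state = state)
}

#' Predict segmentation and edge probability maps
#'
#' @param object a `swsal_net`.
#' @param newdata a matrix (one slice), a list of matrices, or a volume.
#' @param ... unused.
#' @return for a single slice, a list with `seg_prob`/`edge_prob`; otherwise a
#'   list of such lists.
#' @export
predict.swsal_net <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(net_forward(object, newdata))
  slices <- if (!is.null(newdata$slices)) newdata$slices else newdata
  lapply(slices, function(s) net_forward(object, s))
}

#' @export
print.swsal_net <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("dual-head backbone: depth %d, base channels %d, %d parameters\n",
              x$config$depth, x$config$base_channels, npar))
  invisible(x)
}

# checkpoint save/load (plain-text RDS-free format: parameters as doubles)
#' Save / load a network checkpoint
#'
#' Single-file, versioned plain binary-free checkpoint (dput-based text).
#' @param net a `swsal_net`.
#' @param path file path.
#' @export
save_checkpoint <- function(net, path) {
  obj <- list(version = 1L,
              config = unclass(net$config),
              channels = net$channels,
              params = lapply(net$params, function(p)
                list(W = as.vector(p$W), dimW = dim(p$W), b = p$b)))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  cfg <- backbone_config(obj$config$base_channels, obj$config$depth,
                         obj$config$edge_weight_swap)
  params <- lapply(obj$params, function(p)
    list(W = matrix(p$W, p$dimW[1], p$dimW[2]), b = p$b))
  structure(list(config = cfg, params = params, channels = obj$channels),
            class = "swsal_net")
}
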