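# DA-UNet: a U-Net encoder/decoder with squeeze-and-excitation channel
# weighting, additive attention gates on the skip connections, and a
# deeply supervised multi-scale softmax head.  Disabling all three add-ons
# (and keeping a single supervision level) yields the plain U-Net baseline.

#' Hyperparameters of a DA-UNet instance
#'
#' @param depth Number of encoder/decoder resolution levels (the encoder
#'   pools `depth` times before the bottleneck).
#' @param base_channels Feature channels at the first level; doubled at each
#'   deeper level.
#' @param se_reduction Bottleneck divisor of the squeeze-and-excitation
#'   excitation MLP; must divide the channel count at every SE site.
#' @param num_classes Number of segmentation classes (background + artery
#'   by default).
#' @param supervision_levels Number of decoder levels whose class maps are
#'   upsampled and summed before the final softmax (deep supervision).
#'   `1` means only the full-resolution head is used.
#' @param spatial_dims Spatial dimensionality of one network input.  The
#'   engine is 2-D; volumes are segmented slice-wise (see
#'   [predict_volume()]).
#' @param use_se,use_attention Toggle the squeeze-and-excitation blocks and
#'   the attention gates.  With both `FALSE` and `supervision_levels = 1`
#'   the architecture is the plain U-Net used as comparison baseline.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(depth = 4L, base_channels = 16L, se_reduction = 4L,
                         num_classes = 2L, supervision_levels = depth,
                         spatial_dims = 2L, use_se = TRUE,
                         use_attention = TRUE) {
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  se_reduction <- as.integer(se_reduction)
  num_classes <- as.integer(num_classes)
  supervision_levels <- as.integer(supervision_levels)
  if (depth < 1L) stop("depth must be >= 1")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (supervision_levels < 1L || supervision_levels > depth)
    stop("supervision_levels must lie in [1, depth]")
  if (spatial_dims != 2L)
    stop("only spatial_dims = 2 is implemented; segment volumes slice-wise")
  ch <- base_channels * 2L^(seq_len(depth) - 1L)
  if (use_se && any(ch %% se_reduction != 0L))
    stop("channel count at an SE site is not divisible by se_reduction")
  structure(list(depth = depth, base_channels = base_channels,
                 se_reduction = se_reduction, num_classes = num_classes,
                 supervision_levels = supervision_levels,
                 spatial_dims = 2L, use_se = use_se,
                 use_attention = use_attention),
            class = "network_spec")
}

#' Plain U-Net baseline spec matched to a DA-UNet spec
#'
#' Same depth and channel widths, but without squeeze-and-excitation,
#' attention gates, or deep supervision.
#' @param spec A [network_spec()].
#' @return A `network_spec` for the baseline.
#' @export
unet_baseline_spec <- function(spec) {
  network_spec(depth = spec$depth, base_channels = spec$base_channels,
               se_reduction = spec$se_reduction,
               num_classes = spec$num_classes, supervision_levels = 1L,
               use_se = FALSE, use_attention = FALSE)
}

# Channel width at level i (bottleneck = depth + 1).
spec_channels <- function(spec, i) spec$base_channels * 2L^(i - 1L)

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Construct a DA-UNet with freshly initialised weights
#'
#' Convolution and dense weights use He-style normal initialisation;
#' batch-norm scales start at 1, biases at 0.  Two constructions with the
#' same seed are identical.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `daunet_model` with elements `spec`, `params`
#'   (named list of weight matrices/vectors) and `bn` (running batch-norm
#'   moments).
#' @export
build_daunet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  p <- list()
  bn <- new.env(parent = emptyenv())
  add_bn <- function(name, C) {
    p[[paste0(name, "_g")]] <<- rep(1, C)
    p[[paste0(name, "_b")]] <<- rep(0, C)
    st <- new.env(parent = emptyenv())
    st$rm <- rep(0, C); st$rv <- rep(1, C)
    bn[[name]] <- st
  }
  add_conv_block <- function(tag, cin, cout) {
    # no conv bias: batch norm directly follows and absorbs it
    p[[paste0(tag, "_c1_w")]] <<- he_init(9L * cin, cout, 9L * cin)
    add_bn(paste0(tag, "_bn1"), cout)
    p[[paste0(tag, "_c2_w")]] <<- he_init(9L * cout, cout, 9L * cout)
    add_bn(paste0(tag, "_bn2"), cout)
  }
  d <- spec$depth
  for (i in seq_len(d)) {
    cin <- if (i == 1L) 1L else spec_channels(spec, i - 1L)
    add_conv_block(paste0("enc", i), cin, spec_channels(spec, i))
  }
  add_conv_block("bot", spec_channels(spec, d), spec_channels(spec, d + 1L))
  for (i in rev(seq_len(d))) {
    ci <- spec_channels(spec, i)
    cup <- spec_channels(spec, i + 1L)
    if (spec$use_attention) {
      p[[paste0("att", i, "_wy")]] <- he_init(ci, ci, ci)
      p[[paste0("att", i, "_wg")]] <- he_init(cup, ci, cup)
      p[[paste0("att", i, "_b")]] <- rep(0, ci)
      p[[paste0("att", i, "_psi_w")]] <- he_init(ci, 1L, ci)
      p[[paste0("att", i, "_psi_b")]] <- 0
    }
    add_conv_block(paste0("dec", i), ci + cup, ci)
    if (spec$use_se) {
      cr <- ci %/% spec$se_reduction
      p[[paste0("se", i, "_w1")]] <- he_init(ci, cr, ci)
      p[[paste0("se", i, "_b1")]] <- rep(0, cr)
      p[[paste0("se", i, "_w2")]] <- he_init(cr, ci, cr)
      p[[paste0("se", i, "_b2")]] <- rep(0, ci)
    }
  }
  for (i in seq_len(spec$supervision_levels)) {
    ci <- spec_channels(spec, i)
    p[[paste0("ds", i, "_w")]] <- he_init(ci, spec$num_classes, ci)
    p[[paste0("ds", i, "_b")]] <- rep(0, spec$num_classes)
  }
  structure(list(spec = spec, params = p, bn = bn, seed = seed),
            class = "daunet_model")
}

#' @export
print.daunet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "DA-UNet model: depth %d, base channels %d, %s%s%d supervision level(s), %d parameters\n",
    x$spec$depth, x$spec$base_channels,
    if (x$spec$use_se) "SE, " else "no SE, ",
    if (x$spec$use_attention) "attention, " else "no attention, ",
    x$spec$supervision_levels, np))
  invisible(x)
}

# Forward pass on a batch stored in the (H*W*N) x C row layout.
# `bypass` freezes the SE weighting at 1 and/or the attention coefficient
# at 1 while keeping the parameterisation: used to check block-bypass
# equivalence with the plain U-Net.
daunet_forward <- function(model, x, H, W, N, tape = NULL, training = FALSE,
                           target = NULL, bypass = list()) {
  spec <- model$spec
  d <- spec$depth
  if (H %% 2L^d != 0L || W %% 2L^d != 0L)
    stop(sprintf(
      "input spatial extent %dx%d is not divisible by 2^depth = %d; pad the input first",
      H, W, 2L^d))
  pn <- lapply(model$params, function(v) tp_leaf(tape, v))
  se_on <- spec$use_se && !isTRUE(bypass$se)
  att_on <- spec$use_attention && !isTRUE(bypass$attention)
  conv_block <- function(tag, t, h, w) {
    t <- op_conv3(tape, t, pn[[paste0(tag, "_c1_w")]], NULL, h, w, N)
    t <- op_bn(tape, t, pn[[paste0(tag, "_bn1_g")]],
               pn[[paste0(tag, "_bn1_b")]], model$bn[[paste0(tag, "_bn1")]],
               training)
    t <- op_relu(tape, t)
    t <- op_conv3(tape, t, pn[[paste0(tag, "_c2_w")]], NULL, h, w, N)
    t <- op_bn(tape, t, pn[[paste0(tag, "_bn2_g")]],
               pn[[paste0(tag, "_bn2_b")]], model$bn[[paste0(tag, "_bn2")]],
               training)
    op_relu(tape, t)
  }
  skips <- vector("list", d)
  t <- tp_leaf(tape, x)
  t$stop_grad <- TRUE   # no gradient w.r.t. the image itself
  h <- H; w <- W
  for (i in seq_len(d)) {
    t <- conv_block(paste0("enc", i), t, h, w)
    skips[[i]] <- t
    t <- op_maxpool2(tape, t, h, w, N)
    h <- h %/% 2L; w <- w %/% 2L
  }
  t <- conv_block("bot", t, h, w)
  ds_sum <- NULL
  for (i in rev(seq_len(d))) {
    up <- op_upnearest2(tape, t, h, w, N)
    h <- h * 2L; w <- w * 2L
    y <- skips[[i]]
    if (att_on) {
      ay <- op_conv1(tape, y, pn[[paste0("att", i, "_wy")]])
      ag <- op_conv1(tape, up, pn[[paste0("att", i, "_wg")]],
                     pn[[paste0("att", i, "_b")]])
      s <- op_relu(tape, op_add(tape, ay, ag))
      kap <- op_sigmoid(tape, op_conv1(tape, s, pn[[paste0("att", i, "_psi_w")]],
                                       pn[[paste0("att", i, "_psi_b")]]))
      y <- op_scale_rows(tape, y, kap)
    }
    t <- op_concat(tape, y, up)
    t <- conv_block(paste0("dec", i), t, h, w)
    if (se_on) {
      nidx <- rep(seq_len(N), each = h * w)
      b <- op_squeeze(tape, t, nidx, h * w)
      z <- op_relu(tape, op_dense(tape, b, pn[[paste0("se", i, "_w1")]],
                                  pn[[paste0("se", i, "_b1")]]))
      s <- op_sigmoid(tape, op_dense(tape, z, pn[[paste0("se", i, "_w2")]],
                                     pn[[paste0("se", i, "_b2")]]))
      t <- op_scale_channels(tape, t, s, nidx)
    }
    if (i <= spec$supervision_levels) {
      cls <- op_conv1(tape, t, pn[[paste0("ds", i, "_w")]],
                      pn[[paste0("ds", i, "_b")]])
      if (h < H) cls <- op_upbilinear(tape, cls, h, w, H, W, N)
      ds_sum <- if (is.null(ds_sum)) cls else op_add(tape, ds_sum, cls)
    }
  }
  out <- list(logits = ds_sum, param_nodes = pn)
  if (!is.null(target)) {
    out$loss <- op_softmax_ce(tape, ds_sum, target)
    out$probs <- out$loss$probs
  } else {
    out$probs <- softmax_rows(ds_sum$val)
  }
  out
}

# ---- standalone block operations --------------------------------------

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(list(m = x, H = nrow(x), W = 1L, dims = dim(x)))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  list(m = matrix(x, d[1] * d[2], d[3]), H = d[1], W = d[2], dims = d)
}

#' Squeeze-and-excitation channel weighting
#'
#' Squeezes each channel to its spatial mean, passes the channel descriptor
#' through a two-layer bottleneck MLP (ReLU then sigmoid), and rescales
#' every channel of the input by its excitation weight in (0, 1).
#'
#' @param x A feature map: `H x W x C` array.
#' @param reduction Bottleneck divisor of the excitation MLP; must divide
#'   `C` when `weights` are auto-initialised.
#' @param weights Optional list with `w1` (`C x C/r`), `b1`, `w2`
#'   (`C/r x C`), `b2`.  When `NULL`, He-initialised from `seed`.
#' @param seed Seed for auto-initialised weights.
#' @return The rescaled feature map, same shape as `x`, with the per-channel
#'   excitation weights attached as attribute `"excitation"`.
#' @export
se_block <- function(x, reduction = 4L, weights = NULL, seed = 1L) {
  fm <- as_feature_matrix(x)
  C <- ncol(fm$m)
  if (is.null(weights)) {
    if (C %% reduction != 0L)
      stop("channel count is not divisible by the SE reduction")
    cr <- C %/% reduction
    set.seed(seed)
    weights <- list(w1 = he_init(C, cr, C), b1 = rep(0, cr),
                    w2 = he_init(cr, C, cr), b2 = rep(0, C))
  }
  b <- colMeans(fm$m)                                   # squeeze
  z <- pmax(drop(b %*% weights$w1) + weights$b1, 0)     # excite: FC + ReLU
  s <- 1 / (1 + exp(-(drop(z %*% weights$w2) + weights$b2)))  # FC + sigmoid
  y <- fm$m * rep(s, each = nrow(fm$m))                 # re-weight channels
  out <- array(y, fm$dims)
  attr(out, "excitation") <- s
  out
}

#' Additive attention gate
#'
#' Projects the encoder skip features `y` and the gating features `g` to a
#' common channel width with 1x1 convolutions, adds them, applies ReLU, and
#' collapses to a single attention coefficient map `kappa` in (0, 1) via a
#' 1x1 convolution and sigmoid.  The gated output is `kappa * y`, broadcast
#' over channels.
#'
#' @param y Skip feature map, `H x W x Cy` array.
#' @param g Gating feature map at the same spatial resolution,
#'   `H x W x Cg` array (upsample beforehand if coarser).
#' @param weights Optional list with `wy` (`Cy x Ci`), `wg` (`Cg x Ci`),
#'   `b` (length `Ci`), `psi_w` (`Ci x 1`), `psi_b` (scalar).  When `NULL`,
#'   He-initialised with `Ci = Cy` from `seed`.
#' @param seed Seed for auto-initialised weights.
#' @return The gated feature map (same shape as `y`) with the coefficient
#'   map attached as attribute `"kappa"` (`H x W` matrix).
#' @export
attention_gate <- function(y, g, weights = NULL, seed = 1L) {
  fy <- as_feature_matrix(y)
  fg <- as_feature_matrix(g)
  if (fy$H != fg$H || fy$W != fg$W)
    stop("y and g must share spatial shape; upsample g first")
  if (is.null(weights)) {
    set.seed(seed)
    ci <- ncol(fy$m)
    weights <- list(wy = he_init(ncol(fy$m), ci, ncol(fy$m)),
                    wg = he_init(ncol(fg$m), ci, ncol(fg$m)),
                    b = rep(0, ci), psi_w = he_init(ci, 1L, ci), psi_b = 0)
  }
  s <- fy$m %*% weights$wy + fg$m %*% weights$wg +
    rep(weights$b, each = nrow(fy$m))
  s <- pmax(s, 0)
  kappa <- 1 / (1 + exp(-(drop(s %*% weights$psi_w) + weights$psi_b)))
  out <- array(fy$m * kappa, fy$dims)
  attr(out, "kappa") <- matrix(kappa, fy$H, fy$W)
  out
}

#' Deep supervision head
#'
#' Sums per-level class maps after upsampling each coarser map to full
#' resolution with bilinear interpolation, then normalises with a softmax
#' over classes.  Level `i` is expected at `1/2^(i-1)` of full resolution.
#'
#' @param class_maps List of `H_i x W_i x K` arrays, finest first.
#' @return An `H x W x K` array of class probabilities summing to 1 at
#'   every position.
#' @export
deep_supervision_head <- function(class_maps) {
  stopifnot(length(class_maps) >= 1L)
  d1 <- dim(class_maps[[1]])
  K <- d1[3]
  H <- d1[1]; W <- d1[2]
  acc <- matrix(0, H * W, K)
  for (i in seq_along(class_maps)) {
    di <- dim(class_maps[[i]])
    if (length(di) != 3L || di[3] != K)
      stop("every class map must have num_classes channels")
    expect <- c(H %/% 2L^(i - 1L), W %/% 2L^(i - 1L))
    if (!all(di[1:2] == expect))
      stop(sprintf("class map %d has resolution %dx%d, expected %dx%d",
                   i, di[1], di[2], expect[1], expect[2]))
    m <- matrix(class_maps[[i]], di[1] * di[2], K)
    if (di[1] < H) {
      U <- bilinear_mat(di[1], di[2], H, W, 1L)
      m <- as.matrix(U %*% m)
    }
    acc <- acc + m
  }
  array(softmax_rows(acc), c(H, W, K))
}

#' Classification cross-entropy loss
#'
#' Mean over voxels of the negative log predicted probability of the gold
#' class.  Probabilities are clamped at `1e-7` before the logarithm.
#'
#' @param probs Class probabilities: `... x K` array whose last dimension
#'   indexes classes, or an `M x K` matrix.
#' @param gold Integer gold labels in `0..K-1`, matching the leading
#'   dimensions of `probs`.
#' @return Non-negative scalar; 0 exactly when the prediction is one-hot
#'   correct everywhere.
#' @export
cel_loss <- function(probs, gold) {
  d <- dim(probs)
  K <- d[length(d)]
  p <- matrix(probs, ncol = K)
  g <- as.integer(as.vector(gold))
  if (length(g) != nrow(p))
    stop("gold labels do not match the probability map's voxel count")
  if (any(g < 0L | g >= K)) stop("gold labels must lie in [0, num_classes)")
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), g + 1L)], 1e-7)))
}
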