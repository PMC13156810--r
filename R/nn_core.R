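# Self-contained U-Net engine.
#
# All feature maps are 4D arrays (X, Y, Z, C); 2D networks use Z = 1 with
# 3x3x1 kernels. Convolutions run through the compiled kernels; instance
# normalization, activations, pooling and the optimizer are vectorized R.
# Forward passes cache what the hand-written backward pass needs.

lrelu_alpha <- 0.01

conv_pad <- function(k) as.integer(ifelse(k > 1, (k - 1) %/% 2, 0))

init_conv <- function(k, cin, cout) {
  fan_in <- prod(k) * cin
  w <- array(stats::rnorm(prod(k) * cin * cout, 0, sqrt(2 / fan_in)),
             c(k, cin, cout))
  list(w = w, b = numeric(cout))
}

conv_fwd_l <- function(x, p, stride) {
  k <- dim(p$w)[1:3]
  y <- .conv_fwd(x, p$w, p$b, as.integer(stride), conv_pad(k))
  list(y = y, x = x, stride = as.integer(stride))
}

conv_bwd_l <- function(cache, p, gy) {
  k <- dim(p$w)[1:3]
  gx <- .conv_bwd_x(gy, p$w, cache$stride, conv_pad(k), dim(cache$x)[1:3])
  gwb <- .conv_bwd_w(cache$x, gy, as.integer(k), cache$stride, conv_pad(k))
  list(gx = gx, gw = gwb$gw, gb = gwb$gb)
}

# transposed convolution, kernel k = stride (non-overlapping upsample);
# weights dim (k, k, k, c_out, c_in)
tconv_fwd_l <- function(x, p, factor) {
  k <- dim(p$w)[1:3]
  out_sp <- dim(x)[1:3] * as.integer(factor)
  y <- .conv_bwd_x(x, p$w, as.integer(factor), c(0L, 0L, 0L), out_sp)
  cout <- dim(p$w)[4]
  y <- y + rep(p$b, each = prod(out_sp))
  list(y = y, x = x, factor = as.integer(factor))
}

tconv_bwd_l <- function(cache, p, gy) {
  k <- dim(p$w)[1:3]
  zb <- numeric(dim(p$w)[5])
  gx <- .conv_fwd(gy, p$w, zb, cache$factor, c(0L, 0L, 0L))
  gwb <- .conv_bwd_w(gy, cache$x, as.integer(k), cache$factor, c(0L, 0L, 0L))
  gb <- colSums(matrix(gy, ncol = dim(gy)[4]))
  list(gx = gx, gw = gwb$gw, gb = gb)
}

in_fwd_l <- function(x, p, eps = 1e-5) {
  d <- dim(x); s <- prod(d[1:3]); cc <- d[4]
  xm <- matrix(x, s, cc)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = s)) * rep(istd, each = s)
  y <- xhat * rep(p$g, each = s) + rep(p$b, each = s)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, d = d)
}

in_bwd_l <- function(cache, p, gy) {
  d <- cache$d; s <- prod(d[1:3]); cc <- d[4]
  gym <- matrix(gy, s, cc)
  gb <- colSums(gym)
  gg <- colSums(gym * cache$xhat)
  dxhat <- gym * rep(p$g, each = s)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  gx <- (dxhat - rep(m1, each = s) - cache$xhat * rep(m2, each = s)) *
        rep(cache$istd, each = s)
  dim(gx) <- d
  list(gx = gx, gg = gg, gb = gb)
}

lrelu_fwd <- function(x) {
  neg <- x < 0
  x[neg] <- x[neg] * lrelu_alpha
  list(y = x, neg = neg)
}

lrelu_bwd <- function(cache, gy) {
  gy[cache$neg] <- gy[cache$neg] * lrelu_alpha
  gy
}

avgpool_fwd <- function(x, f) {
  d <- dim(x)
  od <- c(d[1:3] %/% pmax(f, 1L), d[4])
  offs <- expand.grid(lapply(f, function(fi) 0:(fi - 1)))
  y <- array(0, od)
  for (r in seq_len(nrow(offs))) {
    y <- y + x[seq(1 + offs[r, 1], by = f[1], length.out = od[1]),
               seq(1 + offs[r, 2], by = f[2], length.out = od[2]),
               seq(1 + offs[r, 3], by = f[3], length.out = od[3]), , drop = FALSE]
  }
  list(y = y / nrow(offs), d = d, f = f)
}

avgpool_bwd <- function(cache, gy) {
  f <- cache$f; d <- cache$d
  od <- dim(gy)
  gx <- array(0, d)
  offs <- expand.grid(lapply(f, function(fi) 0:(fi - 1)))
  g <- gy / nrow(offs)
  for (r in seq_len(nrow(offs))) {
    gx[seq(1 + offs[r, 1], by = f[1], length.out = od[1]),
       seq(1 + offs[r, 2], by = f[2], length.out = od[2]),
       seq(1 + offs[r, 3], by = f[3], length.out = od[3]), ] <- g
  }
  gx
}

unet_channels <- function(cfg) {
  pmin(cfg$base_channels * 2^(seq_len(cfg$encoder_stages) - 1), cfg$max_channels)
}

#' Per-stage spatial sizes of a U-Net
#'
#' Pure bookkeeping: the encoder halves the spatial size at every stage after
#' the first, so stage \code{i} sees \code{input_shape / 2^(i-1)} and the
#' deepest feature map is \code{input_shape / 2^(encoder_stages - 1)}. Inputs
#' must be padded to divisibility by that factor (see [pad_to_divisible()]).
#'
#' @param cfg a network config from [unet2d_config()] or [unet3d_config()].
#' @param input_shape spatial input shape (length 2 for 2D, 3 for 3D).
#' @return matrix of per-stage spatial shapes (rows = stages).
#' @export
unet_shapes <- function(cfg, input_shape) {
  E <- cfg$encoder_stages
  sh <- matrix(0L, E, length(input_shape))
  cur <- as.integer(input_shape)
  for (i in seq_len(E)) {
    sh[i, ] <- cur
    if (i < E) cur <- cur %/% 2L
  }
  rownames(sh) <- paste0("stage", seq_len(E))
  sh
}

#' 2D localization network configuration
#'
#' A 2D U-Net over cross-sectional slices: an encoder of
#' \code{encoder_stages} stages and a decoder of \code{encoder_stages - 1}
#' stages, two convolutions (each with instance normalization and leaky-ReLU
#' activation) per stage, strided-convolution downsampling,
#' transposed-convolution upsampling and encoder-decoder skip connections.
#' One input channel, one sigmoid foreground-probability output.
#'
#' @param encoder_stages encoder depth (default 8; the decoder has one fewer).
#' @param base_channels channels of the first stage (doubling per stage).
#' @param max_channels channel cap.
#' @param deep_supervision attach auxiliary heads at every decoder resolution.
#' @return config list of class \code{unet_config}.
#' @export
unet2d_config <- function(encoder_stages = 8L, base_channels = 32L,
                          max_channels = 320L, deep_supervision = TRUE) {
  structure(list(dim = 2L, encoder_stages = as.integer(encoder_stages),
                 decoder_stages = as.integer(encoder_stages) - 1L,
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 blocks_per_stage = 1L, residual = FALSE,
                 avgpool_stages = integer(0),
                 deep_supervision = isTRUE(deep_supervision)),
            class = "unet_config")
}

#' 3D segmentation network configuration
#'
#' A 3D U-Net with a residual encoder: each block is two convolutions (with
#' instance normalization and leaky-ReLU) plus an identity shortcut (a 1x1x1
#' projection when channels or resolution change). Stages listed in
#' \code{avgpool_stages} downsample by average pooling in their first block;
#' the remaining stages use strided convolution.
#'
#' @param encoder_stages encoder depth (default 6; decoder has one fewer).
#' @param base_channels,max_channels channel schedule as in [unet2d_config()].
#' @param blocks_per_stage residual blocks per encoder stage (default 2).
#' @param avgpool_stages encoder stages that downsample by average pooling.
#' @param deep_supervision attach auxiliary heads at every decoder resolution.
#' @return config list of class \code{unet_config}.
#' @export
unet3d_config <- function(encoder_stages = 6L, base_channels = 32L,
                          max_channels = 320L, blocks_per_stage = 2L,
                          avgpool_stages = c(2L, 3L), deep_supervision = TRUE) {
  structure(list(dim = 3L, encoder_stages = as.integer(encoder_stages),
                 decoder_stages = as.integer(encoder_stages) - 1L,
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 residual = TRUE,
                 avgpool_stages = as.integer(avgpool_stages),
                 deep_supervision = isTRUE(deep_supervision)),
            class = "unet_config")
}

# kernel/stride triples honoring the 2D (Z = 1) degenerate case
net_k3 <- function(cfg) if (cfg$dim == 2L) c(3L, 3L, 1L) else c(3L, 3L, 3L)
net_k1 <- function(cfg) c(1L, 1L, 1L)
net_s2 <- function(cfg) if (cfg$dim == 2L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
net_s1 <- function(cfg) c(1L, 1L, 1L)

#' Build a U-Net model with seeded initialization
#'
#' Weights use He initialization; two builds from the same config and seed
#' are identical.
#'
#' @param cfg a [unet2d_config()] or [unet3d_config()].
#' @param seed integer seed for the weight draw.
#' @return model list of class \code{unet_model} (config plus parameters).
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- unet_channels(cfg)
  E <- cfg$encoder_stages
  k3 <- net_k3(cfg); k1 <- net_k1(cfg)
  params <- with_seed(seed, {
    enc <- vector("list", E)
    for (i in seq_len(E)) {
      blocks <- vector("list", cfg$blocks_per_stage)
      for (b in seq_len(cfg$blocks_per_stage)) {
        cin <- if (b > 1) ch[i] else if (i == 1) 1L else ch[i - 1]
        blk <- list(conv1 = init_conv(k3, cin, ch[i]),
                    in1 = list(g = rep(1, ch[i]), b = rep(0, ch[i])),
                    conv2 = init_conv(k3, ch[i], ch[i]),
                    in2 = list(g = rep(1, ch[i]), b = rep(0, ch[i])))
        if (cfg$residual && (cin != ch[i] || (b == 1 && i > 1)))
          blk$short <- init_conv(k1, cin, ch[i])
        blocks[[b]] <- blk
      }
      enc[[i]] <- blocks
    }
    dec <- vector("list", E - 1)
    for (j in seq_len(E - 1)) {
      s <- E - j
      cur <- if (j == 1) ch[E] else ch[s + 1]
      up <- init_conv(if (cfg$dim == 2L) c(2L, 2L, 1L) else c(2L, 2L, 2L),
                      ch[s], cur)  # weights stored (k, c_out, c_in) for tconv
      up$b <- numeric(ch[s])       # bias lives on the upsampled output channels
      dec[[j]] <- list(
        up = up,
        conv1 = init_conv(k3, 2L * ch[s], ch[s]),
        in1 = list(g = rep(1, ch[s]), b = rep(0, ch[s])),
        conv2 = init_conv(k3, ch[s], ch[s]),
        in2 = list(g = rep(1, ch[s]), b = rep(0, ch[s])),
        head = init_conv(k1, ch[s], 1L))
    }
    list(enc = enc, dec = dec)
  })
  structure(list(cfg = cfg, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$cfg
  cat("<unet_model> ", cfg$dim, "D, ", cfg$encoder_stages, "/",
      cfg$decoder_stages, " stages, channels ",
      paste(unet_channels(cfg), collapse = "-"),
      ", ", format(n_params(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a \code{unet_model}.
#' @return integer count.
#' @export
n_params <- function(model) {
  cnt <- 0
  walk <- function(x) {
    if (is.numeric(x)) cnt <<- cnt + length(x)
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(model$params)
  cnt
}

unet_forward <- function(model, x, train = TRUE) {
  cfg <- model$cfg; P <- model$params
  E <- cfg$encoder_stages
  cache <- list(enc = vector("list", E), dec = vector("list", E - 1))
  skips <- vector("list", E)
  cur <- x
  for (i in seq_len(E)) {
    bl <- vector("list", cfg$blocks_per_stage)
    for (b in seq_len(cfg$blocks_per_stage)) {
      blk <- P$enc[[i]][[b]]
      down <- (i > 1 && b == 1)
      pool <- down && (i %in% cfg$avgpool_stages)
      stride <- if (down && !pool) net_s2(cfg) else net_s1(cfg)
      c_ <- list(pool = NULL, down = down)
      if (pool) { ap <- avgpool_fwd(cur, net_s2(cfg)); c_$pool <- ap; cur <- ap$y }
      xin <- cur
      c1 <- conv_fwd_l(xin, blk$conv1, stride)
      n1 <- in_fwd_l(c1$y, blk$in1)
      a1 <- lrelu_fwd(n1$y)
      c2 <- conv_fwd_l(a1$y, blk$conv2, net_s1(cfg))
      n2 <- in_fwd_l(c2$y, blk$in2)
      h <- n2$y
      c_$c1 <- c1; c_$n1 <- n1; c_$a1neg <- a1$neg; c_$c2 <- c2; c_$n2 <- n2
      if (cfg$residual) {
        if (!is.null(blk$short)) {
          cs <- conv_fwd_l(xin, blk$short, stride)
          c_$cs <- cs
          h <- h + cs$y
        } else h <- h + xin
      }
      a2 <- lrelu_fwd(h)
      c_$a2neg <- a2$neg
      cur <- a2$y
      bl[[b]] <- c_
    }
    cache$enc[[i]] <- bl
    skips[[i]] <- cur
  }
  logits <- vector("list", E - 1)
  for (j in seq_len(E - 1)) {
    s <- E - j
    d <- P$dec[[j]]
    up <- tconv_fwd_l(cur, d$up, net_s2(cfg))
    sk <- skips[[s]]
    cat_ <- array(c(up$y, sk), c(dim(up$y)[1:3], dim(up$y)[4] + dim(sk)[4]))
    c1 <- conv_fwd_l(cat_, d$conv1, net_s1(cfg))
    n1 <- in_fwd_l(c1$y, d$in1)
    a1 <- lrelu_fwd(n1$y)
    c2 <- conv_fwd_l(a1$y, d$conv2, net_s1(cfg))
    n2 <- in_fwd_l(c2$y, d$in2)
    a2 <- lrelu_fwd(n2$y)
    cur <- a2$y
    hd <- conv_fwd_l(cur, d$head, net_s1(cfg))
    logits[[j]] <- hd$y
    cache$dec[[j]] <- list(up = up, c1 = c1, n1 = n1, a1neg = a1$neg,
                           c2 = c2, n2 = n2, a2neg = a2$neg, hd = hd,
                           nup = dim(up$y)[4])
  }
  list(logits = logits, cache = if (train) cache else NULL)
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# backward pass; dlogits = list of gradients w.r.t. each decoder head's
# logits (NULL entries allowed). Returns gradients shaped like params.
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg; P <- model$params
  E <- cfg$encoder_stages
  G <- zero_like(P)
  dskip <- vector("list", E)
  dcur <- NULL
  for (j in rev(seq_len(E - 1))) {
    s <- E - j
    d <- P$dec[[j]]; cc <- cache$dec[[j]]
    dout <- if (is.null(dcur)) 0 else dcur
    if (!is.null(dlogits[[j]])) {
      hb <- conv_bwd_l(cc$hd, d$head, dlogits[[j]])
      G$dec[[j]]$head$w <- G$dec[[j]]$head$w + hb$gw
      G$dec[[j]]$head$b <- G$dec[[j]]$head$b + hb$gb
      dout <- dout + hb$gx
    }
    dout <- lrelu_bwd(list(neg = cc$a2neg), dout)
    nb2 <- in_bwd_l(cc$n2, d$in2, dout)
    G$dec[[j]]$in2$g <- G$dec[[j]]$in2$g + nb2$gg
    G$dec[[j]]$in2$b <- G$dec[[j]]$in2$b + nb2$gb
    cb2 <- conv_bwd_l(cc$c2, d$conv2, nb2$gx)
    G$dec[[j]]$conv2$w <- G$dec[[j]]$conv2$w + cb2$gw
    G$dec[[j]]$conv2$b <- G$dec[[j]]$conv2$b + cb2$gb
    da1 <- lrelu_bwd(list(neg = cc$a1neg), cb2$gx)
    nb1 <- in_bwd_l(cc$n1, d$in1, da1)
    G$dec[[j]]$in1$g <- G$dec[[j]]$in1$g + nb1$gg
    G$dec[[j]]$in1$b <- G$dec[[j]]$in1$b + nb1$gb
    cb1 <- conv_bwd_l(cc$c1, d$conv1, nb1$gx)
    G$dec[[j]]$conv1$w <- G$dec[[j]]$conv1$w + cb1$gw
    G$dec[[j]]$conv1$b <- G$dec[[j]]$conv1$b + cb1$gb
    nup <- cc$nup
    dcat <- cb1$gx
    dup <- dcat[, , , seq_len(nup), drop = FALSE]
    dsk <- dcat[, , , nup + seq_len(dim(dcat)[4] - nup), drop = FALSE]
    dskip[[s]] <- if (is.null(dskip[[s]])) dsk else dskip[[s]] + dsk
    ub <- tconv_bwd_l(cc$up, d$up, dup)
    G$dec[[j]]$up$w <- G$dec[[j]]$up$w + ub$gw
    G$dec[[j]]$up$b <- G$dec[[j]]$up$b + ub$gb
    dcur <- ub$gx
  }
  # encoder, deepest stage first; dcur currently holds grad at encoder output
  for (i in rev(seq_len(E))) {
    dstage <- dcur
    if (!is.null(dskip[[i]])) dstage <- if (is.null(dstage)) dskip[[i]] else dstage + dskip[[i]]
    for (b in rev(seq_len(cfg$blocks_per_stage))) {
      blk <- P$enc[[i]][[b]]; cc <- cache$enc[[i]][[b]]
      dh <- lrelu_bwd(list(neg = cc$a2neg), dstage)
      dxin <- NULL
      if (cfg$residual) {
        if (!is.null(blk$short)) {
          sb <- conv_bwd_l(cc$cs, blk$short, dh)
          G$enc[[i]][[b]]$short$w <- G$enc[[i]][[b]]$short$w + sb$gw
          G$enc[[i]][[b]]$short$b <- G$enc[[i]][[b]]$short$b + sb$gb
          dxin <- sb$gx
        } else dxin <- dh
      }
      nb2 <- in_bwd_l(cc$n2, blk$in2, dh)
      G$enc[[i]][[b]]$in2$g <- G$enc[[i]][[b]]$in2$g + nb2$gg
      G$enc[[i]][[b]]$in2$b <- G$enc[[i]][[b]]$in2$b + nb2$gb
      cb2 <- conv_bwd_l(cc$c2, blk$conv2, nb2$gx)
      G$enc[[i]][[b]]$conv2$w <- G$enc[[i]][[b]]$conv2$w + cb2$gw
      G$enc[[i]][[b]]$conv2$b <- G$enc[[i]][[b]]$conv2$b + cb2$gb
      da1 <- lrelu_bwd(list(neg = cc$a1neg), cb2$gx)
      nb1 <- in_bwd_l(cc$n1, blk$in1, da1)
      G$enc[[i]][[b]]$in1$g <- G$enc[[i]][[b]]$in1$g + nb1$gg
      G$enc[[i]][[b]]$in1$b <- G$enc[[i]][[b]]$in1$b + nb1$gb
      cb1 <- conv_bwd_l(cc$c1, blk$conv1, nb1$gx)
      G$enc[[i]][[b]]$conv1$w <- G$enc[[i]][[b]]$conv1$w + cb1$gw
      G$enc[[i]][[b]]$conv1$b <- G$enc[[i]][[b]]$conv1$b + cb1$gb
      dstage <- cb1$gx
      if (!is.null(dxin)) dstage <- dstage + dxin
      if (!is.null(cc$pool)) dstage <- avgpool_bwd(cc$pool, dstage)
    }
    dcur <- dstage
  }
  G
}

#' Combined binary cross-entropy + Dice loss
#'
#' \code{loss = w_bce * BCE(p, t) + w_dice * (1 - softDice(p, t))} with
#' probabilities clamped away from 0/1. The default 1:1 weighting balances
#' the voxel-wise and overlap-wise terms.
#'
#' @param pred array of foreground probabilities in (0, 1).
#' @param target binary array of the same shape.
#' @param weights named weights \code{c(bce =, dice =)}, both positive.
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, weights = c(bce = 1, dice = 1)) {
  if (!identical(dim(pred), dim(target)) &&
      !(is.null(dim(pred)) && length(pred) == length(target)))
    stop("shape mismatch between pred and target")
  if (any(weights <= 0)) stop("loss weights must be positive")
  eps <- 1e-7
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  t <- as.numeric(target)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  sdice <- (2 * sum(p * t) + 1e-5) / (sum(p) + sum(t) + 1e-5)
  unname(weights["bce"] * bce + weights["dice"] * (1 - sdice))
}

# loss and gradient w.r.t. logits for one head
loss_grad_logits <- function(z, t, weights = c(bce = 1, dice = 1)) {
  p <- 1 / (1 + exp(-z))
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(p)
  bce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  sp <- sum(p); st <- sum(t); spt <- sum(p * t)
  denom <- sp + st + 1e-5
  sdice <- (2 * spt + 1e-5) / denom
  loss <- weights["bce"] * bce + weights["dice"] * (1 - sdice)
  dp_dice <- -(2 * t * denom - (2 * spt + 1e-5)) / denom^2
  dz <- weights["bce"] * (p - t) / n + weights["dice"] * dp_dice * p * (1 - p)
  dim(dz) <- dim(z)
  list(loss = unname(loss), dz = dz)
}

# nearest-neighbor downsample of a (binary) 4D target by integer factors
downsample_target <- function(t, f) {
  d <- dim(t)
  t[seq(1, d[1], by = f[1]), seq(1, d[2], by = f[2]),
    seq(1, d[3], by = f[3]), , drop = FALSE]
}

# deep-supervision head weights: halve with depth, normalized to sum 1;
# index j = decoder stage (1 = deepest, E-1 = full resolution)
ds_weights <- function(n_heads, deep_supervision = TRUE) {
  if (!deep_supervision) {
    w <- c(rep(0, n_heads - 1), 1)
  } else {
    w <- 2^(seq_len(n_heads) - n_heads)  # deepest smallest
  }
  w / sum(w)
}

# loss + parameter gradients for one sample (x, t are 4D arrays)
unet_loss_grads <- function(model, x, t, weights = c(bce = 1, dice = 1)) {
  fw <- unet_forward(model, x, train = TRUE)
  nh <- length(fw$logits)
  hw <- ds_weights(nh, model$cfg$deep_supervision)
  dlog <- vector("list", nh)
  total <- 0
  for (j in seq_len(nh)) {
    if (hw[j] == 0) next
    f <- dim(t)[1:3] %/% dim(fw$logits[[j]])[1:3]
    tj <- if (all(f == 1L)) t else downsample_target(t, f)
    lg <- loss_grad_logits(fw$logits[[j]], tj, weights)
    total <- total + hw[j] * lg$loss
    dlog[[j]] <- hw[j] * lg$dz
  }
  grads <- unet_backward(model, fw$cache, dlog)
  list(loss = total, grads = grads)
}

# elementwise combine two parameter-shaped lists
map2_params <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (k in seq_along(a)) if (!is.null(a[[k]])) out[[k]] <- map2_params(a[[k]], b[[k]], f)
  out
}

#' Predict foreground probabilities with a U-Net
#'
#' Pads the input to the divisibility the encoder requires, runs the network
#' fully convolutionally and returns the sigmoid probability map at input
#' resolution (padding removed).
#'
#' @param model a \code{unet_model}.
#' @param x numeric array: (H, W) for 2D models, (X, Y, Z) for 3D.
#' @return probability array shaped like \code{x}.
#' @export
unet_predict <- function(model, x) {
  cfg <- model$cfg
  orig <- dim(x)
  if (cfg$dim == 2L) {
    stopifnot(length(orig) == 2)
    x4 <- array(x, c(orig, 1L, 1L))
  } else {
    stopifnot(length(orig) == 3)
    x4 <- array(x, c(orig, 1L))
  }
  div <- 2L^(cfg$encoder_stages - 1L)
  divs <- if (cfg$dim == 2L) c(div, div, 1L) else rep(div, 3L)
  pad <- (divs - dim(x4)[1:3] %% divs) %% divs
  if (any(pad > 0)) {
    nd <- dim(x4)[1:3] + pad
    xp <- array(0, c(nd, 1L))
    xp[seq_len(dim(x4)[1]), seq_len(dim(x4)[2]), seq_len(dim(x4)[3]), ] <- x4
    x4 <- xp
  }
  fw <- unet_forward(model, x4, train = FALSE)
  z <- fw$logits[[length(fw$logits)]]
  p <- 1 / (1 + exp(-z))
  p <- p[seq_len(orig[1]), seq_len(if (length(orig) > 1) orig[2] else 1),
         seq_len(if (length(orig) > 2) orig[3] else 1), 1, drop = FALSE]
  array(p, orig)
}

# one SGD-Nesterov step over an accumulated gradient; state carries momentum
sgd_nesterov_step <- function(params, grads, state, lr, momentum = 0.99) {
  if (is.null(state)) state <- zero_like(params)
  state <- map2_params(state, grads, function(v, g) momentum * v + g)
  params <- map2_params(params,
                        map2_params(grads, state, function(g, v) g + momentum * v),
                        function(w, d) w - lr * d)
  list(params = params, state = state)
}
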