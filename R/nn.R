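# Nested residual U-block network (U2-Net style) for image-domain AC/SC,
# implemented from first principles: explicit forward caches and hand-derived
# backward passes over the conv / pool / bilinear-resize kernels in src/.
#
# A network is described by a config (see u2net_config()), its parameters by a
# flat named list of conv blocks {w: (kh*kw*cin) x cout matrix, b: cout vector}
# plus per-block metadata held in the config's schema. Parameters round-trip
# losslessly through flatten_params()/unflatten_params(), which is what the
# federated engine exchanges.
#
# Mini-batches are carried through the whole graph as cubes with B*C slices
# (sample-major), so each conv layer costs one GEMM per batch rather than one
# per sample.

# ---- RSU block configuration -------------------------------------------------

#' Residual U-block configuration
#'
#' An RSU block is a small symmetric encoder-decoder ("U") whose output is
#' added to a skip projection of its input, giving intra-stage multi-scale
#' features. `depth` counts the encoder levels inside the block; `depth = 1`
#' degenerates to a residual double convolution with no resampling. With
#' `dilated = TRUE` the block keeps full resolution and widens its receptive
#' field with dilated convolutions instead of pooling (used at the coarsest
#' stages where further downsampling is pointless).
#'
#' @param depth integer >= 1, number of encoder levels inside the block.
#' @param in_channels,mid_channels,out_channels positive integers.
#' @param dilated logical; dilation instead of down/upsampling.
#' @return an `rsu_config` list.
#' @export
rsu_config <- function(depth, in_channels, mid_channels, out_channels,
                       dilated = FALSE) {
  stopifnot(depth >= 1, in_channels >= 1, mid_channels >= 1, out_channels >= 1)
  structure(list(depth = as.integer(depth), cin = as.integer(in_channels),
                 mid = as.integer(mid_channels), cout = as.integer(out_channels),
                 dilated = isTRUE(dilated)),
            class = "rsu_config")
}

# Layer schema for one RSU block: named conv descriptors (kh, kw, cin, cout, dil).
rsu_schema <- function(cfg, pre) {
  conv <- function(nm, cin, cout, k = 3L, dil = 1L)
    setNames(list(list(kh = k, kw = k, cin = cin, cout = cout, dil = dil)),
             paste0(pre, nm))
  sc <- list()
  if (cfg$depth == 1L) {
    sc <- c(sc, conv("stem", cfg$cin, cfg$mid), conv("dec1", cfg$mid, cfg$cout))
  } else {
    sc <- c(sc, conv("stem", cfg$cin, cfg$cout), conv("enc1", cfg$cout, cfg$mid))
    for (i in 2:cfg$depth) {
      dil <- if (cfg$dilated) 2L^(i - 1L) else 1L
      sc <- c(sc, conv(paste0("enc", i), cfg$mid, cfg$mid, dil = dil))
    }
    sc <- c(sc, conv("bot", cfg$mid, cfg$mid,
                     dil = if (cfg$dilated) 2L^cfg$depth else 2L))
    for (i in cfg$depth:2) {
      dil <- if (cfg$dilated) 2L^(i - 1L) else 1L
      sc <- c(sc, conv(paste0("dec", i), 2L * cfg$mid, cfg$mid, dil = dil))
    }
    sc <- c(sc, conv("dec1", 2L * cfg$mid, cfg$cout))
  }
  if (cfg$cin != cfg$cout)
    sc <- c(sc, conv("skip", cfg$cin, cfg$cout, k = 1L))
  sc
}

# ---- conv + ReLU primitive ---------------------------------------------------

cr_fwd <- function(x, p, th, nb, relu = TRUE) {
  cpp_conv2d_fwd(x, th$w, th$b, p$kh, p$kw, p$dil, nb, relu)
}

# Returns list(dx, dw, db); `y` is the post-ReLU output from the forward pass,
# used to mask the upstream gradient.
cr_bwd <- function(x, y, p, th, dy, nb, relu = TRUE) {
  cpp_conv2d_bwd(x, th$w, dy, p$kh, p$kw, p$dil, nb,
                 if (relu) y else NULL)
}

# Per-sample channel range from a sample-major batched cube.
ch_range <- function(x, from, len, nb) {
  C <- dim(x)[3] %/% nb
  idx <- as.vector(outer(from:(from + len - 1L), (seq_len(nb) - 1L) * C, "+"))
  array(x[, , idx, drop = FALSE], c(dim(x)[1], dim(x)[2], length(idx)))
}

# ---- RSU forward / backward --------------------------------------------------

rsu_fwd <- function(x, theta, schema, pre, cfg, nb) {
  nm <- function(s) paste0(pre, s)
  th <- function(s) theta[[nm(s)]]
  sp <- function(s) schema[[nm(s)]]
  C <- list(x = x)
  if (cfg$depth == 1L) {
    C$stem <- cr_fwd(x, sp("stem"), th("stem"), nb)
    C$u <- cr_fwd(C$stem, sp("dec1"), th("dec1"), nb)
  } else {
    d <- cfg$depth
    C$stem <- cr_fwd(x, sp("stem"), th("stem"), nb)
    ein <- vector("list", d); e <- vector("list", d); pidx <- vector("list", d)
    ein[[1]] <- C$stem
    e[[1]] <- cr_fwd(C$stem, sp("enc1"), th("enc1"), nb)
    for (i in 2:d) {
      if (cfg$dilated) ein[[i]] <- e[[i - 1]]
      else {
        dm <- dim(e[[i - 1]])
        if (dm[1] %% 2L != 0L || dm[2] %% 2L != 0L)
          stop("RSU block '", pre, "' needs spatial size divisible by ",
               2L^(cfg$depth - 1L), "; got ", dm[1], "x", dm[2])
        pl <- cpp_maxpool2_fwd(e[[i - 1]])
        ein[[i]] <- pl$y; pidx[[i]] <- pl$idx
      }
      e[[i]] <- cr_fwd(ein[[i]], sp(paste0("enc", i)), th(paste0("enc", i)), nb)
    }
    C$ein <- ein; C$e <- e; C$pidx <- pidx
    C$bot <- cr_fwd(e[[d]], sp("bot"), th("bot"), nb)
    h <- C$bot
    dins <- vector("list", d); douts <- vector("list", d)
    for (i in d:1) {
      if (i < d && !cfg$dilated)
        h <- cpp_resize_bilinear(h, dim(e[[i]])[1], dim(e[[i]])[2])
      dins[[i]] <- cpp_cat_channels(h, e[[i]], nb)
      h <- cr_fwd(dins[[i]], sp(paste0("dec", i)), th(paste0("dec", i)), nb)
      douts[[i]] <- h
    }
    C$dins <- dins; C$douts <- douts
    C$u <- h
  }
  if (cfg$cin != cfg$cout) {
    C$skip <- cr_fwd(x, sp("skip"), th("skip"), nb, relu = FALSE)
    C$out <- C$u + C$skip
  } else {
    C$out <- C$u + x
  }
  C
}

# Backward through one RSU block. `acc(name, dw, db)` accumulates parameter
# gradients; returns the gradient with respect to the block input.
rsu_bwd <- function(dout, C, theta, schema, pre, cfg, acc, nb) {
  nm <- function(s) paste0(pre, s)
  th <- function(s) theta[[nm(s)]]
  sp <- function(s) schema[[nm(s)]]
  if (cfg$cin != cfg$cout) {
    g <- cr_bwd(C$x, C$skip, sp("skip"), th("skip"), dout, nb, relu = FALSE)
    acc(nm("skip"), g$dw, g$db)
    dx_skip <- g$dx
  } else {
    dx_skip <- dout
  }
  if (cfg$depth == 1L) {
    g <- cr_bwd(C$stem, C$u, sp("dec1"), th("dec1"), dout, nb)
    acc(nm("dec1"), g$dw, g$db)
    g2 <- cr_bwd(C$x, C$stem, sp("stem"), th("stem"), g$dx, nb)
    acc(nm("stem"), g2$dw, g2$db)
    return(g2$dx + dx_skip)
  }
  d <- cfg$depth; mid <- cfg$mid
  de <- vector("list", d)
  dh <- dout
  for (i in 1:d) {
    g <- cr_bwd(C$dins[[i]], C$douts[[i]], sp(paste0("dec", i)),
                th(paste0("dec", i)), dh, nb)
    acc(nm(paste0("dec", i)), g$dw, g$db)
    dh_part <- ch_range(g$dx, 1L, mid, nb)
    de_part <- ch_range(g$dx, mid + 1L, dim(g$dx)[3] %/% nb - mid, nb)
    de[[i]] <- if (is.null(de[[i]])) de_part else de[[i]] + de_part
    if (i < d && !cfg$dilated) {
      up_src <- C$douts[[i + 1]]
      dh <- cpp_resize_bilinear_adj(dh_part, dim(up_src)[1], dim(up_src)[2])
    } else {
      dh <- dh_part
    }
  }
  # dh now carries the gradient on the bottom conv output
  g <- cr_bwd(C$e[[d]], C$bot, sp("bot"), th("bot"), dh, nb)
  acc(nm("bot"), g$dw, g$db)
  de[[d]] <- de[[d]] + g$dx
  for (i in d:2) {
    g <- cr_bwd(C$ein[[i]], C$e[[i]], sp(paste0("enc", i)),
                th(paste0("enc", i)), de[[i]], nb)
    acc(nm(paste0("enc", i)), g$dw, g$db)
    dxi <- g$dx
    if (!cfg$dilated)
      dxi <- cpp_maxpool2_bwd(dxi, C$pidx[[i]],
                              dim(C$e[[i - 1]])[1], dim(C$e[[i - 1]])[2])
    de[[i - 1]] <- if (is.null(de[[i - 1]])) dxi else de[[i - 1]] + dxi
  }
  g <- cr_bwd(C$ein[[1]], C$e[[1]], sp("enc1"), th("enc1"), de[[1]], nb)
  acc(nm("enc1"), g$dw, g$db)
  g2 <- cr_bwd(C$x, C$stem, sp("stem"), th("stem"), g$dx, nb)
  acc(nm("stem"), g2$dw, g2$db)
  g2$dx + dx_skip
}

# ---- U2-Net assembly ---------------------------------------------------------

#' Nested U-block network configuration
#'
#' Assembles RSU blocks into the two-level nested U-shape: `n` encoder stages
#' separated by 2x2 max pooling, `n - 1` decoder stages fed by bilinear
#' upsampling and encoder skip concatenation, a 3x3 linear side head per
#' decoder stage plus one on the bottom encoder stage (deep supervision), and
#' a 1x1 fusion conv over the concatenated side outputs. Inputs must be
#' divisible by `2^(n - 1)`; `u2net_fwd()` zero-pads and crops automatically.
#'
#' Two presets are provided. `"desk"` (4 stages over 3 resolution levels,
#' base width 8) is small enough to train on a CPU in minutes and is the
#' configuration used throughout the package tests; `"full"` mirrors the
#' published U2-Net topology (6 stages, RSU depths 7-6-5-4 and two dilated
#' bottom stages).
#'
#' @param preset `"desk"` or `"full"`, or `NULL` when `stages` is given.
#' @param stages optional list of [rsu_config()] for the encoder (decoder is
#'   mirrored automatically); first stage must have `in_channels = 1`.
#' @param base_width stage output channels when building from a preset.
#' @return a `u2net_config` with the full parameter schema attached.
#' @export
u2net_config <- function(preset = "desk", stages = NULL, base_width = NULL) {
  if (is.null(stages)) {
    if (preset == "desk") {
      w <- base_width %||% 8L; m <- max(1L, w %/% 2L)
      stages <- list(
        rsu_config(2, 1, m, w),
        rsu_config(2, w, m, w),
        rsu_config(1, w, m, w),
        rsu_config(2, w, m, w, dilated = TRUE))
    } else if (preset == "full") {
      w <- base_width %||% 32L; m <- max(1L, w %/% 2L)
      stages <- list(
        rsu_config(7, 1, m, w),
        rsu_config(6, w, m, w),
        rsu_config(5, w, m, w),
        rsu_config(4, w, m, w),
        rsu_config(4, w, m, w, dilated = TRUE),
        rsu_config(4, w, m, w, dilated = TRUE))
    } else stop("unknown preset: ", preset)
  }
  stopifnot(length(stages) >= 2, stages[[1]]$cin == 1L)
  n <- length(stages)
  w <- stages[[1]]$cout
  dstages <- lapply(seq_len(n - 1), function(k) {
    s <- stages[[k]]
    rsu_config(s$depth, 2L * w, s$mid, w, dilated = s$dilated)
  })
  cfg <- list(stages = stages, dstages = dstages, n = n, width = w,
              divisor = 2L^(n - 1L))
  schema <- list()
  for (k in seq_len(n))
    schema <- c(schema, rsu_schema(stages[[k]], paste0("en", k, ".")))
  for (k in seq_len(n - 1))
    schema <- c(schema, rsu_schema(cfg$dstages[[k]], paste0("de", k, ".")))
  for (k in seq_len(n))
    schema <- c(schema, setNames(list(list(kh = 3L, kw = 3L, cin = w, cout = 1L,
                                           dil = 1L)), paste0("side", k)))
  schema <- c(schema, list(fuse = list(kh = 1L, kw = 1L, cin = n, cout = 1L,
                                       dil = 1L)))
  cfg$schema <- schema
  structure(cfg, class = "u2net_config")
}

#' Initialise network parameters
#'
#' He-normal weights for the hidden (ReLU) convolutions and zero biases. The
#' linear side heads start near zero (small scaled-normal weights) and the
#' fusion conv starts as the exact mean of the side outputs: the network then
#' begins from a consistent "predict ~0 everywhere" state instead of a random
#' mixture of untrained heads, which removes a long seed-dependent warm-up
#' phase from short training schedules. Deterministic given `seed`.
#'
#' @param cfg a [u2net_config()].
#' @param seed integer seed.
#' @return flat named list of parameter blocks.
#' @export
u2net_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  theta <- lapply(names(cfg$schema), function(nmi) {
    p <- cfg$schema[[nmi]]
    fan_in <- p$kh * p$kw * p$cin
    if (nmi == "fuse")
      return(list(w = matrix(1 / p$cin, fan_in, p$cout), b = numeric(p$cout)))
    sdev <- if (p$cout == 1L) 0.01 * sqrt(1 / fan_in) else sqrt(2 / fan_in)
    list(w = matrix(rnorm(fan_in * p$cout, sd = sdev), fan_in, p$cout),
         b = numeric(p$cout))
  })
  names(theta) <- names(cfg$schema)
  theta
}

# Stack a list of H x W matrices into a padded (Hp, Wp, B) cube.
stack_batch <- function(xs, div) {
  H <- nrow(xs[[1]]); W <- ncol(xs[[1]])
  Hp <- as.integer(ceiling(H / div) * div)
  Wp <- as.integer(ceiling(W / div) * div)
  out <- array(0, c(Hp, Wp, length(xs)))
  for (b in seq_along(xs)) {
    stopifnot(nrow(xs[[b]]) == H, ncol(xs[[b]]) == W)
    out[seq_len(H), seq_len(W), b] <- xs[[b]]
  }
  list(x = out, H = H, W = W)
}

#' Forward pass of the nested U-block network
#'
#' @param x input slice (H x W matrix, normalized NAC image) or list of
#'   slices, processed as one batch.
#' @param theta flat parameter list from [u2net_init()] or
#'   [unflatten_params()].
#' @param cfg a [u2net_config()].
#' @param with_cache keep intermediate activations for a backward pass.
#' @return list with `fused` and `sides`: for a single matrix input, an
#'   H x W matrix and a list of such matrices (one per decoder stage plus the
#'   bottom stage); for a list input, lists over the batch.
#' @export
u2net_fwd <- function(x, theta, cfg, with_cache = FALSE) {
  single <- is.matrix(x)
  xs <- if (single) list(x) else x
  nb <- length(xs)
  sb <- stack_batch(xs, cfg$divisor)
  xin <- sb$x
  n <- cfg$n
  enc <- vector("list", n); pidx <- vector("list", n); pin <- vector("list", n)
  h <- xin
  for (k in seq_len(n)) {
    if (k > 1) {
      pl <- cpp_maxpool2_fwd(h)
      pin[[k]] <- dim(h)[1:2]; pidx[[k]] <- pl$idx; h <- pl$y
    }
    enc[[k]] <- rsu_fwd(h, theta, cfg$schema, paste0("en", k, "."),
                        cfg$stages[[k]], nb)
    h <- enc[[k]]$out
  }
  dec <- vector("list", n)
  for (k in (n - 1):1) {
    hu <- cpp_resize_bilinear(h, dim(enc[[k]]$out)[1], dim(enc[[k]]$out)[2])
    din <- cpp_cat_channels(hu, enc[[k]]$out, nb)
    dec[[k]] <- rsu_fwd(din, theta, cfg$schema, paste0("de", k, "."),
                        cfg$dstages[[k]], nb)
    h <- dec[[k]]$out
  }
  Hp <- dim(xin)[1]; Wp <- dim(xin)[2]
  sides_raw <- vector("list", n); sides <- vector("list", n)
  for (k in seq_len(n)) {
    src <- if (k < n) dec[[k]]$out else enc[[n]]$out
    sides_raw[[k]] <- cr_fwd(src, cfg$schema[[paste0("side", k)]],
                             theta[[paste0("side", k)]], nb, relu = FALSE)
    sides[[k]] <- cpp_resize_bilinear(sides_raw[[k]], Hp, Wp)
  }
  scat <- Reduce(function(a, b) cpp_cat_channels(a, b, nb), sides)
  fused <- cr_fwd(scat, cfg$schema$fuse, theta$fuse, nb, relu = FALSE)
  crop1 <- function(a, b) matrix(a[seq_len(sb$H), seq_len(sb$W), b], sb$H, sb$W)
  out <- if (single) {
    list(fused = crop1(fused, 1), sides = lapply(sides, crop1, b = 1))
  } else {
    list(fused = lapply(seq_len(nb), crop1, a = fused),
         sides = lapply(sides, function(s) lapply(seq_len(nb), crop1, a = s)))
  }
  if (with_cache)
    out$cache <- list(xin = xin, enc = enc, dec = dec, pidx = pidx, pin = pin,
                      sides_raw = sides_raw, sides = sides, scat = scat,
                      fused = fused, H = sb$H, W = sb$W, nb = nb,
                      single = single)
  out
}

# Backward pass: dfused / dsides are gradients w.r.t. the cropped outputs
# (cubes of nb slices, or matrices when the forward input was a single
# matrix). Returns a flat named list of parameter gradients.
u2net_bwd <- function(dfused, dsides, cache, theta, cfg) {
  grads <- new.env(parent = emptyenv())
  acc <- function(name, dw, db) {
    g <- grads[[name]]
    if (is.null(g)) grads[[name]] <- list(w = dw, b = db)
    else grads[[name]] <- list(w = g$w + dw, b = g$b + db)
  }
  nb <- cache$nb
  Hp <- dim(cache$xin)[1]; Wp <- dim(cache$xin)[2]
  embed <- function(d) {
    if (is.matrix(d)) d <- array(d, c(dim(d), 1L))
    out <- array(0, c(Hp, Wp, nb))
    out[seq_len(cache$H), seq_len(cache$W), ] <- d
    out
  }
  n <- cfg$n
  dfused_p <- embed(dfused)
  g <- cr_bwd(cache$scat, cache$fused, cfg$schema$fuse, theta$fuse, dfused_p,
              nb, relu = FALSE)
  acc("fuse", g$dw, g$db)
  dscat <- g$dx
  dsrc <- vector("list", n)
  for (k in seq_len(n)) {
    dside_full <- ch_range(dscat, k, 1L, nb) + embed(dsides[[k]])
    src <- if (k < n) cache$dec[[k]]$out else cache$enc[[n]]$out
    draw <- cpp_resize_bilinear_adj(dside_full, dim(src)[1], dim(src)[2])
    g <- cr_bwd(src, cache$sides_raw[[k]], cfg$schema[[paste0("side", k)]],
                theta[[paste0("side", k)]], draw, nb, relu = FALSE)
    acc(paste0("side", k), g$dw, g$db)
    dsrc[[k]] <- g$dx
  }
  # decoder stages k = 1 .. n-1 (reverse of forward order)
  denc <- vector("list", n)
  dh <- dsrc[[1]]
  for (k in seq_len(n - 1)) {
    dx <- rsu_bwd(dh, cache$dec[[k]], theta, cfg$schema, paste0("de", k, "."),
                  cfg$dstages[[k]], acc, nb)
    w <- cfg$width
    dhu <- ch_range(dx, 1L, w, nb)
    denc[[k]] <- ch_range(dx, w + 1L, dim(dx)[3] %/% nb - w, nb)
    up_src <- if (k + 1 <= n - 1) cache$dec[[k + 1]]$out else cache$enc[[n]]$out
    dh <- cpp_resize_bilinear_adj(dhu, dim(up_src)[1], dim(up_src)[2])
    if (k + 1 <= n - 1) dh <- dh + dsrc[[k + 1]]
  }
  denc[[n]] <- dh + dsrc[[n]]
  # encoder stages n .. 1
  dcur <- NULL
  for (k in n:1) {
    dtot <- denc[[k]]
    if (!is.null(dcur)) dtot <- dtot + dcur
    dx <- rsu_bwd(dtot, cache$enc[[k]], theta, cfg$schema, paste0("en", k, "."),
                  cfg$stages[[k]], acc, nb)
    if (k > 1)
      dcur <- cpp_maxpool2_bwd(dx, cache$pidx[[k]], cache$pin[[k]][1],
                               cache$pin[[k]][2])
    else dcur <- dx
  }
  out <- as.list(grads)
  out[names(theta)]
}

# ---- deep supervision loss ---------------------------------------------------

#' Deep-supervision L2 loss
#'
#' Sum of per-output mean squared errors: the fused output and every side
#' output are each compared to the target with equal weight, so the gradient
#' reaches all decoder scales directly. For a batch the loss is the mean over
#' samples.
#'
#' @param fwd result of [u2net_fwd()] (single slice or batch).
#' @param target H x W matrix, or list of them matching a batch forward.
#' @return list with `loss` and the per-output gradients (`dfused`, `dsides`)
#'   needed by the backward pass.
#' @export
deep_supervision_loss <- function(fwd, target) {
  single <- is.matrix(fwd$fused)
  tostack <- function(z) if (is.matrix(z)) z else {
    array(unlist(z), c(dim(z[[1]]), length(z)))
  }
  tg <- tostack(target)
  f <- tostack(fwd$fused)
  stopifnot(all(dim(f) == dim(tg)))
  nel <- length(tg)
  res_f <- f - tg
  loss <- sum(res_f^2) / nel
  dfused <- 2 * res_f / nel
  dsides <- vector("list", length(fwd$sides))
  for (k in seq_along(fwd$sides)) {
    s <- tostack(fwd$sides[[k]])
    stopifnot(all(dim(s) == dim(tg)))
    r <- s - tg
    loss <- loss + sum(r^2) / nel
    dsides[[k]] <- 2 * r / nel
  }
  list(loss = loss, dfused = dfused, dsides = dsides)
}

# ---- parameter vector plumbing ----------------------------------------------

#' Flatten parameters to a numeric vector
#'
#' The flat vector is what the federated engine broadcasts, aggregates and
#' passes between centres; the order is fixed by the config schema, so any two
#' vectors from the same config are conformable. The round-trip through
#' [unflatten_params()] is bit-exact.
#'
#' @param theta flat named parameter list.
#' @return numeric vector.
#' @export
flatten_params <- function(theta) {
  unlist(lapply(theta, function(p) c(as.numeric(p$w), p$b)), use.names = FALSE)
}

#' @rdname flatten_params
#' @param v numeric vector from [flatten_params()].
#' @param cfg the matching [u2net_config()] (or any config carrying `schema`).
#' @export
unflatten_params <- function(v, cfg) {
  theta <- vector("list", length(cfg$schema))
  names(theta) <- names(cfg$schema)
  off <- 0L
  for (nmi in names(cfg$schema)) {
    p <- cfg$schema[[nmi]]
    nw <- p$kh * p$kw * p$cin * p$cout
    w <- matrix(v[off + seq_len(nw)], p$kh * p$kw * p$cin, p$cout)
    off <- off + nw
    b <- v[off + seq_len(p$cout)]
    off <- off + p$cout
    theta[[nmi]] <- list(w = w, b = b)
  }
  stopifnot(off == length(v))
  theta
}

#' Total parameter count of a network config
#' @param cfg a [u2net_config()].
#' @return integer.
#' @export
u2net_n_params <- function(cfg) {
  sum(vapply(cfg$schema, function(p) p$kh * p$kw * p$cin * p$cout + p$cout, 0))
}

# ---- trainable-model interface ----------------------------------------------

#' Wrap a network config as a trainable model
#'
#' The federated engine is agnostic to the model: it only needs `init(seed)`,
#' `loss_grad(theta, X, Y)` (mean loss and gradient over a list of paired
#' slices) and `predict(theta, X)`, all operating on the flat parameter
#' vector. This wrapper provides that interface for the nested U-block
#' network; [linear_model()] provides it for a linear least-squares toy used
#' to validate the aggregation algebra. Large sample lists are processed in
#' chunks of `chunk` slices to bound memory.
#'
#' @param cfg a [u2net_config()].
#' @param chunk maximum batch size held in memory at once.
#' @return a `fed_model` list.
#' @export
u2net_model <- function(cfg, chunk = 8L) {
  structure(list(
    cfg = cfg,
    n_params = u2net_n_params(cfg),
    init = function(seed) flatten_params(u2net_init(cfg, seed)),
    loss_grad = function(theta_v, X, Y) {
      th <- unflatten_params(theta_v, cfg)
      total <- 0; gsum <- NULL
      starts <- seq(1, length(X), by = chunk)
      for (s in starts) {
        idx <- s:min(s + chunk - 1, length(X))
        fwd <- u2net_fwd(X[idx], th, cfg, with_cache = TRUE)
        ls <- deep_supervision_loss(fwd, Y[idx])
        g <- u2net_bwd(ls$dfused, ls$dsides, fwd$cache, th, cfg)
        gv <- flatten_params(g)
        total <- total + ls$loss * length(idx)
        gsum <- if (is.null(gsum)) gv * length(idx) else gsum + gv * length(idx)
      }
      list(loss = total / length(X), grad = gsum / length(X))
    },
    predict = function(theta_v, X) {
      th <- unflatten_params(theta_v, cfg)
      out <- vector("list", length(X))
      starts <- seq(1, length(X), by = chunk)
      for (s in starts) {
        idx <- s:min(s + chunk - 1, length(X))
        out[idx] <- u2net_fwd(X[idx], th, cfg)$fused
      }
      out
    }), class = "fed_model")
}

#' Linear least-squares toy model
#'
#' `y = X theta` with loss `mean((X theta - y)^2)`. Each sample is a
#' `(X = row vector, Y = scalar)` pair. Used to validate the federated
#' aggregation algebra against closed-form gradients.
#'
#' @param p number of coefficients.
#' @return a `fed_model` list.
#' @export
linear_model <- function(p) {
  structure(list(
    n_params = p,
    init = function(seed) { set.seed(seed); rnorm(p, sd = 0.1) },
    loss_grad = function(theta_v, X, Y) {
      Xm <- do.call(rbind, X)
      yv <- unlist(Y)
      r <- as.numeric(Xm %*% theta_v) - yv
      list(loss = mean(r^2), grad = as.numeric(2 * crossprod(Xm, r) / length(yv)))
    },
    predict = function(theta_v, X) {
      lapply(X, function(x) as.numeric(x %*% theta_v))
    }), class = "fed_model")
}
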