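# ---------------------------------------------------------------------------
# Generator and discriminator builders.
#
# Both generators map a normalized (H, W, inChannels) slice stack in [-1, 1]
# to an (H, W, 1) CT slice bounded to [-1, 1] by a tanh output. The
# discriminator is a strided-convolution patch critic scoring (condition,
# candidate) stacks.
# ---------------------------------------------------------------------------

#' Generator configuration
#'
#' Desk-scale defaults build sub-million-parameter networks for CPU use;
#' clinical full-scale widths are available through [clinicalScaleConfig()].
#'
#' @param kind `"resunet"` or `"swinunet"`.
#' @param inChannels 1 (CBCT only) or 2 (CBCT + MRI, CBCT first).
#' @param filters Per-level channel widths (ResUnet) or embedding dims
#'   (SwinUnet); length = depth.
#' @param heads Per-level attention head counts (SwinUnet only); each must
#'   divide the corresponding embedding dim.
#' @param sliceShape Expected H x W of input slices.
#' @param windowSize Attention window side (SwinUnet).
#' @param nResBlocks Residual blocks per level (ResUnet).
#' @param nSwinBlocks Swin blocks per level (SwinUnet); blocks alternate
#'   plain and shifted windows.
#' @param mlpRatio Hidden width multiplier of the Swin MLP.
#' @param residual Add the global residual from the CBCT channel
#'   (`tanh(atanh(cbct) + correction)`), so an untrained generator starts at
#'   the CBCT-copy baseline. Disable to reproduce a plain randomly
#'   initialized generator.
#' @return A validated config list.
#' @export
generatorConfig <- function(kind = c("resunet", "swinunet"), inChannels = 1L,
                            filters = NULL, heads = NULL,
                            sliceShape = c(64L, 64L), windowSize = 4L,
                            nResBlocks = 1L, nSwinBlocks = 2L, mlpRatio = 2,
                            residual = TRUE) {
  kind <- match.arg(kind)
  if (is.null(filters))
    filters <- if (kind == "resunet") c(8L, 16L, 32L) else c(16L, 32L, 64L)
  if (kind == "swinunet" && is.null(heads))
    heads <- pmax(1L, as.integer(filters / 8L))
  if (!inChannels %in% c(1L, 2L)) stop("inChannels must be 1 or 2")
  if (kind == "swinunet") {
    if (length(heads) != length(filters))
      stop("heads must have one entry per level")
    if (any(filters %% heads != 0))
      stop("each embedding dim must be divisible by its head count")
  }
  list(kind = kind, inChannels = as.integer(inChannels),
       filters = as.integer(filters), heads = as.integer(heads),
       sliceShape = as.integer(sliceShape), windowSize = as.integer(windowSize),
       nResBlocks = as.integer(nResBlocks), nSwinBlocks = as.integer(nSwinBlocks),
       mlpRatio = mlpRatio, residual = isTRUE(residual))
}

#' Clinical full-scale generator configurations
#'
#' ResUnet widths `[64,128,256,512,1024]`; SwinUnet embedding dims
#' `[128,256,512,1024,2048]` with heads `[8,16,32,32,32]`.
#'
#' @param kind `"resunet"` or `"swinunet"`.
#' @param withMri Whether the MRI channel is enabled (2 input channels).
#' @return A config list as from [generatorConfig()].
#' @export
clinicalScaleConfig <- function(kind = c("resunet", "swinunet"),
                                 withMri = TRUE) {
  kind <- match.arg(kind)
  if (kind == "resunet")
    generatorConfig("resunet", inChannels = if (withMri) 2L else 1L,
                    filters = c(64L, 128L, 256L, 512L, 1024L),
                    sliceShape = c(512L, 512L))
  else
    generatorConfig("swinunet", inChannels = if (withMri) 2L else 1L,
                    filters = c(128L, 256L, 512L, 1024L, 2048L),
                    heads = c(8L, 16L, 32L, 32L, 32L),
                    sliceShape = c(512L, 512L))
}

#' Discriminator configuration
#'
#' @param filters Per-block widths; clinical full scale is `c(64,128,256,512)` with
#'   4 stride-2 blocks.
#' @param inChannels Total stacked channels (condition channels + 1
#'   candidate channel for Pix2Pix; 1 for CycleGAN critics).
#' @return A validated config list.
#' @export
discriminatorConfig <- function(filters = c(8L, 16L, 32L), inChannels = 2L) {
  stopifnot(length(filters) >= 1, all(filters > 0), inChannels >= 1)
  list(kind = "discriminator", filters = as.integer(filters),
       nBlocks = length(filters), inChannels = as.integer(inChannels))
}

.checkDivisible <- function(hw, depth, kind) {
  f <- 2^(depth - 1L)
  if (any(hw %% f != 0))
    stop(kind, " input sides must be divisible by ", f, "; got ",
         paste(hw, collapse = "x"), call. = FALSE)
}

# ---- ResUnet ---------------------------------------------------------------

#' Build a ResUnet generator
#'
#' Encoder-decoder with stride-2 downsampling, nearest-neighbor upsampling,
#' skip concatenation, and residual blocks at every level; tanh output.
#'
#' @param cfg A [generatorConfig()] with `kind = "resunet"`.
#' @param seed RNG seed for weight initialization.
#' @return A model handle usable with [runGenerator()] and the training
#'   functions.
#' @export
buildResUnet <- function(cfg, seed = 1L) {
  stopifnot(cfg$kind == "resunet")
  .checkDivisible(cfg$sliceShape, length(cfg$filters), "resunet")
  withRng(seed, {
    m <- newModel("resunet", cfg)
    f <- cfg$filters
    L <- length(f)
    addConv(m, "stem", 3, 3, cfg$inChannels, f[1])
    for (i in seq_len(L - 1)) {
      for (r in seq_len(cfg$nResBlocks)) {
        addConv(m, sprintf("enc%d.res%d.a", i, r), 3, 3, f[i], f[i])
        addConv(m, sprintf("enc%d.res%d.b", i, r), 3, 3, f[i], f[i])
      }
      addConv(m, sprintf("down%d", i), 3, 3, f[i], f[i + 1])
    }
    for (r in seq_len(cfg$nResBlocks)) {
      addConv(m, sprintf("mid.res%d.a", r), 3, 3, f[L], f[L])
      addConv(m, sprintf("mid.res%d.b", r), 3, 3, f[L], f[L])
    }
    for (i in rev(seq_len(L - 1))) {
      addConv(m, sprintf("up%d", i), 3, 3, f[i + 1], f[i])
      addConv(m, sprintf("fuse%d", i), 3, 3, 2 * f[i], f[i])
      for (r in seq_len(cfg$nResBlocks)) {
        addConv(m, sprintf("dec%d.res%d.a", i, r), 3, 3, f[i], f[i])
        addConv(m, sprintf("dec%d.res%d.b", i, r), 3, 3, f[i], f[i])
      }
    }
    addConv(m, "head", 3, 3, f[1], 1, gain = 0)
    m$forward <- .resunetForward
    m
  })
}

.resBlock <- function(m, name, x) {
  h <- opRelu(pConv(m, paste0(name, ".a"), x))
  opRelu(opAdd(pConv(m, paste0(name, ".b"), h), x))
}

.resunetForward <- function(m, x) {
  cfg <- m$cfg
  d <- dim(x$value)
  if (d[3] != cfg$inChannels)
    stop("generator expects ", cfg$inChannels, " channels, got ", d[3],
         call. = FALSE)
  .checkDivisible(d[1:2], length(cfg$filters), "resunet")
  L <- length(cfg$filters)
  h <- opRelu(pConv(m, "stem", x))
  skips <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    for (r in seq_len(cfg$nResBlocks)) h <- .resBlock(m, sprintf("enc%d.res%d", i, r), h)
    skips[[i]] <- h
    h <- opRelu(pConv(m, sprintf("down%d", i), h, stride = 2L))
  }
  for (r in seq_len(cfg$nResBlocks)) h <- .resBlock(m, sprintf("mid.res%d", r), h)
  for (i in rev(seq_len(L - 1))) {
    h <- opRelu(pConv(m, sprintf("up%d", i), opUpsample2(h)))
    h <- opRelu(pConv(m, sprintf("fuse%d", i), opConcatC(h, skips[[i]])))
    for (r in seq_len(cfg$nResBlocks)) h <- .resBlock(m, sprintf("dec%d.res%d", i, r), h)
  }
  # global residual: the network learns a pre-activation correction to the
  # CBCT channel (tanh(atanh(cbct) + correction) equals the CBCT at init)
  out <- pConv(m, "head", h)
  if (cfg$residual) out <- opAdd(out, .residBase(x))
  opTanh(out)
}

.residBase <- function(x) {
  nnConst(atanh(pmin(pmax(x$value[, , 1L, , drop = FALSE], -0.999), 0.999)))
}

# ---- SwinUnet --------------------------------------------------------------

#' Build a SwinUnet generator
#'
#' U-shaped network whose encoder/decoder blocks use windowed multi-head
#' self-attention (alternating plain and shifted windows) with pre-norm
#' residual MLPs; convolutional patch embedding/merging; tanh output. Same
#' I/O contract as [buildResUnet()].
#'
#' @inheritParams buildResUnet
#' @export
buildSwinUnet <- function(cfg, seed = 1L) {
  stopifnot(cfg$kind == "swinunet")
  withRng(seed, {
    m <- newModel("swinunet", cfg)
    f <- cfg$filters
    L <- length(f)
    addConv(m, "embed", 2, 2, cfg$inChannels, f[1])  # stride-2 patch embed
    for (i in seq_len(L)) {
      for (b in seq_len(cfg$nSwinBlocks))
        .addSwinBlock(m, sprintf("enc%d.b%d", i, b), f[i], cfg$mlpRatio)
      if (i < L) addConv(m, sprintf("merge%d", i), 2, 2, f[i], f[i + 1])
    }
    for (i in rev(seq_len(L - 1))) {
      addConv(m, sprintf("expand%d", i), 3, 3, f[i + 1], f[i])
      addConv(m, sprintf("fuse%d", i), 3, 3, 2 * f[i], f[i])
      for (b in seq_len(cfg$nSwinBlocks))
        .addSwinBlock(m, sprintf("dec%d.b%d", i, b), f[i], cfg$mlpRatio)
    }
    addConv(m, "final", 3, 3, f[1], f[1])
    addConv(m, "head", 3, 3, f[1], 1, gain = 0)
    m$forward <- .swinForward
    m
  })
}

.addSwinBlock <- function(m, name, dim, mlpRatio) {
  addLayerNorm(m, paste0(name, ".ln1"), dim)
  addDense(m, paste0(name, ".qkv"), dim, 3 * dim, gain = 1)
  addDense(m, paste0(name, ".proj"), dim, dim, gain = 1)
  addLayerNorm(m, paste0(name, ".ln2"), dim)
  addDense(m, paste0(name, ".mlp1"), dim, round(mlpRatio * dim))
  addDense(m, paste0(name, ".mlp2"), round(mlpRatio * dim), dim, gain = 1)
}

# (H,W,C,N) -> (C, win^2, nWindows*N); win must divide H and W.
.windowPartition <- function(x, win) {
  d <- dim(x$value)
  nh <- d[1] %/% win; nw <- d[2] %/% win
  h <- opReshape(x, c(win, nh, win, nw, d[3], d[4]))
  h <- opAperm(h, c(1, 3, 5, 2, 4, 6))
  h <- opReshape(h, c(win * win, d[3], nh * nw * d[4]))
  opAperm(h, c(2, 1, 3))
}

.windowMerge <- function(x, win, d) {
  nh <- d[1] %/% win; nw <- d[2] %/% win
  h <- opAperm(x, c(2, 1, 3))
  h <- opReshape(h, c(win, win, d[3], nh, nw, d[4]))
  h <- opAperm(h, c(1, 4, 2, 5, 3, 6))
  opReshape(h, d)
}

.windowAttention <- function(m, name, xw, heads) {
  # xw: (C, T, B) windows; joint QKV projection applied to all tokens at once
  d <- dim(xw$value)
  C <- d[1]; T <- d[2]; B <- d[3]
  hd <- C %/% heads
  x2 <- opReshape(xw, c(C, T * B))
  qkv <- pDense(m, paste0(name, ".qkv"), pLayerNorm(m, paste0(name, ".ln1"), x2))
  toHeads <- function(rows) {
    h <- opReshape(opRowSlice(qkv, rows), c(hd, heads, T, B))
    opReshape(opAperm(h, c(1, 3, 2, 4)), c(hd, T, heads * B))
  }
  q <- toHeads(seq_len(C))
  k <- toHeads(C + seq_len(C))
  v <- toHeads(2 * C + seq_len(C))
  att <- opSoftmaxDim2(opScale(opBmm(q, k, tA = TRUE), 1 / sqrt(hd)))
  out <- opBmm(v, att, tB = TRUE)                       # (hd, T, heads*B)
  out <- opAperm(opReshape(out, c(hd, T, heads, B)), c(1, 3, 2, 4))
  out <- opReshape(out, c(C, T * B))
  out <- pDense(m, paste0(name, ".proj"), out)
  opReshape(opAdd(out, opReshape(xw, c(C, T * B))), c(C, T, B))
}

.swinBlock <- function(m, name, x, heads, win, shift) {
  d <- dim(x$value)
  if (any(d[1:2] %% win != 0))
    stop("feature map ", d[1], "x", d[2], " not divisible by window ", win,
         call. = FALSE)
  h <- if (shift > 0) opRoll(x, c(-shift, -shift)) else x
  hw <- .windowPartition(h, win)
  hw <- .windowAttention(m, name, hw, heads)
  h <- .windowMerge(hw, win, d)
  if (shift > 0) h <- opRoll(h, c(shift, shift))
  # pre-norm MLP with residual, applied tokenwise
  h2 <- opReshape(h, c(d[3], prod(d) / d[3]))
  mlp <- pDense(m, paste0(name, ".mlp2"),
                opRelu(pDense(m, paste0(name, ".mlp1"),
                              pLayerNorm(m, paste0(name, ".ln2"), h2))))
  opReshape(opAdd(h2, mlp), d)
}

.swinForward <- function(m, x) {
  cfg <- m$cfg
  d <- dim(x$value)
  if (d[3] != cfg$inChannels)
    stop("generator expects ", cfg$inChannels, " channels, got ", d[3],
         call. = FALSE)
  f <- cfg$filters; L <- length(f); win <- cfg$windowSize
  if (any((d[1:2] / 2^L) %% 1 != 0))
    stop("swinunet input sides must be divisible by ", 2^L, call. = FALSE)
  h <- pConv(m, "embed", x, stride = 2L, pad = 0L)
  skips <- vector("list", L - 1)
  for (i in seq_len(L)) {
    for (b in seq_len(cfg$nSwinBlocks)) {
      shift <- if (b %% 2 == 0) win %/% 2 else 0L
      h <- .swinBlock(m, sprintf("enc%d.b%d", i, b), h, cfg$heads[i], win, shift)
    }
    if (i < L) {
      skips[[i]] <- h
      h <- pConv(m, sprintf("merge%d", i), h, stride = 2L, pad = 0L)
    }
  }
  for (i in rev(seq_len(L - 1))) {
    h <- opRelu(pConv(m, sprintf("expand%d", i), opUpsample2(h)))
    h <- opRelu(pConv(m, sprintf("fuse%d", i), opConcatC(h, skips[[i]])))
    for (b in seq_len(cfg$nSwinBlocks)) {
      shift <- if (b %% 2 == 0) win %/% 2 else 0L
      h <- .swinBlock(m, sprintf("dec%d.b%d", i, b), h, cfg$heads[i], win, shift)
    }
  }
  h <- opRelu(pConv(m, "final", opUpsample2(h)))
  # global residual from the CBCT channel, as in the ResUnet path
  out <- pConv(m, "head", h)
  if (cfg$residual) out <- opAdd(out, .residBase(x))
  opTanh(out)
}

# ---- discriminator ---------------------------------------------------------

#' Build a patch discriminator
#'
#' Strided 4x4 convolutions with leaky ReLU produce a spatial map of
#' real/fake logits over image patches.
#'
#' @param cfg A [discriminatorConfig()].
#' @param seed RNG seed for weight initialization.
#' @return A model handle; `model$forward(model, x)` maps
#'   `(H, W, inChannels, N)` to an `(H/2^nBlocks, W/2^nBlocks, 1, N)` logit map.
#' @export
buildDiscriminator <- function(cfg, seed = 1L) {
  stopifnot(cfg$kind == "discriminator")
  withRng(seed, {
    m <- newModel("discriminator", cfg)
    cin <- cfg$inChannels
    for (i in seq_along(cfg$filters)) {
      addConv(m, sprintf("block%d", i), 4, 4, cin, cfg$filters[i])
      cin <- cfg$filters[i]
    }
    addConv(m, "head", 3, 3, cin, 1, gain = 1)
    m$forward <- function(m, x) {
      d <- dim(x$value)
      if (d[3] != m$cfg$inChannels)
        stop("discriminator expects ", m$cfg$inChannels, " channels, got ",
             d[3], call. = FALSE)
      h <- x
      for (i in seq_along(m$cfg$filters))
        h <- opLeakyRelu(pConv(m, sprintf("block%d", i), h, stride = 2L, pad = 1L))
      pConv(m, "head", h)
    }
    m
  })
}

#' Analytic receptive field of one discriminator output unit
#'
#' Computed from the kernel/stride chain (4x4 stride-2 blocks plus the 3x3
#' stride-1 head).
#'
#' @param cfg A [discriminatorConfig()].
#' @return Receptive field side length in input pixels.
#' @export
discriminatorReceptiveField <- function(cfg) {
  rf <- 1; jump <- 1
  for (i in seq_len(cfg$nBlocks)) {
    rf <- rf + (4 - 1) * jump
    jump <- jump * 2
  }
  rf + (3 - 1) * jump
}

# ---- inference -------------------------------------------------------------

#' Run a generator in inference mode
#'
#' Deterministic given fixed weights: no tape is recorded and no noise is
#' involved.
#'
#' @param model A generator handle.
#' @param input `(H, W, C)` or `(H, W, C, N)` array, normalized to [-1, 1].
#' @return Array of predicted normalized CT slices, same leading dims, 1
#'   channel.
#' @export
runGenerator <- function(model, input) {
  d <- dim(input)
  squeeze <- length(d) == 3L
  if (squeeze) dim(input) <- c(d, 1L)
  nnRecording(FALSE)
  out <- model$forward(model, nnConst(input))$value
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
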