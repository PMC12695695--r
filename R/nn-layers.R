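# ---------------------------------------------------------------------------
# Layer parameter helpers, the Adam optimizer, and model-handle plumbing.
#
# A model handle is an environment with $params (named list of leaf tensors),
# $cfg, $kind and $forward(model, x) returning a tape tensor. Weights are
# He-initialized from the R RNG, so a model is a pure function of its
# construction seed.
# ---------------------------------------------------------------------------

newModel <- function(kind, cfg) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$cfg <- cfg
  m$params <- list()
  class(m) <- c(paste0(kind, "Model"), "dualsctModel")
  m
}

addConv <- function(model, name, kh, kw, cin, cout, gain = 2) {
  # gain 0 zero-initializes the layer (used for output heads so generators
  # start exactly at their residual baseline)
  sd <- sqrt(gain / (kh * kw * cin))
  w <- nnParam(array(if (sd > 0) stats::rnorm(kh * kw * cin * cout, 0, sd)
                     else 0, c(kh, kw, cin, cout)))
  b <- nnParam(rep(0, cout))
  model$params[[paste0(name, ".w")]] <- w
  model$params[[paste0(name, ".b")]] <- b
  invisible(NULL)
}

addDense <- function(model, name, nin, nout, gain = 2) {
  sd <- sqrt(gain / nin)
  w <- nnParam(matrix(stats::rnorm(nout * nin, 0, sd), nout, nin))
  b <- nnParam(rep(0, nout))
  model$params[[paste0(name, ".w")]] <- w
  model$params[[paste0(name, ".b")]] <- b
  invisible(NULL)
}

addLayerNorm <- function(model, name, nfeat) {
  model$params[[paste0(name, ".g")]] <- nnParam(rep(1, nfeat))
  model$params[[paste0(name, ".b")]] <- nnParam(rep(0, nfeat))
  invisible(NULL)
}

pConv <- function(model, name, x, stride = 1L, pad = NULL) {
  opConv2d(x, model$params[[paste0(name, ".w")]],
           model$params[[paste0(name, ".b")]], stride = stride, pad = pad)
}

pDense <- function(model, name, x) {
  opAddBias(opMatmul(model$params[[paste0(name, ".w")]], x),
            model$params[[paste0(name, ".b")]])
}

pLayerNorm <- function(model, name, x) {
  opLayerNormCols(x, model$params[[paste0(name, ".g")]],
                  model$params[[paste0(name, ".b")]])
}

#' Count trainable parameters of a model
#'
#' @param model A model handle from [buildResUnet()], [buildSwinUnet()] or
#'   [buildDiscriminator()].
#' @return Integer total of trainable scalar parameters.
#' @examples
#' g <- buildResUnet(generatorConfig("resunet", filters = c(8, 16, 32)))
#' countParameters(g)
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), 0))
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p$value) %||% length(p$value))),
       v = lapply(params, function(p) array(0, dim(p$value) %||% length(p$value))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(state, params, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- params[[i]]$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]]$value <- params[[i]]$value -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

# Snapshot / restore parameter values (checkpointing).
paramValues <- function(model) lapply(model$params, function(p) p$value)

setParamValues <- function(model, values) {
  stopifnot(identical(names(values), names(model$params)))
  for (i in seq_along(values)) model$params[[i]]$value <- values[[i]]
  invisible(model)
}

#' Save / load a generator or discriminator model
#'
#' Weights and config are stored with `saveRDS`; `loadModel` rebuilds the
#' architecture and restores the weights.
#'
#' @param model A model handle.
#' @param path File path.
#' @return `loadModel` returns the rebuilt model handle.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(kind = model$kind, cfg = model$cfg,
               values = paramValues(model)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  model <- switch(obj$kind,
    resunet = buildResUnet(obj$cfg),
    swinunet = buildSwinUnet(obj$cfg),
    discriminator = buildDiscriminator(obj$cfg),
    stop("unknown model kind: ", obj$kind))
  setParamValues(model, obj$values)
  model
}
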