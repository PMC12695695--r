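#' @useDynLib dualsct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Reverse-mode autodiff tape.
#
# A tensor is an environment holding $value (numeric array), $grad (set during
# the backward sweep), $parents (list of parent tensors) and $backward (a
# closure mapping the output gradient to a list of parent gradients). The tape
# records operation nodes in creation order; nnBackward() traverses it in
# reverse. Parameters are leaf tensors kept outside the tape so their gradients
# survive tape resets.
# ---------------------------------------------------------------------------

.nnTape <- new.env(parent = emptyenv())
.nnTape$nodes <- vector("list", 1024L)
.nnTape$n <- 0L
.nnTape$recording <- FALSE

nnTapeReset <- function() {
  .nnTape$nodes <- vector("list", 1024L)
  .nnTape$n <- 0L
  invisible(NULL)
}

nnRecording <- function(on) {
  .nnTape$recording <- isTRUE(on)
  invisible(NULL)
}

nnNode <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  class(node) <- "nnTensor"
  if (.nnTape$recording && length(parents)) {
    n <- .nnTape$n + 1L
    if (n > length(.nnTape$nodes))
      .nnTape$nodes <- c(.nnTape$nodes, vector("list", length(.nnTape$nodes)))
    .nnTape$nodes[[n]] <- node
    .nnTape$n <- n
  }
  node
}

#' @noRd
nnParam <- function(value) {
  node <- nnNode(value)
  node$isParam <- TRUE
  node
}

nnConst <- function(value) nnNode(value)

nnDetach <- function(x) nnConst(x$value)

asTensor <- function(x) if (inherits(x, "nnTensor")) x else nnConst(x)

#' Run the backward sweep from a scalar loss tensor
#' @noRd
nnBackward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  if (.nnTape$n > 0L) {
    for (i in seq(.nnTape$n, 1L)) {
      node <- .nnTape$nodes[[i]]
      g <- node$grad
      if (is.null(g) || is.null(node$backward)) next
      pgrads <- node$backward(g)
      for (j in seq_along(node$parents)) {
        pg <- pgrads[[j]]
        if (is.null(pg)) next
        p <- node$parents[[j]]
        p$grad <- if (is.null(p$grad)) pg else p$grad + pg
      }
    }
  }
  invisible(NULL)
}

nnZeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops -------------------------------------------------------

opAdd <- function(x, y) {
  x <- asTensor(x); y <- asTensor(y)
  nnNode(x$value + y$value, list(x, y), function(g) list(g, g))
}

opSub <- function(x, y) {
  x <- asTensor(x); y <- asTensor(y)
  nnNode(x$value - y$value, list(x, y), function(g) list(g, -g))
}

opMul <- function(x, y) {
  x <- asTensor(x); y <- asTensor(y)
  nnNode(x$value * y$value, list(x, y),
         function(g) list(g * y$value, g * x$value))
}

opScale <- function(x, k) {
  nnNode(x$value * k, list(x), function(g) list(g * k))
}

opRelu <- function(x) {
  m <- x$value > 0
  nnNode(x$value * m, list(x), function(g) list(g * m))
}

opLeakyRelu <- function(x, alpha = 0.2) {
  m <- ifelse(x$value > 0, 1, alpha)
  nnNode(x$value * m, list(x), function(g) list(g * m))
}

opTanh <- function(x) {
  v <- tanh(x$value)
  nnNode(v, list(x), function(g) list(g * (1 - v^2)))
}

opSigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  nnNode(v, list(x), function(g) list(g * v * (1 - v)))
}

# ---- shape ops -------------------------------------------------------------

opReshape <- function(x, dims) {
  old <- dim(x$value)
  v <- x$value
  dim(v) <- dims
  nnNode(v, list(x), function(g) { dim(g) <- old; list(g) })
}

opAperm <- function(x, perm) {
  inv <- order(perm)
  nnNode(aperm(x$value, perm), list(x), function(g) list(aperm(g, inv)))
}

opConcatC <- function(x, y) {
  # concatenate along the channel axis (3rd of 4)
  dx <- dim(x$value); dy <- dim(y$value)
  stopifnot(all(dx[-3] == dy[-3]))
  v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$value
  v[, , dx[3] + seq_len(dy[3]), ] <- y$value
  nnNode(v, list(x, y), function(g) {
    list(g[, , seq_len(dx[3]), , drop = FALSE],
         g[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

opRowSlice <- function(x, rows) {
  # select rows of a 2D matrix tensor
  d <- dim(x$value)
  v <- x$value[rows, , drop = FALSE]
  nnNode(v, list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[rows, ] <- g
    list(gx)
  })
}

opChanSlice <- function(x, ch) {
  # select one channel of (H,W,C,N), keeping a singleton channel axis
  d <- dim(x$value)
  v <- x$value[, , ch, , drop = FALSE]
  nnNode(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , ch, ] <- g
    list(gx)
  })
}

opRoll <- function(x, shift) {
  # circular shift along the first two axes of (H,W,C,N)
  d <- dim(x$value)
  idx1 <- ((seq_len(d[1]) - 1 - shift[1]) %% d[1]) + 1
  idx2 <- ((seq_len(d[2]) - 1 - shift[2]) %% d[2]) + 1
  v <- x$value[idx1, idx2, , , drop = FALSE]
  nnNode(v, list(x), function(g) {
    j1 <- ((seq_len(d[1]) - 1 + shift[1]) %% d[1]) + 1
    j2 <- ((seq_len(d[2]) - 1 + shift[2]) %% d[2]) + 1
    list(g[j1, j2, , , drop = FALSE])
  })
}

# ---- conv / spatial ops ----------------------------------------------------

opConv2d <- function(x, w, b, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (dim(w$value)[1] - 1L) %/% 2L
  v <- .cpp_conv2d_fw(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  nnNode(v, list(x, w, b), function(g) {
    bw <- .cpp_conv2d_bw(x$value, w$value, g, as.integer(stride), as.integer(pad))
    list(bw$gx, bw$gw, bw$gb)
  })
}

opUpsample2 <- function(x) {
  d <- dim(x$value)
  i1 <- rep(seq_len(d[1]), each = 2)
  i2 <- rep(seq_len(d[2]), each = 2)
  v <- x$value[i1, i2, , , drop = FALSE]
  nnNode(v, list(x), function(g) {
    # adjoint of nearest upsampling: sum each 2x2 block
    g1 <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] + g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    list(g1[, seq(1, 2 * d[2], 2), , , drop = FALSE] + g1[, seq(2, 2 * d[2], 2), , , drop = FALSE])
  })
}

# ---- matrix / attention ops ------------------------------------------------

opMatmul <- function(a, b) {
  nnNode(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

opAddBias <- function(x, b) {
  # x: (features, tokens); b: length features
  nnNode(x$value + b$value, list(x, b), function(g) {
    list(g, rowSums(g))
  })
}

opBmm <- function(a, b, tA = FALSE, tB = FALSE) {
  v <- .cpp_bmm(a$value, b$value, tA, tB)
  nnNode(v, list(a, b), function(g) {
    ga <- if (!tA) .cpp_bmm(g, b$value, FALSE, !tB) else .cpp_bmm(b$value, g, tB, TRUE)
    gb <- if (!tB) .cpp_bmm(a$value, g, !tA, FALSE) else .cpp_bmm(g, a$value, TRUE, tA)
    list(ga, gb)
  })
}

opSoftmaxDim2 <- function(x) {
  # softmax along the 2nd axis of (m, n, B)
  d <- dim(x$value)
  m <- apply(x$value, c(1, 3), max)
  e <- exp(x$value - aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2)))
  s <- apply(e, c(1, 3), sum)
  v <- e / aperm(array(s, c(d[1], d[3], d[2])), c(1, 3, 2))
  nnNode(v, list(x), function(g) {
    dot <- apply(g * v, c(1, 3), sum)
    list(v * (g - aperm(array(dot, c(d[1], d[3], d[2])), c(1, 3, 2))))
  })
}

opLayerNormCols <- function(x, gamma, beta, eps = 1e-5) {
  # normalize each column (token) of (features, tokens) to zero mean/unit var
  v <- x$value
  f <- nrow(v)
  mu <- colMeans(v)
  xc <- sweep(v, 2, mu)
  va <- colMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  out <- xhat * gamma$value + beta$value
  nnNode(out, list(x, gamma, beta), function(g) {
    ggamma <- rowSums(g * xhat)
    gbeta <- rowSums(g)
    gxhat <- g * gamma$value
    colg <- colMeans(gxhat)
    colgx <- colMeans(gxhat * xhat)
    gx <- sweep(gxhat, 2, colg) - xhat * rep(colgx, each = f)
    gx <- sweep(gx, 2, istd, `*`)
    list(gx, ggamma, gbeta)
  })
}

# ---- reductions / losses ---------------------------------------------------

opMeanAll <- function(x) {
  n <- length(x$value)
  nnNode(mean(x$value), list(x), function(g) list(array(g / n, dim(x$value))))
}

opMae <- function(x, target, mask = NULL) {
  t <- if (inherits(target, "nnTensor")) target$value else target
  d <- x$value - t
  if (is.null(mask)) {
    n <- length(d)
    nnNode(mean(abs(d)), list(x), function(g) list(g * sign(d) / n))
  } else {
    n <- sum(mask)
    if (n == 0) stop("empty mask in MAE loss")
    nnNode(sum(abs(d) * mask) / n, list(x),
           function(g) list(g * sign(d) * mask / n))
  }
}

opBceLogits <- function(x, target) {
  # numerically stable binary cross-entropy on logits; target in [0,1]
  s <- x$value
  v <- mean(pmax(s, 0) - s * target + log1p(exp(-abs(s))))
  n <- length(s)
  nnNode(v, list(x), function(g) {
    list(g * (1 / (1 + exp(-s)) - target) / n)
  })
}
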