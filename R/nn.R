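# Minimal reverse-mode neural-network engine.
#
# All architectures in this package use 1-D convolution kernels (1x5, 1x2,
# 4x1, ...) over a 20x20 spatial grid with spectral bands as channels, so
# convolutions are implemented as a handful of shifted BLAS matrix products
# rather than a general im2col. Internal layouts:
#   dense activations: (features, batch) matrices
#   conv activations:  (channels, height, width, batch) arrays
# Batch norm treats dense rows / conv channels as features. Gradients are
# propagated all the way to the network input, which is what the
# integrated-gradients attribution consumes.

#' Layer constructors for sequential networks
#'
#' Building blocks consumed by \code{\link{buildNetwork}}:
#' fully-connected, rectifier, batch-normalization, dropout, 2-D
#' convolution (stride 1, "same" zero padding), max/average pooling
#' (stride = pool size) and flatten.
#'
#' @param units output width of a dense layer.
#' @return a layer description list.
#' @export
nnDense <- function(units) list(type = "dense", units = as.integer(units))

#' @rdname nnDense
#' @export
nnReLU <- function() list(type = "relu")

#' @rdname nnDense
#' @param momentum running-statistics momentum for batch norm.
#' @export
nnBatchNorm <- function(momentum = 0.9) {
  list(type = "bn", momentum = momentum, eps = 1e-5)
}

#' @rdname nnDense
#' @param rate dropout probability in [0, 1).
#' @export
nnDropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

#' @rdname nnDense
#' @param filters number of convolution filters.
#' @param kernel integer length-2 kernel (height, width).
#' @export
nnConv2d <- function(filters, kernel) {
  list(type = "conv", filters = as.integer(filters),
       kernel = as.integer(kernel))
}

#' @rdname nnDense
#' @param kind "max" or "average".
#' @param size integer length-2 pool size (height, width); also the stride.
#' @export
nnPool <- function(kind = c("max", "average"), size) {
  kind <- match.arg(kind)
  list(type = "pool", kind = kind, size = as.integer(size))
}

#' @rdname nnDense
#' @export
nnFlatten <- function() list(type = "flatten")

#' Assemble and initialize a sequential network
#'
#' Propagates shapes through the layer stack (erroring if a pooling layer
#' would collapse a spatial axis to zero), and He-initializes dense and
#' convolution weights from the supplied seed.
#'
#' @param inputShape integer vector: a single length for 1-D (dense) input,
#'   or (height, width, channels) for image input.
#' @param layers list of layer descriptions from the \code{nn*} helpers.
#' @param seed integer RNG seed for weight initialization.
#' @return an object of class \code{sbNetwork}.
#' @export
buildNetwork <- function(inputShape, layers, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  shape <- as.integer(inputShape)           # (H, W, C) or length
  params <- vector("list", length(layers))
  state <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      fanIn <- if (length(shape) == 1L) shape else prod(shape)
      if (length(shape) != 1L)
        stop("dense layer ", i, " needs flattened input; add nnFlatten()")
      params[[i]] <- list(
        W = matrix(stats::rnorm(l$units * fanIn, sd = sqrt(2 / fanIn)),
                   l$units, fanIn),
        b = numeric(l$units))
      shape <- l$units
    } else if (l$type == "conv") {
      if (length(shape) != 3L)
        stop("conv layer ", i, " needs (height, width, channels) input")
      cin <- shape[3L]
      fanIn <- cin * prod(l$kernel)
      params[[i]] <- list(
        W = array(stats::rnorm(cin * prod(l$kernel) * l$filters,
                               sd = sqrt(2 / fanIn)),
                  c(cin, l$kernel[1L], l$kernel[2L], l$filters)),
        b = numeric(l$filters))
      shape <- c(shape[1L], shape[2L], l$filters)   # same padding
    } else if (l$type == "bn") {
      nf <- if (length(shape) == 1L) shape else shape[3L]
      params[[i]] <- list(gamma = rep(1, nf), beta = numeric(nf))
      state[[i]] <- list(mean = numeric(nf), var = rep(1, nf))
    } else if (l$type == "pool") {
      if (length(shape) != 3L)
        stop("pool layer ", i, " needs (height, width, channels) input")
      ho <- shape[1L] %/% l$size[1L]
      wo <- shape[2L] %/% l$size[2L]
      if (ho < 1L || wo < 1L)
        stop(sprintf("pool layer %d (%dx%d) collapses the %dx%d input to zero",
                     i, l$size[1L], l$size[2L], shape[1L], shape[2L]))
      shape <- c(ho, wo, shape[3L])
    } else if (l$type == "flatten") {
      shape <- prod(shape)
    } else if (l$type %in% c("relu", "dropout")) {
      # shape preserved
    } else stop("unknown layer type: ", l$type)
    layers[[i]]$outShape <- shape
  }
  structure(list(inputShape = as.integer(inputShape), layers = layers,
                 params = params, state = state, seed = as.integer(seed)),
            class = "sbNetwork")
}

#' @export
print.sbNetwork <- function(x, ...) {
  cat(sprintf("sbNetwork: input (%s), %d layers, %d parameters\n",
              paste(x$inputShape, collapse = "x"), length(x$layers),
              nParams(x)))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param net an \code{sbNetwork}.
#' @return integer number of trainable scalars (batch-norm gains and shifts
#'   included; running statistics are not trainable).
#' @export
nParams <- function(net) {
  sum(vapply(net$params, function(p)
    if (is.null(p)) 0L else sum(vapply(p, length, 1L)), 1L))
}

# (H, W, C, N) user batch -> internal (C, H, W, N)
toInternal <- function(x) {
  if (length(dim(x)) == 4L) aperm(x, c(3L, 1L, 2L, 4L))
  else t(x)                               # (N, D) matrix -> (D, N)
}

convPad <- function(x, kh, kw) {
  d <- dim(x)
  pt <- (kh - 1L) %/% 2L; pb <- (kh - 1L) - pt
  pl <- (kw - 1L) %/% 2L; pr <- (kw - 1L) - pl
  xp <- array(0, c(d[1L], d[2L] + kh - 1L, d[3L] + kw - 1L, d[4L]))
  xp[, pt + seq_len(d[2L]), pl + seq_len(d[3L]), ] <- x
  list(xp = xp, pt = pt, pl = pl)
}

netForward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    p <- net$params[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- p$W %*% x + p$b
    } else if (l$type == "relu") {
      caches[[i]] <- list(pos = x > 0)
      x <- x * caches[[i]]$pos
    } else if (l$type == "bn") {
      isConv <- length(dim(x)) == 4L
      d <- dim(x)
      xm <- if (isConv) matrix(x, nrow = d[1L]) else x
      if (train) {
        mu <- rowMeans(xm)
        v <- rowMeans((xm - mu)^2)
        st <- net$state[[i]]
        st$mean <- l$momentum * st$mean + (1 - l$momentum) * mu
        st$var <- l$momentum * st$var + (1 - l$momentum) * v
        net$state[[i]] <- st
      } else {
        mu <- net$state[[i]]$mean
        v <- net$state[[i]]$var
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- (xm - mu) * invstd
      ym <- p$gamma * xhat + p$beta
      caches[[i]] <- list(xhat = xhat, invstd = invstd, isConv = isConv,
                          d = d, train = train)
      x <- if (isConv) array(ym, d) else ym
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        keep <- array(stats::runif(length(x)) >= l$rate, dim(x) %||% length(x))
        scale <- 1 / (1 - l$rate)
        caches[[i]] <- list(keep = keep, scale = scale)
        x <- x * keep * scale
      } else caches[[i]] <- list(keep = NULL)
    } else if (l$type == "conv") {
      d <- dim(x)
      kh <- l$kernel[1L]; kw <- l$kernel[2L]
      pad <- convPad(x, kh, kw)
      H <- d[2L]; W <- d[3L]; N <- d[4L]
      ymat <- matrix(p$b, l$filters, H * W * N)
      for (di in seq_len(kh)) for (dj in seq_len(kw)) {
        xs <- pad$xp[, di:(di + H - 1L), dj:(dj + W - 1L), , drop = FALSE]
        ymat <- ymat + crossprod(matrix(p$W[, di, dj, ], d[1L], l$filters),
                                 matrix(xs, nrow = d[1L]))
      }
      caches[[i]] <- list(xp = pad$xp, d = d)
      x <- array(ymat, c(l$filters, H, W, N))
    } else if (l$type == "pool") {
      d <- dim(x)
      ph <- l$size[1L]; pw <- l$size[2L]
      ho <- d[2L] %/% ph; wo <- d[3L] %/% pw
      first <- TRUE
      y <- NULL; winner <- NULL
      for (di in seq_len(ph)) for (dj in seq_len(pw)) {
        s <- x[, seq(di, by = ph, length.out = ho),
               seq(dj, by = pw, length.out = wo), , drop = FALSE]
        if (l$kind == "max") {
          if (first) { y <- s; winner <- array(1L, dim(s)) }
          else {
            id <- (di - 1L) * pw + dj
            upd <- s > y
            y[upd] <- s[upd]
            winner[upd] <- id
          }
        } else {
          if (first) y <- s else y <- y + s
        }
        first <- FALSE
      }
      if (l$kind == "average") y <- y / (ph * pw)
      caches[[i]] <- list(d = d, winner = winner, ho = ho, wo = wo)
      x <- y
    } else if (l$type == "flatten") {
      caches[[i]] <- list(d = dim(x))
      x <- matrix(x, ncol = dim(x)[4L])
    }
  }
  list(out = x, caches = caches, state = net$state)
}

netBackward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dx <- dOut
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    p <- net$params[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = dx %*% t(cc$x), b = rowSums(dx))
      dx <- crossprod(p$W, dx)
    } else if (l$type == "relu") {
      dx <- dx * cc$pos
    } else if (l$type == "bn") {
      dym <- if (cc$isConv) matrix(dx, nrow = dim(dx)[1L]) else dx
      grads[[i]] <- list(gamma = rowSums(dym * cc$xhat), beta = rowSums(dym))
      if (cc$train) {
        m <- ncol(dym)
        dxhat <- dym * p$gamma
        dxm <- cc$invstd / m *
          (m * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
      } else {
        dxm <- dym * p$gamma * cc$invstd
      }
      dx <- if (cc$isConv) array(dxm, cc$d) else dxm
    } else if (l$type == "dropout") {
      if (!is.null(cc$keep)) dx <- dx * cc$keep * cc$scale
    } else if (l$type == "conv") {
      d <- cc$d
      kh <- l$kernel[1L]; kw <- l$kernel[2L]
      H <- d[2L]; W <- d[3L]; N <- d[4L]
      dymat <- matrix(dx, nrow = l$filters)
      dW <- array(0, dim(p$W))
      dxp <- array(0, dim(cc$xp))
      for (di in seq_len(kh)) for (dj in seq_len(kw)) {
        xsmat <- matrix(cc$xp[, di:(di + H - 1L), dj:(dj + W - 1L), ,
                              drop = FALSE], nrow = d[1L])
        dW[, di, dj, ] <- tcrossprod(xsmat, dymat)
        dxs <- matrix(p$W[, di, dj, ], d[1L], l$filters) %*% dymat
        dxp[, di:(di + H - 1L), dj:(dj + W - 1L), ] <-
          dxp[, di:(di + H - 1L), dj:(dj + W - 1L), , drop = FALSE] +
          array(dxs, c(d[1L], H, W, N))
      }
      grads[[i]] <- list(W = dW, b = rowSums(dymat))
      pt <- (kh - 1L) %/% 2L; pl <- (kw - 1L) %/% 2L
      dx <- dxp[, pt + seq_len(H), pl + seq_len(W), , drop = FALSE]
    } else if (l$type == "pool") {
      d <- cc$d
      ph <- l$size[1L]; pw <- l$size[2L]
      dxFull <- array(0, d)
      for (di in seq_len(ph)) for (dj in seq_len(pw)) {
        id <- (di - 1L) * pw + dj
        contrib <- if (l$kind == "max") dx * (cc$winner == id)
                   else dx / (ph * pw)
        dxFull[, seq(di, by = ph, length.out = cc$ho),
               seq(dj, by = pw, length.out = cc$wo), ] <-
          dxFull[, seq(di, by = ph, length.out = cc$ho),
                 seq(dj, by = pw, length.out = cc$wo), , drop = FALSE] +
          contrib
      }
      dx <- dxFull
    } else if (l$type == "flatten") {
      dx <- array(dx, cc$d)
    }
  }
  list(grads = grads, dInput = dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamInit <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(w) list(m = w * 0, v = w * 0))
  })
}

adamStep <- function(net, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (i in seq_along(net$params)) {
    p <- net$params[[i]]
    if (is.null(p)) next
    for (nm in names(p)) {
      g <- grads[[i]][[nm]]
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$params[[i]][[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(net = net, opt = opt)
}
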