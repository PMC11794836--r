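# Minimal seeded neural-network engine (internal).
#
# No deep-learning framework ships with this R stack, so convolution is
# implemented as im2col patch gathering (a compiled index gather with a
# precomputed source-index vector) followed by dense GEMM; transposed
# convolution is the exact adjoint of a convolution geometry, reusing
# the same index vector with gather and scatter swapped.
# Sample layout: each image/feature map is one column, flattened with
# rows fastest, then columns, then channels (H, W, C).

conv_geom <- function(Hin, Win, Cin, k = 3L, s = 2L, p = 1L) {
  Hout <- (Hin + 2L * p - k) %/% s + 1L
  Wout <- (Win + 2L * p - k) %/% s + 1L
  kkC <- k * k * Cin
  g <- expand.grid(kr = seq_len(k), kc = seq_len(k), c = seq_len(Cin),
                   ho = seq_len(Hout), wo = seq_len(Wout))
  # patch-row index: kr fastest, then kc, then channel (matches W columns)
  q <- (g$c - 1L) * k * k + (g$kc - 1L) * k + g$kr
  pos <- (g$wo - 1L) * Hout + g$ho
  row <- (pos - 1L) * kkC + q
  r <- (g$ho - 1L) * s - p + g$kr
  cc <- (g$wo - 1L) * s - p + g$kc
  ok <- r >= 1L & r <= Hin & cc >= 1L & cc <= Win
  idx <- integer(kkC * Hout * Wout)            # 0 = zero-padded source
  idx[row[ok]] <- (g$c[ok] - 1L) * Hin * Win + (cc[ok] - 1L) * Hin + r[ok]
  list(Hin = Hin, Win = Win, Cin = Cin, k = k, s = s, p = p,
       Hout = Hout, Wout = Wout, kkC = kkC, idx = idx,
       D = Hin * Win * Cin)
}

act_fwd <- function(z, act, slope = 0.01) {
  switch(act,
    linear = list(a = z, d = NULL),
    relu = { d <- (z > 0) + 0; list(a = z * d, d = d) },
    lrelu = { d <- (z > 0) + slope * (z <= 0); list(a = z * d, d = d) },
    sigmoid = { a <- 1 / (1 + exp(-z)); list(a = a, d = a * (1 - a)) },
    stop("unknown activation: ", act))
}

nn_conv <- function(name, geom, Cout, act) {
  list(type = "conv", name = name, geom = geom, Cout = Cout, act = act,
       W = NULL, b = NULL)
}
nn_tconv <- function(name, geom, Csmall, act) {
  # geom maps big -> small; the layer runs small -> big (adjoint direction)
  list(type = "tconv", name = name, geom = geom, Csmall = Csmall, act = act,
       W = NULL, b = NULL)
}
nn_dense <- function(name, n_in, n_out, act) {
  list(type = "dense", name = name, n_in = n_in, n_out = n_out, act = act,
       W = NULL, b = NULL)
}
nn_dropout <- function(name, p) list(type = "dropout", name = name, p = p)

# He-normal initialization, deterministic under the caller's RNG state.
nn_init <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      l$W <- matrix(rnorm(l$Cout * l$geom$kkC, 0, sqrt(2 / l$geom$kkC)),
                    nrow = l$Cout)
      l$b <- numeric(l$Cout)
    } else if (l$type == "tconv") {
      l$W <- matrix(rnorm(l$Csmall * l$geom$kkC, 0, sqrt(2 / l$Csmall)),
                    nrow = l$Csmall)
      l$b <- numeric(l$geom$Cin)
    } else if (l$type == "dense") {
      l$W <- matrix(rnorm(l$n_out * l$n_in, 0, sqrt(2 / l$n_in)), nrow = l$n_out)
      l$b <- numeric(l$n_out)
    }
    layers[[i]] <- l
  }
  layers
}

layer_fwd <- function(l, X, train) {
  if (l$type == "conv") {
    g <- l$geom
    N <- ncol(X)
    P <- kd_gather(X, g$idx)
    dim(P) <- c(g$kkC, g$Hout * g$Wout * N)
    Z <- l$W %*% P + l$b
    dim(Z) <- c(l$Cout, g$Hout * g$Wout, N)
    Z <- aperm(Z, c(2, 1, 3))
    dim(Z) <- c(g$Hout * g$Wout * l$Cout, N)
    av <- act_fwd(Z, l$act)
    list(a = av$a, cache = list(P = P, d = av$d, N = N))
  } else if (l$type == "tconv") {
    g <- l$geom
    N <- ncol(X)
    HsWs <- g$Hout * g$Wout
    dim(X) <- c(HsWs, l$Csmall, N)
    Xs <- aperm(X, c(2, 1, 3))
    dim(Xs) <- c(l$Csmall, HsWs * N)
    U <- crossprod(l$W, Xs)
    dim(U) <- c(g$kkC * HsWs, N)
    Y <- kd_scatter(U, g$idx, g$D)
    Y <- Y + rep(l$b, each = g$Hin * g$Win)
    av <- act_fwd(Y, l$act)
    list(a = av$a, cache = list(Xs = Xs, d = av$d, N = N))
  } else if (l$type == "dense") {
    Z <- l$W %*% X + l$b
    av <- act_fwd(Z, l$act)
    list(a = av$a, cache = list(X = X, d = av$d))
  } else if (l$type == "dropout") {
    if (train && l$p > 0) {
      m <- (matrix(stats::runif(length(X)), nrow(X)) >= l$p) / (1 - l$p)
      list(a = X * m, cache = list(m = m))
    } else {
      list(a = X, cache = list(m = NULL))
    }
  } else stop("unknown layer type")
}

layer_bwd <- function(l, dA, cache) {
  if (l$type == "conv") {
    g <- l$geom
    dZ <- if (is.null(cache$d)) dA else dA * cache$d
    N <- cache$N
    dim(dZ) <- c(g$Hout * g$Wout, l$Cout, N)
    dZ <- aperm(dZ, c(2, 1, 3))
    dim(dZ) <- c(l$Cout, g$Hout * g$Wout * N)
    gW <- tcrossprod(dZ, cache$P)
    gb <- rowSums(dZ)
    dP <- crossprod(l$W, dZ)
    dim(dP) <- c(g$kkC * g$Hout * g$Wout, N)
    dX <- kd_scatter(dP, g$idx, g$D)
    list(dX = dX, gW = gW, gb = gb)
  } else if (l$type == "tconv") {
    g <- l$geom
    dZ <- if (is.null(cache$d)) dA else dA * cache$d
    N <- cache$N
    HsWs <- g$Hout * g$Wout
    sums <- matrix(rowSums(dZ), nrow = g$Hin * g$Win)
    gb <- colSums(sums)
    dU <- kd_gather(dZ, g$idx)
    dim(dU) <- c(g$kkC, HsWs * N)
    gW <- tcrossprod(cache$Xs, dU)
    dXs <- l$W %*% dU
    dim(dXs) <- c(l$Csmall, HsWs, N)
    dXs <- aperm(dXs, c(2, 1, 3))
    dim(dXs) <- c(HsWs * l$Csmall, N)
    list(dX = dXs, gW = gW, gb = gb)
  } else if (l$type == "dense") {
    dZ <- if (is.null(cache$d)) dA else dA * cache$d
    list(dX = crossprod(l$W, dZ), gW = tcrossprod(dZ, cache$X), gb = rowSums(dZ))
  } else if (l$type == "dropout") {
    list(dX = if (is.null(cache$m)) dA else dA * cache$m, gW = NULL, gb = NULL)
  }
}

net_fwd <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  A <- X
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], A, train)
    A <- r$a
    caches[[i]] <- r$cache
  }
  list(out = A, caches = caches)
}

net_bwd <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], dA, caches[[i]])
    grads[[i]] <- r[c("gW", "gb")]
    dA <- r$dX
  }
  list(dX = dA, grads = grads)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) NULL
    else list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(layers, grads, state, lr, t, trainable,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    if (is.null(state[[i]]) || !trainable[i] || is.null(grads[[i]]$gW)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[i]]$gW
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[i]]$gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[i]]$gb
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[i]]$gb^2
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

layer_params <- function(layers) {
  out <- lapply(layers, function(l) if (is.null(l$W)) NULL else list(W = l$W, b = l$b))
  names(out) <- vapply(layers, `[[`, "", "name")
  out
}

#' Flatten a list of chromosome images to a pixel matrix
#'
#' @param images List of `chromo_image` (or matrices), all 32x32.
#' @return 1024 x N numeric matrix, one image per column.
#' @export
images_to_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  mats <- lapply(images, function(im) {
    px <- if (inherits(im, "chromo_image")) im$pixels else im
    if (!all(dim(px) == c(32L, 32L))) {
      stop("images must be standardized to 32x32 first", call. = FALSE)
    }
    as.vector(px)
  })
  do.call(cbind, mats)
}

image_labels <- function(images) {
  vapply(images, function(im) isTRUE(im$is_abnormal), logical(1))
}
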