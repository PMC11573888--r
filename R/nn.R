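# Minimal CNN engine: im2col convolutions, max pooling, inception-style
# parallel-branch blocks, global average pooling, dense softmax head, and
# an Adam optimizer. Batches are H x W x C x N arrays; all heavy lifting
# is BLAS matrix products. Internal to the classifier module.

nn_conv_node <- function(kh, kw, cin, cout, pad = "same", act = "relu") {
  fan_in <- kh * kw * cin
  list(
    type = "conv", kh = kh, kw = kw, cin = cin, cout = cout, pad = pad, act = act,
    W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
    b = rep(0, cout)
  )
}

nn_dense_node <- function(din, dout) {
  list(
    type = "dense", din = din, dout = dout,
    W = matrix(rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
    b = rep(0, dout)
  )
}

nn_maxpool_node <- function() list(type = "maxpool")
nn_gap_node <- function() list(type = "gap")
nn_stem_node <- function(size) list(type = "stem", size = size)
nn_inception_node <- function(branches) list(type = "inception", branches = branches)

conv_forward <- function(x, node) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- node$kh; kw <- node$kw
  if (node$pad == "same") {
    ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
    xp <- array(0, c(H + kh - 1, W + kw - 1, C, N))
    xp[(ph + 1):(ph + H), (pw + 1):(pw + W), , ] <- x
    outH <- H; outW <- W
  } else {
    xp <- x; outH <- H - kh + 1; outW <- W - kw + 1
  }
  cols <- matrix(0, outH * outW * N, kh * kw * C)
  for (ix in seq_len(kw)) for (iy in seq_len(kh)) {
    blk <- aperm(xp[iy:(iy + outH - 1), ix:(ix + outW - 1), , , drop = FALSE], c(1, 2, 4, 3))
    idx <- (ix - 1) * kh + iy
    cols[, ((idx - 1) * C + 1):(idx * C)] <- matrix(blk, outH * outW * N, C)
  }
  z <- cols %*% node$W
  z <- z + rep(node$b, each = nrow(z))
  a <- if (node$act == "relu") pmax(z, 0) else z
  out <- aperm(array(a, c(outH, outW, N, node$cout)), c(1, 2, 4, 3))
  list(out = out, cache = list(cols = cols, z = z, in_dim = d, xp_dim = dim(xp),
                               outH = outH, outW = outW))
}

conv_backward <- function(dout, node, cache) {
  N <- cache$in_dim[4]; C <- cache$in_dim[3]
  kh <- node$kh; kw <- node$kw
  outH <- cache$outH; outW <- cache$outW
  dmat <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = node$cout)
  if (node$act == "relu") dmat <- dmat * (cache$z > 0)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, node$W)
  dxp <- array(0, cache$xp_dim)
  for (ix in seq_len(kw)) for (iy in seq_len(kh)) {
    idx <- (ix - 1) * kh + iy
    blk <- array(dcols[, ((idx - 1) * C + 1):(idx * C)], c(outH, outW, N, C))
    dxp[iy:(iy + outH - 1), ix:(ix + outW - 1), , ] <-
      dxp[iy:(iy + outH - 1), ix:(ix + outW - 1), , ] + aperm(blk, c(1, 2, 4, 3))
  }
  if (node$pad == "same") {
    ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
    H <- cache$in_dim[1]; W <- cache$in_dim[2]
    dx <- dxp[(ph + 1):(ph + H), (pw + 1):(pw + W), , , drop = FALSE]
  } else {
    dx <- dxp
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1, d[1], 2); re <- ro + 1
  co <- seq(1, d[2], 2); ce <- co + 1
  s <- list(
    x[ro, co, , , drop = FALSE], x[ro, ce, , , drop = FALSE],
    x[re, co, , , drop = FALSE], x[re, ce, , , drop = FALSE]
  )
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(out = m, cache = list(slices = s, m = m, in_dim = d))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  ro <- seq(1, d[1], 2); re <- ro + 1
  co <- seq(1, d[2], 2); ce <- co + 1
  used <- array(FALSE, dim(cache$m))
  idx <- list(list(ro, co), list(ro, ce), list(re, co), list(re, ce))
  for (k in 1:4) {
    mask <- (cache$slices[[k]] == cache$m) & !used # route ties to first slice
    used <- used | mask
    dx[idx[[k]][[1]], idx[[k]][[2]], , ] <- mask * dout
  }
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  out <- apply(x, c(3, 4), mean) # (C, N)
  list(out = t(out), cache = list(in_dim = d)) # (N, C)
}

gap_backward <- function(dout, cache) {
  d <- cache$in_dim
  g <- t(dout) / (d[1] * d[2]) # (C, N)
  array(rep(g, each = d[1] * d[2]), d)
}

dense_forward <- function(x, node) { # x: (N, din)
  z <- x %*% node$W + rep(node$b, each = nrow(x))
  list(out = z, cache = list(x = x))
}

dense_backward <- function(dout, node, cache) {
  list(
    dx = tcrossprod(dout, node$W),
    grads = list(W = crossprod(cache$x, dout), b = colSums(dout))
  )
}

stem_forward <- function(x, node) {
  d <- dim(x)
  if (d[1] == node$size) return(x)
  f <- d[1] / node$size
  if (f != round(f)) abort("input size incompatible with model stem")
  out <- array(0, c(node$size, d[2] %/% f, d[3], d[4]))
  for (n in seq_len(d[4])) out[, , , n] <- pool_array(x[, , , n], as.integer(f))
  out
}

node_forward <- function(node, x) {
  switch(node$type,
    stem = list(out = stem_forward(x, node), cache = NULL),
    conv = conv_forward(x, node),
    maxpool = maxpool_forward(x),
    gap = gap_forward(x),
    dense = dense_forward(x, node),
    inception = {
      outs <- list(); caches <- list()
      for (bi in seq_along(node$branches)) {
        h <- x; bc <- list()
        for (li in seq_along(node$branches[[bi]])) {
          r <- conv_forward(h, node$branches[[bi]][[li]])
          h <- r$out; bc[[li]] <- r$cache
        }
        outs[[bi]] <- h; caches[[bi]] <- bc
      }
      ch <- vapply(outs, function(o) dim(o)[3], numeric(1))
      d1 <- dim(outs[[1]])
      cat_out <- array(0, c(d1[1], d1[2], sum(ch), d1[4]))
      at <- 0
      for (bi in seq_along(outs)) {
        cat_out[, , (at + 1):(at + ch[bi]), ] <- outs[[bi]]
        at <- at + ch[bi]
      }
      list(out = cat_out, cache = list(branch_caches = caches, ch = ch))
    },
    abort(sprintf("unknown node type '%s'", node$type))
  )
}

node_backward <- function(node, dout, cache) {
  switch(node$type,
    stem = list(dx = NULL, grads = NULL), # preprocessing layer; no gradient needed
    conv = conv_backward(dout, node, cache),
    maxpool = list(dx = maxpool_backward(dout, cache), grads = NULL),
    gap = list(dx = gap_backward(dout, cache), grads = NULL),
    dense = dense_backward(dout, node, cache),
    inception = {
      at <- 0; dx <- NULL; grads <- list()
      for (bi in seq_along(node$branches)) {
        dbr <- dout[, , (at + 1):(at + cache$ch[bi]), , drop = FALSE]
        at <- at + cache$ch[bi]
        bg <- list()
        for (li in rev(seq_along(node$branches[[bi]]))) {
          r <- conv_backward(dbr, node$branches[[bi]][[li]], cache$branch_caches[[bi]][[li]])
          dbr <- r$dx; bg[[li]] <- r$grads
        }
        grads[[bi]] <- bg
        dx <- if (is.null(dx)) dbr else dx + dbr
      }
      list(dx = dx, grads = grads)
    }
  )
}

nn_forward <- function(nodes, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(nodes)) else NULL
  for (i in seq_along(nodes)) {
    r <- node_forward(nodes[[i]], x)
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

softmax_probs <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and gradient wrt logits; y is an N-vector of 1-based
# class indices
softmax_ce <- function(z, y) {
  p <- softmax_probs(z)
  n <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  dz <- p
  dz[cbind(seq_len(n), y)] <- dz[cbind(seq_len(n), y)] - 1
  list(loss = loss, dz = dz / n, probs = p)
}

nn_backward <- function(nodes, caches, dz) {
  grads <- vector("list", length(nodes))
  dout <- dz
  for (i in rev(seq_along(nodes))) {
    r <- node_backward(nodes[[i]], dout, caches[[i]])
    grads[i] <- list(r$grads) # [[<-]] with NULL would drop the slot
    dout <- r$dx
    if (is.null(dout) && i > 1) break # stem reached; nothing below has parameters
  }
  grads
}

# flatten node parameters / gradients into a named list of arrays
collect_params <- function(nodes, grads = NULL) {
  out <- list()
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    g <- if (is.null(grads)) NULL else grads[[i]]
    if (nd$type %in% c("conv", "dense")) {
      src <- if (is.null(grads)) nd else g
      out[[paste0("n", i, ".W")]] <- src$W
      out[[paste0("n", i, ".b")]] <- src$b
    } else if (nd$type == "inception") {
      for (bi in seq_along(nd$branches)) for (li in seq_along(nd$branches[[bi]])) {
        src <- if (is.null(grads)) nd$branches[[bi]][[li]] else g[[bi]][[li]]
        out[[paste0("n", i, ".b", bi, ".l", li, ".W")]] <- src$W
        out[[paste0("n", i, ".b", bi, ".l", li, ".b")]] <- src$b
      }
    }
  }
  out
}

assign_params <- function(nodes, params) {
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$type %in% c("conv", "dense")) {
      nodes[[i]]$W <- params[[paste0("n", i, ".W")]]
      nodes[[i]]$b <- params[[paste0("n", i, ".b")]]
    } else if (nd$type == "inception") {
      for (bi in seq_along(nd$branches)) for (li in seq_along(nd$branches[[bi]])) {
        nodes[[i]]$branches[[bi]][[li]]$W <- params[[paste0("n", i, ".b", bi, ".l", li, ".W")]]
        nodes[[i]]$branches[[bi]][[li]]$b <- params[[paste0("n", i, ".b", bi, ".l", li, ".b")]]
      }
    }
  }
  nodes
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
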