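# Minimal dense neural-network engine used by the TRM and the backbones.
#
# Tensors are numeric arrays with dims (channels, height, width, batch); all
# heavy lifting is im2col gathers plus BLAS matrix products. Each layer is an
# environment exposing a common closure interface:
#   fw(x, training)   forward pass, caches what backward needs
#   bw(g)             backward pass, fills $grads, returns grad wrt input
#   init()            (re)initialise trainable values using the current RNG
#   params()/grads()  named lists of arrays (same shapes)
#   set_params(p)     overwrite trainable values
#   state()/set_state(s)  non-trainable buffers (batch-norm running stats)
# Gradients of every layer are validated against central finite differences in
# the test suite; nothing here is stochastic except dropout and init().

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- function() list()
  e$grads <- function() list()
  e$set_params <- function(p) invisible(NULL)
  e$init <- function() invisible(NULL)
  e$state <- function() list()
  e$set_state <- function(s) invisible(NULL)
  class(e) <- "nn_layer"
  e
}

# im2col index table for a (Cin, H, W) volume and a (kh, kw) kernel with
# strides (sh, sw): K x P matrix of linear indices, K = Cin*kh*kw ordered
# channel-fastest, P = Ho*Wo ordered row-fastest.
im2col_idx <- function(Cin, H, W, kh, kw, sh = 1L, sw = 1L) {
  Ho <- (H - kh) %/% sh + 1L
  Wo <- (W - kw) %/% sw + 1L
  ci <- rep.int(seq_len(Cin), kh * kw)
  di <- rep(rep(seq_len(kh) - 1L, each = Cin), kw)
  dj <- rep(seq_len(kw) - 1L, each = Cin * kh)
  base_k <- ci + di * Cin + dj * (Cin * H)
  ho <- rep.int(seq_len(Ho), Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  off_p <- (ho - 1L) * sh * Cin + (wo - 1L) * sw * (Cin * H)
  list(idx = outer(base_k, off_p, `+`), Ho = Ho, Wo = Wo,
       K = Cin * kh * kw, P = Ho * Wo)
}

pad_hw <- function(x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * ph, d[3L] + 2L * pw, d[4L]))
  xp[, ph + seq_len(d[2L]), pw + seq_len(d[3L]), ] <- x
  xp
}

unpad_hw <- function(x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  x[, ph + seq_len(d[2L] - 2L * ph), pw + seq_len(d[3L] - 2L * pw), ,
    drop = FALSE]
}

# scatter-add of an im2col gradient back onto the input volume
col2im_add <- function(dXc, idxv, nrow_out) {
  agg <- rowsum(dXc, group = idxv, reorder = FALSE)
  out <- matrix(0, nrow_out, ncol(dXc))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' 2-D convolution layer (valid or zero-padded, strided, optionally grouped)
#' @keywords internal
nn_conv2d <- function(in_ch, out_ch, kh, kw, stride = c(1L, 1L),
                      pad = c(0L, 0L), bias = TRUE, groups = 1L) {
  stopifnot(in_ch %% groups == 0L, out_ch %% groups == 0L)
  L <- new_layer("conv2d")
  L$in_ch <- as.integer(in_ch); L$out_ch <- as.integer(out_ch)
  L$kh <- as.integer(kh); L$kw <- as.integer(kw)
  L$sh <- as.integer(stride[1L]); L$sw <- as.integer(stride[2L])
  L$ph <- as.integer(pad[1L]); L$pw <- as.integer(pad[2L])
  L$groups <- as.integer(groups)
  L$cig <- L$in_ch %/% L$groups          # input channels per group
  L$cog <- L$out_ch %/% L$groups
  L$Kg <- L$cig * L$kh * L$kw            # im2col rows per group
  L$has_bias <- isTRUE(bias)

  L$init <- function() {
    bound <- 1 / sqrt(L$Kg)
    L$W <- matrix(stats::runif(L$Kg * L$out_ch, -bound, bound), L$Kg, L$out_ch)
    if (L$has_bias) L$b <- stats::runif(L$out_ch, -bound, bound)
    invisible(NULL)
  }
  L$init()

  L$params <- function() {
    if (L$has_bias) list(W = L$W, b = L$b) else list(W = L$W)
  }
  L$grads <- function() {
    if (L$has_bias) list(W = L$dW, b = L$db) else list(W = L$dW)
  }
  L$set_params <- function(p) {
    L$W <- p$W
    if (L$has_bias) L$b <- p$b
    invisible(NULL)
  }

  L$fw <- function(x, training = FALSE) {
    x <- pad_hw(x, L$ph, L$pw)
    d <- dim(x)
    if (d[1L] != L$in_ch)
      stop_eegtrm("conv2d: expected %d input channels, got %d",
                  L$in_ch, d[1L], class = "eegtrm_shape_error")
    key <- paste(d[2L], d[3L], sep = "x")
    if (is.null(L$ii) || !identical(L$ii_key, key)) {
      L$ii <- im2col_idx(L$cig, d[2L], d[3L], L$kh, L$kw, L$sh, L$sw)
      L$ii_key <- key
    }
    ii <- L$ii; N <- d[4L]
    L$in_dim <- d
    PN <- ii$P * N
    out <- matrix(0, L$out_ch, PN)
    L$Xc <- vector("list", L$groups)
    idxv <- as.vector(ii$idx)
    for (g in seq_len(L$groups)) {
      crows <- (g - 1L) * L$cig + seq_len(L$cig)
      xg <- if (L$groups == 1L) x else x[crows, , , , drop = FALSE]
      Xm <- matrix(xg, L$cig * d[2L] * d[3L], N)
      Xc <- Xm[idxv, , drop = FALSE]
      dim(Xc) <- c(ii$K, PN)
      L$Xc[[g]] <- Xc
      orows <- (g - 1L) * L$cog + seq_len(L$cog)
      out[orows, ] <- crossprod(L$W[, orows, drop = FALSE], Xc)
    }
    if (L$has_bias) out <- out + L$b
    dim(out) <- c(L$out_ch, ii$Ho, ii$Wo, N)
    out
  }

  L$bw <- function(g) {
    ii <- L$ii; d <- L$in_dim; N <- d[4L]
    gm <- matrix(g, L$out_ch, ii$P * N)
    L$dW <- matrix(0, L$Kg, L$out_ch)
    if (L$has_bias) L$db <- rowSums(gm)
    dx <- array(0, d)
    idxv <- as.vector(ii$idx)
    chw <- L$cig * d[2L] * d[3L]
    for (gi in seq_len(L$groups)) {
      orows <- (gi - 1L) * L$cog + seq_len(L$cog)
      gg <- gm[orows, , drop = FALSE]
      L$dW[, orows] <- tcrossprod(L$Xc[[gi]], gg)
      dXc <- L$W[, orows, drop = FALSE] %*% gg
      dim(dXc) <- c(ii$K * ii$P, N)
      dXm <- col2im_add(dXc, idxv, chw)
      if (L$groups == 1L) {
        dx <- array(dXm, d)
      } else {
        crows <- (gi - 1L) * L$cig + seq_len(L$cig)
        dx[crows, , , ] <- array(dXm, c(L$cig, d[2L], d[3L], N))
      }
    }
    L$Xc <- NULL
    unpad_hw(dx, L$ph, L$pw)
  }
  L
}

#' Batch normalization over the channel dimension
#'
#' Normalizes per channel across all remaining dimensions (spatial positions
#' and batch). Running statistics are buffers, not trainable parameters.
#' @keywords internal
nn_batchnorm <- function(ch, eps = 1e-5, momentum = 0.1, affine = TRUE) {
  L <- new_layer("batchnorm")
  L$ch <- as.integer(ch); L$eps <- eps; L$mom <- momentum
  L$affine <- isTRUE(affine)
  L$init <- function() {
    if (L$affine) { L$gamma <- rep(1, L$ch); L$beta <- rep(0, L$ch) }
    L$run_mean <- rep(0, L$ch); L$run_var <- rep(1, L$ch)
    invisible(NULL)
  }
  L$init()
  L$params <- function() if (L$affine) list(gamma = L$gamma, beta = L$beta) else list()
  L$grads <- function() if (L$affine) list(gamma = L$dgamma, beta = L$dbeta) else list()
  L$set_params <- function(p) {
    if (L$affine) { L$gamma <- p$gamma; L$beta <- p$beta }
    invisible(NULL)
  }
  L$state <- function() list(run_mean = L$run_mean, run_var = L$run_var)
  L$set_state <- function(s) {
    L$run_mean <- s$run_mean; L$run_var <- s$run_var
    invisible(NULL)
  }

  L$fw <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- matrix(x, L$ch, prod(d) / L$ch)
    M <- ncol(xm)
    if (training) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc * xc)
      if (M > 1L) {
        L$run_mean <- (1 - L$mom) * L$run_mean + L$mom * mu
        L$run_var <- (1 - L$mom) * L$run_var + L$mom * v * M / (M - 1L)
      }
    } else {
      mu <- L$run_mean
      xc <- xm - mu
      v <- L$run_var
    }
    s <- sqrt(v + L$eps)
    xhat <- xc / s
    L$cache <- list(xhat = xhat, s = s, M = M, training = training, dims = d)
    y <- if (L$affine) xhat * L$gamma + L$beta else xhat
    dim(y) <- d
    y
  }

  L$bw <- function(g) {
    cc <- L$cache
    gm <- matrix(g, L$ch, cc$M)
    if (L$affine) {
      L$dgamma <- rowSums(gm * cc$xhat)
      L$dbeta <- rowSums(gm)
      dxhat <- gm * L$gamma
    } else dxhat <- gm
    if (cc$training) {
      dx <- (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat)) / cc$s
    } else {
      dx <- dxhat / cc$s
    }
    dim(dx) <- cc$dims
    L$cache <- NULL
    dx
  }
  L
}

#' Elementwise activation layer: elu, square, safe log or identity
#' @keywords internal
nn_activation <- function(type = c("elu", "square", "log", "identity"),
                          eps = 1e-6) {
  type <- match.arg(type)
  L <- new_layer(paste0("act_", type))
  L$type <- type; L$eps <- eps
  L$fw <- function(x, training = FALSE) {
    y <- switch(type,
      elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
      square = x * x,
      log = log(pmax(x, eps)),
      identity = x)
    L$cache <- list(x = x, y = y)
    y
  }
  L$bw <- function(g) {
    cc <- L$cache; L$cache <- NULL
    switch(type,
      elu = g * ifelse(cc$x > 0, 1, cc$y + 1),
      square = g * 2 * cc$x,
      log = g * ifelse(cc$x > eps, 1 / cc$x, 0),
      identity = g)
  }
  L
}

# shared spatial gather for pooling: (C,H,W,N) -> columns (K, P*C*N)
pool_gather <- function(L, x) {
  d <- dim(x)
  key <- paste(d[2L], d[3L], sep = "x")
  if (is.null(L$ii) || !identical(L$ii_key, key)) {
    L$ii <- im2col_idx(1L, d[2L], d[3L], L$kh, L$kw, L$sh, L$sw)
    L$ii_key <- key
  }
  xp <- aperm(x, c(2L, 3L, 1L, 4L))                 # (H, W, C, N)
  Xm <- matrix(xp, d[2L] * d[3L], d[1L] * d[4L])
  Xc <- Xm[as.vector(L$ii$idx), , drop = FALSE]     # (K*P, C*N)
  dim(Xc) <- c(L$ii$K, L$ii$P * d[1L] * d[4L])      # cols ordered (p, c, n)
  list(Xc = Xc, d = d)
}

pool_scatter <- function(L, dXc_cols, d) {
  # dXc_cols: (K, P*C*N) gradient wrt gathered columns
  dim(dXc_cols) <- c(L$ii$K * L$ii$P, d[1L] * d[4L])
  dXm <- col2im_add(dXc_cols, as.vector(L$ii$idx), d[2L] * d[3L])
  dxp <- array(dXm, c(d[2L], d[3L], d[1L], d[4L]))
  aperm(dxp, c(3L, 1L, 2L, 4L))
}

#' Average pooling layer
#' @keywords internal
nn_avgpool <- function(kh, kw, sh = kh, sw = kw) {
  L <- new_layer("avgpool")
  L$kh <- as.integer(kh); L$kw <- as.integer(kw)
  L$sh <- as.integer(sh); L$sw <- as.integer(sw)
  L$fw <- function(x, training = FALSE) {
    pg <- pool_gather(L, x)
    L$in_dim <- pg$d
    y <- colMeans(pg$Xc)                            # (P*C*N), order (p, c, n)
    ya <- array(y, c(L$ii$Ho, L$ii$Wo, pg$d[1L], pg$d[4L]))
    aperm(ya, c(3L, 1L, 2L, 4L))
  }
  L$bw <- function(g) {
    d <- L$in_dim
    gp <- aperm(g, c(2L, 3L, 1L, 4L))               # (Ho, Wo, C, N)
    gv <- as.vector(gp) / L$ii$K
    dXc <- matrix(rep(gv, each = L$ii$K), L$ii$K)
    pool_scatter(L, dXc, d)
  }
  L
}

#' Max pooling layer (non-overlapping windows)
#' @keywords internal
nn_maxpool <- function(kh, kw, sh = kh, sw = kw) {
  stopifnot(sh >= kh, sw >= kw)   # backward assumes disjoint windows
  L <- new_layer("maxpool")
  L$kh <- as.integer(kh); L$kw <- as.integer(kw)
  L$sh <- as.integer(sh); L$sw <- as.integer(sw)
  L$fw <- function(x, training = FALSE) {
    pg <- pool_gather(L, x)
    L$in_dim <- pg$d
    Xc <- pg$Xc
    mx <- Xc[1L, ]; am <- rep.int(1L, ncol(Xc))
    if (L$ii$K > 1L) for (k in 2L:L$ii$K) {
      hit <- Xc[k, ] > mx
      mx[hit] <- Xc[k, hit]; am[hit] <- k
    }
    L$am <- am
    ya <- array(mx, c(L$ii$Ho, L$ii$Wo, pg$d[1L], pg$d[4L]))
    aperm(ya, c(3L, 1L, 2L, 4L))
  }
  L$bw <- function(g) {
    d <- L$in_dim; ii <- L$ii
    gp <- aperm(g, c(2L, 3L, 1L, 4L))
    gv <- as.vector(gp)                              # order (p, c, n)
    ncols <- length(gv)
    p_of <- ((seq_len(ncols) - 1L) %% ii$P) + 1L
    cn_of <- ((seq_len(ncols) - 1L) %/% ii$P) + 1L
    rows <- ii$idx[cbind(L$am, p_of)]                # spatial linear index
    lin <- rows + (cn_of - 1L) * (d[2L] * d[3L])
    dXm <- numeric(d[2L] * d[3L] * d[1L] * d[4L])
    dXm[lin] <- gv                                   # windows disjoint
    dxp <- array(dXm, c(d[2L], d[3L], d[1L], d[4L]))
    aperm(dxp, c(3L, 1L, 2L, 4L))
  }
  L
}

#' Dropout layer
#' @keywords internal
nn_dropout <- function(p = 0.5) {
  L <- new_layer("dropout")
  L$p <- p
  L$fw <- function(x, training = FALSE) {
    if (!training || L$p <= 0) { L$mask <- NULL; return(x) }
    m <- array(stats::runif(length(x)) >= L$p, dim(x)) / (1 - L$p)
    L$mask <- m
    x * m
  }
  L$bw <- function(g) if (is.null(L$mask)) g else g * L$mask
  L
}

#' Flatten (C,H,W,N) to a (C*H*W, N) matrix
#' @keywords internal
nn_flatten <- function() {
  L <- new_layer("flatten")
  L$fw <- function(x, training = FALSE) {
    L$in_dim <- dim(x)
    matrix(x, prod(L$in_dim[1:3]), L$in_dim[4L])
  }
  L$bw <- function(g) array(g, L$in_dim)
  L
}

#' Fully connected layer on (features, batch) matrices
#' @keywords internal
nn_linear <- function(in_f, out_f, bias = TRUE) {
  L <- new_layer("linear")
  L$in_f <- as.integer(in_f); L$out_f <- as.integer(out_f)
  L$has_bias <- isTRUE(bias)
  L$init <- function() {
    bound <- 1 / sqrt(L$in_f)
    L$W <- matrix(stats::runif(L$in_f * L$out_f, -bound, bound), L$in_f, L$out_f)
    if (L$has_bias) L$b <- stats::runif(L$out_f, -bound, bound)
    invisible(NULL)
  }
  L$init()
  L$params <- function() if (L$has_bias) list(W = L$W, b = L$b) else list(W = L$W)
  L$grads <- function() if (L$has_bias) list(W = L$dW, b = L$db) else list(W = L$dW)
  L$set_params <- function(p) {
    L$W <- p$W; if (L$has_bias) L$b <- p$b
    invisible(NULL)
  }
  L$fw <- function(x, training = FALSE) {
    L$x <- x
    y <- crossprod(L$W, x)
    if (L$has_bias) y <- y + L$b
    y
  }
  L$bw <- function(g) {
    L$dW <- tcrossprod(L$x, g)
    if (L$has_bias) L$db <- rowSums(g)
    L$x <- NULL
    L$W %*% g
  }
  L
}

# ---- model-level helpers -----------------------------------------------

seq_forward <- function(layers, x, training = FALSE) {
  for (L in layers) x <- L$fw(x, training)
  x
}

seq_backward <- function(layers, g) {
  for (L in rev(layers)) g <- L$bw(g)
  g
}

seq_param_count <- function(layers) {
  sum(vapply(layers, function(L) sum(vapply(L$params(), length, 0L)), 0))
}

seq_get_state <- function(layers) {
  lapply(layers, function(L) list(params = L$params(), state = L$state()))
}

seq_set_state <- function(layers, st) {
  for (i in seq_along(layers)) {
    if (length(st[[i]]$params)) layers[[i]]$set_params(st[[i]]$params)
    if (length(st[[i]]$state)) layers[[i]]$set_state(st[[i]]$state)
  }
  invisible(NULL)
}

seq_init <- function(layers) {
  for (L in layers) L$init()
  invisible(NULL)
}

#' Softmax cross-entropy loss and gradient
#'
#' @param scores (n_classes, batch) matrix of unnormalized scores.
#' @param y integer class labels in 1..n_classes.
#' @return list(loss, grad) with grad on the score scale (mean reduction).
#' @keywords internal
softmax_xent <- function(scores, y) {
  n <- ncol(scores)
  sm <- sweep(scores, 2L, apply(scores, 2L, max))
  es <- exp(sm)
  p <- sweep(es, 2L, colSums(es), `/`)
  iy <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(p[iy], 1e-12)))
  g <- p
  g[iy] <- g[iy] - 1
  list(loss = loss, grad = g / n)
}

#' Adam optimizer state for a list of layers
#' @keywords internal
adam_new <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$b1 <- beta1; opt$b2 <- beta2
  opt$eps <- eps; opt$wd <- weight_decay; opt$t <- 0L
  opt$m <- lapply(layers, function(L) lapply(L$params(), function(p) p * 0))
  opt$v <- opt$m
  opt
}

adam_step <- function(layers, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(layers)) {
    ps <- layers[[i]]$params()
    if (!length(ps)) next
    gs <- layers[[i]]$grads()
    for (nm in names(ps)) {
      g <- gs[[nm]]
      if (opt$wd > 0) g <- g + opt$wd * ps[[nm]]
      opt$m[[i]][[nm]] <- opt$b1 * opt$m[[i]][[nm]] + (1 - opt$b1) * g
      opt$v[[i]][[nm]] <- opt$b2 * opt$v[[i]][[nm]] + (1 - opt$b2) * g * g
      mhat <- opt$m[[i]][[nm]] / bc1
      vhat <- opt$v[[i]][[nm]] / bc2
      ps[[nm]] <- ps[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
    layers[[i]]$set_params(ps)
  }
  invisible(NULL)
}
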