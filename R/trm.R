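#' Plan the convolution kernel schedule for a grid
#'
#' Starting from the full H x W grid, each layer applies a valid (unpadded,
#' stride-1) 2-D convolution. While at least one feature-map dimension still
#' exceeds the base kernel size k, the layer uses a kernel of
#' (min(k, h), min(k, w)); once the feature map is no larger than k x k, a
#' single kernel of exactly the feature-map size finishes the reduction, so
#' the schedule always terminates at a 1 x 1 map.
#'
#' @param H,W grid rows and columns (integers >= 1).
#' @param k base kernel size, normally 3 or 5 (other odd values are accepted
#'   with a warning).
#' @return an object of class `kernel_schedule` with elements `base_kernel`,
#'   `layers` (list of c(kh, kw)), `feature_maps` (list of c(h, w) after each
#'   layer) and `input_grid`.
#' @export
#' @examples
#' plan_schedule(7, 9, 5)   # [(5,5), (3,5)] -> 1 x 1
#' plan_schedule(7, 7, 3)   # [(3,3), (3,3), (3,3)]
plan_schedule <- function(H, W, k = 5L) {
  H <- as.integer(H); W <- as.integer(W); k <- as.integer(k)
  if (is.na(H) || is.na(W) || H < 1L || W < 1L)
    stop_eegtrm("grid dimensions must be >= 1 (got %s x %s)", H, W,
                class = "eegtrm_domain_error")
  if (is.na(k) || k < 1L || k %% 2L == 0L)
    stop_eegtrm("base kernel size must be a positive odd integer (got %s)", k,
                class = "eegtrm_domain_error")
  if (!k %in% c(3L, 5L))
    warning(sprintf("base kernel %d is nonstandard (typical choices: 3, 5)", k))
  layers <- list(); fmaps <- list()
  h <- H; w <- W
  repeat {
    if (h > k || w > k) kern <- c(min(k, h), min(k, w))
    else kern <- c(h, w)
    h <- h - kern[1L] + 1L
    w <- w - kern[2L] + 1L
    layers[[length(layers) + 1L]] <- kern
    fmaps[[length(fmaps) + 1L]] <- c(h, w)
    if (h == 1L && w == 1L) break
  }
  structure(list(base_kernel = k, layers = layers, feature_maps = fmaps,
                 input_grid = c(H, W)),
            class = "kernel_schedule")
}

#' @export
print.kernel_schedule <- function(x, ...) {
  cat(sprintf("<kernel_schedule> %d x %d grid, base kernel %d\n",
              x$input_grid[1L], x$input_grid[2L], x$base_kernel))
  for (i in seq_along(x$layers))
    cat(sprintf("  layer %d: kernel %d x %d -> feature map %d x %d\n", i,
                x$layers[[i]][1L], x$layers[[i]][2L],
                x$feature_maps[[i]][1L], x$feature_maps[[i]][2L]))
  invisible(x)
}

#' Specify a TRM configuration and its closed-form parameter count
#'
#' Under the default policy the convolutions carry no additive bias and a
#' single affine channel normalization follows the full stack, giving
#' `C*k1h*k1w + sum_{l>=2} C^2*klh*klw + 2C` trainable parameters (the first
#' layer sees one input channel; every layer outputs C channels).
#'
#' @param montage a [montage_grid].
#' @param k base kernel size (3 or 5).
#' @param conv_bias add a bias term to every convolution (non-default).
#' @param norm_policy `"final-affine"` (default: one affine batch norm over
#'   the C output channels after the stack), `"per-layer-affine"` (an affine
#'   batch norm after every convolution) or `"none"`.
#' @return an object of class `trm_spec` with the derived `schedule` and
#'   `trainable_parameter_count`.
#' @export
trm_spec <- function(montage, k = 5L, conv_bias = FALSE,
                     norm_policy = c("final-affine", "per-layer-affine",
                                     "none")) {
  norm_policy <- match.arg(norm_policy)
  schedule <- plan_schedule(montage$height, montage$width, k)
  C <- length(montage$channel_names)
  ks <- vapply(schedule$layers, prod, 0)
  n_layers <- length(ks)
  count <- C * ks[1L] + if (n_layers > 1L) sum(C * C * ks[-1L]) else 0
  if (conv_bias) count <- count + C * n_layers
  count <- count + switch(norm_policy,
                          "final-affine" = 2 * C,
                          "per-layer-affine" = 2 * C * n_layers,
                          "none" = 0)
  structure(list(montage = montage, channels = C, schedule = schedule,
                 conv_bias = conv_bias, norm_policy = norm_policy,
                 trainable_parameter_count = as.integer(count)),
            class = "trm_spec")
}

#' @export
print.trm_spec <- function(x, ...) {
  cat(sprintf(
    "<trm_spec> TRM-(%d,%d) for '%s': C=%d, %d conv layers, %d parameters\n",
    x$schedule$base_kernel, x$schedule$base_kernel, x$montage$name,
    x$channels, length(x$schedule$layers), x$trainable_parameter_count))
  invisible(x)
}

#' Count trainable parameters
#'
#' For a `trm_spec` this evaluates the closed form; for assembled modules and
#' networks it enumerates every trainable array of the built layers. The two
#' routes agree exactly (a property the test suite asserts).
#'
#' @param x a `trm_spec`, `trm_module` or `eeg_network`.
#' @return integer parameter total.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.trm_spec <- function(x) x$trainable_parameter_count

#' @export
count_parameters.trm_module <- function(x) as.integer(seq_param_count(x$layers))

#' @export
count_parameters.eeg_network <- function(x) as.integer(seq_param_count(x$layers))

# ---- TRM assembly -------------------------------------------------------

# Composite engine layer: topographic mapping + conv stack + normalization +
# reshape. Engine tensor contract: (1, C, TP, N) -> (1, C, TP, N); the 2-D
# convolutions act per time slice with time folded into the batch axis.
trm_engine_layers <- function(spec, activation = "identity") {
  C <- spec$channels
  sched <- spec$schedule$layers
  layers <- list()
  in_ch <- 1L
  for (i in seq_along(sched)) {
    layers[[length(layers) + 1L]] <-
      nn_conv2d(in_ch, C, sched[[i]][1L], sched[[i]][2L],
                bias = spec$conv_bias)
    if (spec$norm_policy == "per-layer-affine")
      layers[[length(layers) + 1L]] <- nn_batchnorm(C)
    if (activation != "identity" && i < length(sched))
      layers[[length(layers) + 1L]] <- nn_activation(activation)
    in_ch <- C
  }
  if (spec$norm_policy == "final-affine")
    layers[[length(layers) + 1L]] <- nn_batchnorm(C)
  layers
}

nn_trm <- function(spec, activation = "identity") {
  L <- new_layer("trm")
  L$spec <- spec
  L$C <- spec$channels
  L$H <- spec$montage$height; L$W <- spec$montage$width
  L$cell <- montage_cell_index(spec$montage)
  L$inner <- trm_engine_layers(spec, activation)

  L$init <- function() seq_init(L$inner)
  L$params <- function() {
    ps <- lapply(L$inner, function(l) l$params())
    stats::setNames(unlist(ps, recursive = FALSE),
                    unlist(lapply(seq_along(ps), function(i)
                      if (length(ps[[i]])) paste0("L", i, ".", names(ps[[i]]))
                      else character(0))))
  }
  L$grads <- function() {
    gs <- lapply(L$inner, function(l) l$grads())
    stats::setNames(unlist(gs, recursive = FALSE),
                    unlist(lapply(seq_along(gs), function(i)
                      if (length(gs[[i]])) paste0("L", i, ".", names(gs[[i]]))
                      else character(0))))
  }
  L$set_params <- function(p) {
    for (i in seq_along(L$inner)) {
      nm <- names(L$inner[[i]]$params())
      if (length(nm))
        L$inner[[i]]$set_params(stats::setNames(
          p[paste0("L", i, ".", nm)], nm))
    }
    invisible(NULL)
  }
  L$state <- function() lapply(L$inner, function(l) l$state())
  L$set_state <- function(s) {
    for (i in seq_along(L$inner))
      if (length(s[[i]])) L$inner[[i]]$set_state(s[[i]])
    invisible(NULL)
  }

  L$fw <- function(x, training = FALSE) {
    d <- dim(x)                             # (1, C, TP, N)
    if (d[1L] != 1L || d[2L] != L$C)
      stop_eegtrm("TRM expects %d input channels, got %d", L$C, d[2L],
                  class = "eegtrm_shape_error")
    TPN <- d[3L] * d[4L]
    topo <- matrix(0, L$H * L$W, TPN)
    topo[L$cell, ] <- x                     # (C, TP*N) by column-major layout
    dim(topo) <- c(1L, L$H, L$W, TPN)
    y <- seq_forward(L$inner, topo, training)   # (C, 1, 1, TP*N)
    dim(y) <- c(1L, L$C, d[3L], d[4L])
    L$in_dim <- d
    y
  }

  L$bw <- function(g) {
    d <- L$in_dim
    dim(g) <- c(L$C, 1L, 1L, d[3L] * d[4L])
    gt <- seq_backward(L$inner, g)          # (1, H, W, TP*N)
    dim(gt) <- c(L$H * L$W, d[3L] * d[4L])
    gx <- gt[L$cell, , drop = FALSE]
    dim(gx) <- d
    gx
  }
  L
}

#' Build a trainable TRM
#'
#' Assembles the full module: topographic mapping of each epoch onto the
#' montage grid, the scheduled stack of valid 2-D convolutions applied
#' identically at every time point (time folded into the batch axis; the
#' first layer sees one input channel, all layers output C channels),
#' normalization per `norm_policy`, and a reshape back to C x TP. Output
#' shape equals input shape for every batch size and TP >= 1.
#'
#' @inheritParams trm_spec
#' @param activation optional elementwise nonlinearity between convolution
#'   layers (`"identity"` default, per the module's linear design; `"elu"`
#'   available). Does not change the parameter count.
#' @param seed integer seed for weight initialization (uniform fan-in).
#' @return an object of class `trm_module`.
#' @seealso [trm_forward()], [embed()], [count_parameters()]
#' @export
#' @examples
#' m <- load_montage("ebdsdd-7x9")
#' trm <- build_trm(m, k = 5)
#' count_parameters(trm)   # 46860
build_trm <- function(montage, k = 5L, conv_bias = FALSE,
                      norm_policy = "final-affine",
                      activation = "identity", seed = 1L) {
  spec <- trm_spec(montage, k, conv_bias, norm_policy)
  layer <- with_seed(seed, nn_trm(spec, activation))
  structure(list(spec = spec, layers = list(layer), seed = seed),
            class = "trm_module")
}

#' @export
print.trm_module <- function(x, ...) {
  print(x$spec)
  invisible(x)
}

#' Apply a TRM to epochs
#'
#' @param trm a [trm_module].
#' @param x numeric array (trials, C, TP).
#' @param training use batch statistics in the normalization layer (as during
#'   training) instead of running statistics.
#' @return array of the same shape as `x`.
#' @export
trm_forward <- function(trm, x, training = FALSE) {
  d <- dim(x)
  xe <- aperm(x, c(2L, 3L, 1L))
  dim(xe) <- c(1L, d[2L], d[3L], d[1L])
  y <- trm$layers[[1L]]$fw(xe, training)
  dim(y) <- c(d[2L], d[3L], d[1L])
  aperm(y, c(3L, 1L, 2L))
}

#' Prepend a TRM to a classification backbone
#'
#' The combined network feeds each input epoch through the TRM (whose output
#' has the same C x TP shape) and then through the unmodified backbone; the
#' backbone's internals and parameter count are untouched, so
#' `count_parameters(embed(trm, bb)) == count_parameters(trm) +
#' count_parameters(bb)`.
#'
#' @param trm a [trm_module].
#' @param backbone an [eeg_network] built by [build_backbone()].
#' @return an [eeg_network] of kind `"combined"`.
#' @export
embed <- function(trm, backbone) {
  if (!inherits(trm, "trm_module") || !inherits(backbone, "eeg_network"))
    stop_eegtrm("embed() needs a trm_module and an eeg_network",
                class = "eegtrm_composition_error")
  if (trm$spec$channels != backbone$expected_channels)
    stop_eegtrm("TRM outputs %d channels but backbone expects %d",
                trm$spec$channels, backbone$expected_channels,
                class = "eegtrm_composition_error")
  new_network(name = paste0(backbone$name, "+trm-",
                            trm$spec$schedule$base_kernel),
              expected_channels = backbone$expected_channels,
              expected_timepoints = backbone$expected_timepoints,
              n_classes = backbone$n_classes,
              layers = c(trm$layers, backbone$layers),
              kind = "combined")
}
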