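# Minimal reimplementations of the three standard raw-EEG decoding networks
# (shallow and deep convolutional nets after Schirrmeister et al.'s designs,
# and the compact depthwise-separable net after Lawhern et al.'s design),
# sized by (C, TP, n_classes). They conform to the backbone contract --
# forward: (batch, C, TP) -> (batch, n_classes) scores -- and are not
# bit-exact replicas of any third-party implementation.

new_network <- function(name, expected_channels, expected_timepoints,
                        n_classes, layers, kind = "backbone") {
  structure(list(name = name,
                 expected_channels = as.integer(expected_channels),
                 expected_timepoints = as.integer(expected_timepoints),
                 n_classes = as.integer(n_classes),
                 layers = layers, kind = kind),
            class = "eeg_network")
}

#' @export
print.eeg_network <- function(x, ...) {
  cat(sprintf("<eeg_network '%s'> (%s) %d ch x %d tp -> %d classes, %d parameters\n",
              x$name, x$kind, x$expected_channels, x$expected_timepoints,
              x$n_classes, count_parameters(x)))
  invisible(x)
}

#' Forward pass of a network on epochs
#'
#' @param net an [eeg_network].
#' @param x numeric array (trials, C, TP) or an [epoch_set].
#' @param training training mode (batch-norm batch statistics, dropout on).
#' @return (trials, n_classes) score matrix (unnormalized; softmax lives in
#'   the loss).
#' @export
network_forward <- function(net, x, training = FALSE) {
  if (inherits(x, "epoch_set")) x <- x$data
  d <- dim(x)
  if (length(d) != 3L || d[2L] != net$expected_channels)
    stop_eegtrm("network '%s' expects %d channels, got %s", net$name,
                net$expected_channels,
                if (length(d) == 3L) d[2L] else "a non-3D array",
                class = "eegtrm_shape_error")
  xe <- aperm(x, c(2L, 3L, 1L))
  dim(xe) <- c(1L, d[2L], d[3L], d[1L])
  scores <- seq_forward(net$layers, xe, training)   # (n_classes, N)
  t(scores)
}

network_backward <- function(net, gscores) {
  seq_backward(net$layers, t(gscores))
  invisible(NULL)
}

#' Reinitialize a network's trainable values
#' @param net an [eeg_network] or [trm_module]; @param seed integer seed.
#' @export
network_init <- function(net, seed) {
  with_seed(seed, seq_init(net$layers))
  invisible(net)
}

# largest temporal conv/pool cascade that fits `width`, shrinking the deep
# net's nominal kernel (10) and pool (3) where the input is short
deep_block_dims <- function(width, kt = 10L, pool = 3L) {
  kt <- min(kt, width)
  after_conv <- width - kt + 1L
  pw <- min(pool, after_conv)
  list(kt = kt, pool = pw, width = (after_conv - pw) %/% pw + 1L)
}

build_shallow <- function(C, TP, n_classes) {
  kt <- 25L; pool_k <- 75L; pool_s <- 15L; nf <- 40L
  min_tp <- kt - 1L + pool_k
  if (TP < min_tp)
    stop_eegtrm("shallow backbone needs TP >= %d (got %d)", min_tp, TP,
                class = "eegtrm_construction_error")
  w1 <- TP - kt + 1L
  wo <- (w1 - pool_k) %/% pool_s + 1L
  list(layers = list(
    nn_conv2d(1L, nf, 1L, kt, bias = TRUE),
    nn_conv2d(nf, nf, C, 1L, bias = FALSE),
    nn_batchnorm(nf),
    nn_activation("square"),
    nn_avgpool(1L, pool_k, 1L, pool_s),
    nn_activation("log"),
    nn_dropout(0.5),
    nn_flatten(),
    nn_linear(nf * wo, n_classes)))
}

build_deep <- function(C, TP, n_classes) {
  nf <- c(25L, 50L, 100L, 200L)
  layers <- list()
  b1 <- deep_block_dims(TP)
  layers <- c(layers, list(
    nn_conv2d(1L, nf[1L], 1L, b1$kt, bias = FALSE),
    nn_conv2d(nf[1L], nf[1L], C, 1L, bias = FALSE),
    nn_batchnorm(nf[1L]),
    nn_activation("elu"),
    nn_maxpool(1L, b1$pool)))
  w <- b1$width
  for (i in 2:4) {
    bi <- deep_block_dims(w)
    layers <- c(layers, list(
      nn_dropout(0.5),
      nn_conv2d(nf[i - 1L], nf[i], 1L, bi$kt, bias = FALSE),
      nn_batchnorm(nf[i]),
      nn_activation("elu"),
      nn_maxpool(1L, bi$pool)))
    w <- bi$width
  }
  layers <- c(layers, list(nn_dropout(0.5), nn_flatten(),
                           nn_linear(nf[4L] * w, n_classes)))
  list(layers = layers)
}

build_compact <- function(C, TP, n_classes) {
  F1 <- 8L; D <- 2L; F2 <- F1 * D
  kt <- 63L; ks <- 15L   # odd "same"-padded temporal kernels
  if (TP < 32L)
    stop_eegtrm("compact backbone needs TP >= 32 (got %d)", TP,
                class = "eegtrm_construction_error")
  w1 <- TP %/% 4L
  wo <- (w1 - 8L) %/% 8L + 1L
  list(layers = list(
    nn_conv2d(1L, F1, 1L, kt, pad = c(0L, (kt - 1L) %/% 2L), bias = FALSE),
    nn_batchnorm(F1),
    nn_conv2d(F1, F2, C, 1L, groups = F1, bias = FALSE),   # depthwise spatial
    nn_batchnorm(F2),
    nn_activation("elu"),
    nn_avgpool(1L, 4L),
    nn_dropout(0.25),
    nn_conv2d(F2, F2, 1L, ks, pad = c(0L, (ks - 1L) %/% 2L),
              groups = F2, bias = FALSE),                  # separable: depthwise
    nn_conv2d(F2, F2, 1L, 1L, bias = FALSE),               # ... + pointwise
    nn_batchnorm(F2),
    nn_activation("elu"),
    nn_avgpool(1L, 8L),
    nn_dropout(0.25),
    nn_flatten(),
    nn_linear(F2 * wo, n_classes)))
}

#' Build a classification backbone
#'
#' @param name `"shallow"` (temporal conv, spatial conv, squaring
#'   nonlinearity, average pooling, log, dense), `"deep"` (four conv/max-pool
#'   blocks and a dense layer; temporal kernels and pools shrink automatically
#'   for short inputs) or `"compact"` (temporal conv, depthwise spatial conv,
#'   separable conv, with at least an order of magnitude fewer parameters).
#' @param C,TP expected input channels and time points.
#' @param n_classes number of output classes.
#' @param seed integer seed for weight initialization.
#' @return an [eeg_network].
#' @export
#' @examples
#' bb <- build_backbone("shallow", C = 55, TP = 280, n_classes = 2)
#' count_parameters(bb)
build_backbone <- function(name = c("shallow", "deep", "compact"),
                           C, TP, n_classes, seed = 1L) {
  name <- match.arg(name)
  C <- as.integer(C); TP <- as.integer(TP); n_classes <- as.integer(n_classes)
  built <- with_seed(seed, switch(name,
    shallow = build_shallow(C, TP, n_classes),
    deep = build_deep(C, TP, n_classes),
    compact = build_compact(C, TP, n_classes)))
  new_network(name, C, TP, n_classes, built$layers)
}

#' List the benchmark run configurations
#'
#' Each of the three backbones is evaluated in its original form and with a
#' prepended TRM of base kernel 5 or 3, giving nine configurations per
#' montage layout.
#'
#' @return data.frame with columns `id`, `backbone`, `variant`.
#' @export
registry_list <- function() {
  bbs <- c("shallow", "deep", "compact")
  vars <- c("original", "trm-5", "trm-3")
  g <- expand.grid(backbone = bbs, variant = vars,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(match(g$backbone, bbs), match(g$variant, vars)), ]
  data.frame(id = paste(g$backbone, g$variant, sep = "+"),
             g, row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a registry configuration by identifier
#'
#' @param id one of the ids from [registry_list()], e.g. `"shallow+trm-5"`.
#' @param montage a [montage_grid] (defines C and the TRM grid).
#' @param TP,n_classes input length and class count.
#' @param seed initialization seed.
#' @return an [eeg_network] (combined when the variant uses a TRM).
#' @export
build_registry_entry <- function(id, montage, TP, n_classes, seed = 1L) {
  reg <- registry_list()
  i <- match(id, reg$id)
  if (is.na(i))
    stop_eegtrm("unknown registry id '%s' (known: %s)", id,
                paste(reg$id, collapse = ", "),
                class = "eegtrm_lookup_error")
  C <- length(montage$channel_names)
  bb <- build_backbone(reg$backbone[i], C, TP, n_classes, seed = seed)
  if (reg$variant[i] == "original") return(bb)
  k <- if (reg$variant[i] == "trm-5") 5L else 3L
  embed(build_trm(montage, k, seed = seed + 1L), bb)
}
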