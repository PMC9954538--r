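#' Construct a montage grid
#'
#' A montage grid assigns each EEG channel to one cell of an H x W scalp
#' matrix. Coordinates are 0-based and row-major: row 0 is the frontal edge
#' (top), column 0 the left hemisphere. Cells without an assigned electrode
#' are zero-filled when epochs are mapped to topographic form.
#'
#' @param channel_names ordered character vector of C channel identifiers.
#' @param height,width grid dimensions (integers >= 1).
#' @param assignments C x 2 integer matrix of (row, col) per channel, 0-based,
#'   rows in the order of `channel_names`.
#' @param name optional layout name.
#' @return an object of class `montage_grid`.
#' @export
#' @examples
#' m <- montage_grid(c("C3", "C4"), 1, 2, rbind(c(0, 0), c(0, 1)))
#' m
montage_grid <- function(channel_names, height, width, assignments,
                         name = NULL) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L)
    stop_eegtrm("grid dimensions must be >= 1 (got %s x %s)", height, width,
                class = "eegtrm_domain_error")
  channel_names <- as.character(channel_names)
  C <- length(channel_names)
  if (anyDuplicated(channel_names))
    stop_eegtrm("duplicate channel name(s): %s",
                paste(unique(channel_names[duplicated(channel_names)]),
                      collapse = ", "),
                class = "eegtrm_config_error")
  assignments <- matrix(as.integer(assignments), ncol = 2L,
                        dimnames = list(channel_names, c("row", "col")))
  if (nrow(assignments) != C)
    stop_eegtrm("need one (row, col) per channel (%d channels, %d assignments)",
                C, nrow(assignments), class = "eegtrm_config_error")
  bad <- assignments[, 1L] < 0L | assignments[, 1L] >= height |
         assignments[, 2L] < 0L | assignments[, 2L] >= width
  if (any(bad))
    stop_eegtrm("assignment out of bounds for %d x %d grid: %s",
                height, width,
                paste(channel_names[bad], collapse = ", "),
                class = "eegtrm_bounds_error")
  cell <- assignments[, 1L] + assignments[, 2L] * height   # 0-based linear
  if (anyDuplicated(cell)) {
    i <- which(duplicated(cell) | duplicated(cell, fromLast = TRUE))
    stop_eegtrm("channels share a grid cell: %s",
                paste(channel_names[i], collapse = ", "),
                class = "eegtrm_collision_error")
  }
  if (C > height * width)
    stop_eegtrm("%d channels cannot fit a %d x %d grid", C, height, width,
                class = "eegtrm_domain_error")
  structure(list(channel_names = channel_names, height = height,
                 width = width, assignments = assignments,
                 name = name %||% "custom"),
            class = "montage_grid")
}

#' @export
print.montage_grid <- function(x, ...) {
  cat(sprintf("<montage_grid '%s'> %d channels on a %d x %d grid\n",
              x$name, length(x$channel_names), x$height, x$width))
  invisible(x)
}

# 1-based linear indices into an H x W (row-major-displayed, column-major
# stored) matrix, one per channel in channel order
montage_cell_index <- function(m) {
  m$assignments[, 1L] + m$assignments[, 2L] * m$height + 1L
}

#' Load a montage grid from a YAML configuration
#'
#' The configuration declares `height`, `width`, optionally `name`, and a
#' `channels` mapping of channel name to `[row, col]` (0-based). Channel order
#' in the file is preserved and defines the channel axis of mapped epochs.
#' Two example layouts ship with the package:
#' `"ebdsdd-7x9"` (55 channels, 7 x 9) and `"hgd-7x7"` (44 channels, 7 x 7).
#' Their grid sizes and channel counts follow the two evaluation montages;
#' individual cell placements are documented approximations of the scalp
#' layout and can be edited freely.
#'
#' @param config path to a YAML file, or the name of a shipped layout.
#' @return a validated [montage_grid].
#' @export
#' @examples
#' m <- load_montage("ebdsdd-7x9")
#' m$height; m$width; length(m$channel_names)
load_montage <- function(config) {
  path <- config
  if (!file.exists(path)) {
    shipped <- system.file("extdata", paste0(config, ".yaml"),
                           package = "eegtrm")
    if (nzchar(shipped)) path <- shipped
    else stop_eegtrm("montage config not found: %s", config,
                     class = "eegtrm_config_error")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$height) || is.null(y$width) || is.null(y$channels))
    stop_eegtrm("montage config must declare height, width and channels",
                class = "eegtrm_config_error")
  ch <- names(y$channels)
  if (anyDuplicated(ch))
    stop_eegtrm("duplicate channel name(s) in config: %s",
                paste(unique(ch[duplicated(ch)]), collapse = ", "),
                class = "eegtrm_config_error")
  rc <- t(vapply(y$channels, function(v) as.integer(v[1:2]), integer(2L)))
  montage_grid(ch, y$height, y$width, rc,
               name = y$name %||% sub("\\.ya?ml$", "", basename(path)))
}

#' Map epochs onto the topographic grid
#'
#' Places each channel's time series at its assigned grid cell; the remaining
#' H*W - C cells are exactly zero. Potential values are copied unchanged (no
#' scaling or interpolation), so the transform is lossless and energy
#' preserving.
#'
#' @param epochs an [epoch_set], or a trials x C x TP numeric array whose
#'   channel axis matches `montage`'s channel set.
#' @param montage a [montage_grid].
#' @return numeric array of shape trials x H x W x TP.
#' @seealso [unmap_topomap()] for the exact inverse.
#' @export
map_to_topomap <- function(epochs, montage) {
  x <- epoch_data(epochs, montage)
  d <- dim(x)                                     # (trials, C, TP)
  n <- d[1L]; C <- d[2L]; TP <- d[3L]
  H <- montage$height; W <- montage$width
  cell <- montage_cell_index(montage)
  # reorder to (C, trials*TP) so cell scatter is one indexed assignment
  xm <- matrix(aperm(x, c(2L, 1L, 3L)), C, n * TP)
  topo <- matrix(0, H * W, n * TP)
  topo[cell, ] <- xm
  dim(topo) <- c(H, W, n, TP)
  aperm(topo, c(3L, 1L, 2L, 4L))
}

#' Recover epochs from a topographic stack
#'
#' Exact inverse of [map_to_topomap()]: reads assigned cells in channel order.
#' `unmap_topomap(map_to_topomap(x, m), m)` reproduces `x` bit for bit.
#'
#' @param stack trials x H x W x TP numeric array.
#' @param montage a [montage_grid].
#' @return trials x C x TP numeric array.
#' @export
unmap_topomap <- function(stack, montage) {
  d <- dim(stack)
  if (length(d) != 4L || d[2L] != montage$height || d[3L] != montage$width)
    stop_eegtrm("stack dimensions %s do not match %d x %d montage",
                paste(d, collapse = " x "), montage$height, montage$width,
                class = "eegtrm_dimension_error")
  n <- d[1L]; TP <- d[4L]
  cell <- montage_cell_index(montage)
  tm <- matrix(aperm(stack, c(2L, 3L, 1L, 4L)), montage$height * montage$width,
               n * TP)
  xm <- tm[cell, , drop = FALSE]                  # (C, trials*TP)
  dim(xm) <- c(length(cell), n, TP)
  aperm(xm, c(2L, 1L, 3L))
}

# Resolve epoch data against a montage: channel matching is by name, never by
# position; returns trials x C x TP with channels in montage order.
epoch_data <- function(epochs, montage = NULL) {
  if (inherits(epochs, "epoch_set")) {
    x <- epochs$data
    if (!is.null(montage)) {
      missing_ch <- setdiff(montage$channel_names, epochs$channel_names)
      extra_ch <- setdiff(epochs$channel_names, montage$channel_names)
      if (length(missing_ch) || length(extra_ch))
        stop_eegtrm(
          "channel sets differ (missing from epochs: %s; not in montage: %s)",
          paste(missing_ch, collapse = ", ") %|empty|% "none",
          paste(extra_ch, collapse = ", ") %|empty|% "none",
          class = "eegtrm_mapping_error")
      x <- x[, match(montage$channel_names, epochs$channel_names), ,
             drop = FALSE]
    }
    return(x)
  }
  x <- epochs
  if (length(dim(x)) != 3L)
    stop_eegtrm("epochs must be a trials x channels x timepoints array",
                class = "eegtrm_dimension_error")
  if (!is.null(montage) && dim(x)[2L] != length(montage$channel_names))
    stop_eegtrm("epoch array has %d channels, montage has %d",
                dim(x)[2L], length(montage$channel_names),
                class = "eegtrm_mapping_error")
  x
}

`%|empty|%` <- function(a, b) if (nzchar(a)) a else b
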