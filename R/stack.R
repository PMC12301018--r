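#' Multi-channel confocal image stack
#'
#' Container for a multi-channel 3D fluorescence acquisition. Voxels are held
#' in a 4D array indexed `(channel, z, y, x)` — a single canonical layout so
#' that no reader or writer can silently transpose axes. `depth_origin` states
#' which physical face of the biofilm the first z-plane corresponds to;
#' depth profiling measures depth from the substrate regardless.
#'
#' @param voxels Non-negative numeric array, `(channel, z, y, x)`; a 3D array
#'   is promoted to a single channel.
#' @param voxel_size Numeric length-3, voxel edge lengths `(dz, dy, dx)` in
#'   micrometers; all strictly positive.
#' @param channel_labels Character vector naming the channels (fluorophore or
#'   component names); length must match the channel dimension. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param depth_origin One of `"substrate_at_z0"` (z = 1 is the
#'   concrete-adjacent face; the default) or `"free_surface_at_z0"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size, channel_labels = NULL,
                        depth_origin = c("substrate_at_z0", "free_surface_at_z0")) {
  depth_origin <- match.arg(depth_origin)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(1L, dim(voxels))
  if (length(dim(voxels)) != 4L)
    abort_validation("voxels must be a 3D or 4D array (channel, z, y, x)")
  if (any(dim(voxels) < 1L)) abort_validation("all stack dimensions must be >= 1")
  if (any(voxels < 0)) abort_validation("voxel intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    abort_validation("voxel_size must be three strictly positive values (dz, dy, dx) in um")
  n_ch <- dim(voxels)[1]
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_ch))
  if (length(channel_labels) != n_ch)
    abort_config(sprintf("%d channel labels supplied for %d channels",
                         length(channel_labels), n_ch))
  structure(
    list(voxels = voxels, voxel_size = voxel_size,
         channel_labels = as.character(channel_labels),
         depth_origin = depth_origin),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s), %d x %d x %d (z,y,x) voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (dz,dy,dx): %s um; depth origin: %s\n",
              paste(signif(x$voxel_size, 4), collapse = " x "), x$depth_origin))
  cat(sprintf("  channels: %s\n", paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

n_channels <- function(stack) dim(stack$voxels)[1]

spatial_dim <- function(stack) dim(stack$voxels)[-1]

#' Extract one channel of a stack as a 3D volume
#'
#' @param stack An [image_stack].
#' @param channel Channel index or label.
#' @return A 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_labels)
    if (is.na(i)) abort_config(sprintf("no channel labelled '%s'", channel))
    channel <- i
  }
  if (channel < 1 || channel > n_channels(stack))
    abort_config(sprintf("channel index %s out of range", channel))
  v <- stack$voxels[channel, , , , drop = FALSE]
  dim(v) <- dim(stack$voxels)[-1]
  v
}

#' Binary occupancy mask for one biofilm component
#'
#' @param occupancy Logical or 0/1 3D array `(z, y, x)`.
#' @param component Component name (e.g. `"protein"`, `"all_bacteria"`).
#' @param threshold_used Intensity threshold that produced the mask
#'   (`NA` for ground-truth or manually constructed masks).
#' @param method `"otsu"`, `"manual"`, or `"truth"`.
#' @return An object of class `component_mask`.
#' @export
component_mask <- function(occupancy, component = NA_character_,
                           threshold_used = NA_real_,
                           method = c("otsu", "manual", "truth")) {
  method <- match.arg(method)
  if (length(dim(occupancy)) != 3L)
    abort_validation("occupancy must be a 3D array (z, y, x)")
  occ <- occupancy != 0
  if (is.double(occupancy) || is.integer(occupancy)) {
    if (any(!(occupancy %in% c(0, 1))))
      abort_validation("occupancy values must be 0/1")
  }
  storage.mode(occ) <- "logical"
  structure(
    list(occupancy = occ, component = as.character(component),
         threshold_used = as.numeric(threshold_used), method = method),
    class = "component_mask"
  )
}

#' @export
print.component_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<component_mask> %s: %d / %d voxels foreground (%d x %d x %d), method %s, threshold %s\n",
              x$component, sum(x$occupancy), prod(d), d[1], d[2], d[3],
              x$method, format(x$threshold_used)))
  invisible(x)
}

mask_shape_check <- function(masks) {
  if (length(masks) == 0) return(invisible(NULL))
  shapes <- vapply(masks, function(m) paste(dim(m$occupancy), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    abort_validation(sprintf("masks disagree in shape: %s",
                             paste(unique(shapes), collapse = " vs ")))
  invisible(NULL)
}
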