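# Stack and mask I/O on plain multi-page TIFF. Stacks are written one page
# per (channel, z) plane in channel-major order, with a JSON ImageDescription
# recording shape, voxel size, channel labels and depth origin so that a
# round trip restores the acquisition exactly.

stack_description <- function(stack) {
  jsonlite::toJSON(list(
    software = "biofilmq",
    kind = "stack",
    shape = dim(stack$voxels),
    voxel_size_um = stack$voxel_size,
    channel_labels = stack$channel_labels,
    depth_origin = stack$depth_origin
  ), auto_unbox = FALSE, digits = NA)
}

#' Write a multi-channel stack to TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...);
#' intensities are stored as 64-bit floats so values round-trip bit-for-bit.
#'
#' @param stack An [image_stack].
#' @param path Output file path (`.tif`/`.tiff`).
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) abort_validation("stack must be an image_stack")
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[p]] <- matrix(stack$voxels[ch, z, , ], nrow = d[3], ncol = d[4])
      p <- p + 1L
    }
  }
  write_tiff(path, pages, dtype = "float64",
             description = as.character(stack_description(stack)))
  invisible(path)
}

parse_stack_description <- function(desc) {
  if (is.null(desc)) return(NULL)
  meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  if (is.null(meta) || is.null(meta$software) || !identical(meta$software, "biofilmq"))
    return(NULL)
  if (!identical(as.character(meta$kind %||% "stack"), "stack")) return(NULL)
  meta
}

#' Read a multi-channel stack from TIFF
#'
#' Files written by [write_stack()] restore all metadata. For foreign TIFFs
#' (plain multi-page grayscale) the pages are interpreted as a single-channel
#' z-stack and the voxel size must be supplied via `voxel_size`.
#'
#' @param path TIFF file path.
#' @param channel_labels Optional channel names; must match the channel count.
#' @param voxel_size Optional `(dz, dy, dx)` in um. An explicit value always
#'   wins over file metadata (with a warning), because microscope metadata is
#'   frequently wrong.
#' @param depth_origin Used when the file carries no depth-origin metadata.
#' @return An [image_stack].
#' @export
read_stack <- function(path, channel_labels = NULL, voxel_size = NULL,
                       depth_origin = "substrate_at_z0") {
  tf <- read_tiff(path)
  meta <- parse_stack_description(tf$description)
  n_pages <- length(tf$pages)
  if (!is.null(meta)) {
    shape <- as.integer(meta$shape)
    if (shape[1] * shape[2] != n_pages)
      abort_format(sprintf("TIFF has %d pages but metadata declares %d x %d planes",
                           n_pages, shape[1], shape[2]))
    labels <- as.character(meta$channel_labels)
    file_vox <- as.numeric(meta$voxel_size_um)
    origin <- as.character(meta$depth_origin)
  } else {
    shape <- c(1L, n_pages, nrow(tf$pages[[1]]), ncol(tf$pages[[1]]))
    labels <- NULL
    file_vox <- NULL
    origin <- depth_origin
  }
  if (!is.null(channel_labels)) {
    if (length(channel_labels) != shape[1])
      abort_config(sprintf("%d channel labels supplied for a %d-channel file",
                           length(channel_labels), shape[1]))
    labels <- channel_labels
  }
  if (!is.null(voxel_size)) {
    if (!is.null(file_vox) && !isTRUE(all.equal(as.numeric(voxel_size), file_vox)))
      warning("voxel_size override differs from file metadata; using the override",
              call. = FALSE)
    vox <- voxel_size
  } else if (!is.null(file_vox)) {
    vox <- file_vox
  } else {
    abort_metadata("file carries no voxel-size metadata; supply voxel_size explicitly")
  }
  voxels <- array(0, dim = shape)
  p <- 1L
  for (ch in seq_len(shape[1])) {
    for (z in seq_len(shape[2])) {
      pg <- tf$pages[[p]]
      if (nrow(pg) != shape[3] || ncol(pg) != shape[4])
        abort_format("TIFF pages disagree in size")
      voxels[ch, z, , ] <- pg
      p <- p + 1L
    }
  }
  image_stack(voxels, vox, channel_labels = labels, depth_origin = origin)
}

#' Write component masks as single-channel TIFFs
#'
#' One 8-bit 0/1 TIFF per component plus a JSON sidecar recording threshold
#' provenance (component, method, threshold, shape).
#'
#' @param masks List of [component_mask] objects sharing one spatial shape.
#' @param path Output directory (created if missing).
#' @return Character vector of written TIFF paths, invisibly.
#' @export
write_masks <- function(masks, path) {
  if (length(masks) == 0) {
    warning("no masks to write; nothing done", call. = FALSE)
    return(invisible(character(0)))
  }
  mask_shape_check(masks)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (m in masks) {
    stem <- if (is.na(m$component)) sprintf("mask%02d", length(written) + 1L) else m$component
    f <- file.path(path, paste0("mask_", stem, ".tif"))
    d <- dim(m$occupancy)
    pages <- lapply(seq_len(d[1]), function(z)
      matrix(as.integer(m$occupancy[z, , ]), nrow = d[2], ncol = d[3]))
    desc <- jsonlite::toJSON(list(software = "biofilmq", kind = "mask",
                                  component = m$component, method = m$method,
                                  threshold_used = m$threshold_used, shape = d),
                             auto_unbox = TRUE, digits = NA, na = "null")
    write_tiff(f, pages, dtype = "uint8", description = as.character(desc))
    sidecar <- file.path(path, paste0("mask_", stem, ".json"))
    writeLines(as.character(desc), sidecar)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read a component mask written by [write_masks()]
#'
#' @param path Path to a mask TIFF.
#' @return A [component_mask].
#' @export
read_mask <- function(path) {
  tf <- read_tiff(path)
  meta <- tryCatch(jsonlite::fromJSON(tf$description %||% "{}"),
                   error = function(e) list())
  d <- c(length(tf$pages), nrow(tf$pages[[1]]), ncol(tf$pages[[1]]))
  occ <- array(FALSE, d)
  for (z in seq_len(d[1])) occ[z, , ] <- tf$pages[[z]] != 0
  method <- meta$method %||% "manual"
  component_mask(occ,
                 component = meta$component %||% NA_character_,
                 threshold_used = if (is.null(meta$threshold_used)) NA_real_ else meta$threshold_used,
                 method = if (method %in% c("otsu", "manual", "truth")) method else "manual")
}
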