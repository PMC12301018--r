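# Ground-truthed synthetic data: multi-channel biofilm stacks built from
# random spherical blobs with component-specific depth densities, and EEM
# grids built from 2D Gaussian peaks. Blob morphology is deliberately simple
# — the generator exists to exercise segmentation, quantification and
# profiling with exact truth, not to model biofilm growth.

#' Recipe for a synthetic multi-channel biofilm stack
#'
#' @param shape `(z, y, x)` voxel counts.
#' @param voxel_size `(dz, dy, dx)` in um (default 1 um isotropic).
#' @param components List of component specs, each a list with `component`
#'   (name), `target_fraction` (fraction of the stack volume occupied, in
#'   (0, 0.9]), and `depth_density` — either
#'   `list(type = "uniform", z0_um =, z1_um =)` or
#'   `list(type = "gaussian", mean_um =, sd_um =)` for blob centers.
#' @param blob_radius_um Mean blob radius in um (each blob's radius is
#'   jittered by +/-30%).
#' @param snr Foreground-over-background intensity difference divided by the
#'   Gaussian noise sd; `Inf` means noiseless.
#' @param blur_sigma_um PSF proxy: Gaussian blur sigma in um (0 = none).
#' @param bleed Channel mixing matrix (rows = observed channels, columns =
#'   true signals); `NULL` means identity. Row sums must be <= 1.5.
#' @param background,foreground Intensity levels for empty/occupied voxels.
#' @param seed Integer seed; a fixed seed reproduces the stack bit-for-bit.
#' @return An object of class `stack_recipe`.
#' @export
stack_recipe <- function(shape, voxel_size = c(1, 1, 1), components,
                         blob_radius_um = 4, snr = 5, blur_sigma_um = 1,
                         bleed = NULL, background = 20, foreground = 200,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) abort_config("shape must be three positive voxel counts")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) abort_config("voxel_size must be positive")
  if (!is.finite(blob_radius_um) || blob_radius_um <= 0) abort_config("blob_radius_um must be positive")
  if (!(snr > 0)) abort_config("snr must be positive")
  if (blur_sigma_um < 0) abort_config("blur_sigma_um must be >= 0")
  if (foreground <= background || background < 0)
    abort_config("need foreground > background >= 0")
  components <- lapply(components, function(cp) {
    cp <- as.list(cp)
    if (is.null(cp$component)) abort_config("each component spec needs a 'component' name")
    f <- cp$target_fraction
    if (is.null(f) || !is.finite(f) || f <= 0 || f > 1)
      abort_config(sprintf("target_fraction for '%s' must be in (0, 1]", cp$component))
    if (f > 0.9)
      abort_config(sprintf("target_fraction %.2f for '%s' is infeasible (> 0.9 of the volume)",
                           f, cp$component))
    dd <- cp$depth_density %||% list(type = "uniform", z0_um = 0,
                                     z1_um = shape[1] * voxel_size[1])
    if (!dd$type %in% c("uniform", "gaussian"))
      abort_config("depth_density type must be 'uniform' or 'gaussian'")
    list(component = as.character(cp$component), target_fraction = f,
         depth_density = dd)
  })
  nm <- vapply(components, `[[`, character(1), "component")
  if (anyDuplicated(nm)) abort_config("component names must be unique")
  if (!is.null(bleed)) {
    bleed <- as.matrix(bleed)
    if (!all(dim(bleed) == length(components)))
      abort_config("bleed must be a square components x components matrix")
    if (any(bleed < 0) || any(rowSums(bleed) > 1.5))
      abort_config("bleed entries must be >= 0 with row sums <= 1.5")
  }
  structure(list(shape = shape, voxel_size = voxel_size, components = components,
                 blob_radius_um = blob_radius_um, snr = snr,
                 blur_sigma_um = blur_sigma_um, bleed = bleed,
                 background = background, foreground = foreground,
                 seed = as.integer(seed)),
            class = "stack_recipe")
}

draw_center_z_um <- function(dd, z_extent_um) {
  if (dd$type == "uniform") {
    stats::runif(1, max(0, dd$z0_um), min(z_extent_um, dd$z1_um))
  } else {
    repeat {
      z <- stats::rnorm(1, dd$mean_um, dd$sd_um)
      if (z >= 0 && z <= z_extent_um) return(z)
    }
  }
}

# Stamp one ellipsoidal blob into a logical array; returns linear indices of
# voxels newly set by this blob.
stamp_blob <- function(occ, center_um, radius_um, voxel_size) {
  d <- dim(occ)
  ci <- pmin(pmax(floor(center_um / voxel_size) + 1L, 1L), d)
  rv <- pmax(radius_um / voxel_size, 0.5)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, ci[ax] - ceiling(rv[ax])); hi <- min(d[ax], ci[ax] + ceiling(rv[ax]))
    lo:hi
  })
  dz2 <- (((rng[[1]] - 0.5) * voxel_size[1] - center_um[1]) / radius_um)^2
  dy2 <- (((rng[[2]] - 0.5) * voxel_size[2] - center_um[2]) / radius_um)^2
  dx2 <- (((rng[[3]] - 0.5) * voxel_size[3] - center_um[3]) / radius_um)^2
  inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  sub <- occ[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  newly <- inside & !sub
  if (!any(newly)) return(list(occ = occ, new_idx = integer(0)))
  sub[inside] <- TRUE
  occ[rng[[1]], rng[[2]], rng[[3]]] <- sub
  li <- which(newly)
  co <- arrayInd(li, dim(newly))
  lin <- (rng[[1]][co[, 1]]) + (rng[[2]][co[, 2]] - 1L) * d[1] +
         (rng[[3]][co[, 3]] - 1L) * d[1] * d[2]
  list(occ = occ, new_idx = lin)
}

#' Generate a ground-truthed synthetic biofilm stack
#'
#' Places random spherical blobs per component, with blob-center depths
#' drawn from the component's depth density, until the exact target voxel
#' count `round(target_fraction * n_voxels)` is reached (the final blob is
#' trimmed by random subsampling of its newly added voxels, so realized
#' fractions match targets exactly up to rounding). Channel intensities are
#' `background + (foreground - background) * occupancy`, mixed by the bleed
#' matrix, Gaussian-blurred, and overlaid with seeded Gaussian noise of
#' sd `(foreground - background) / snr`, then clipped at 0.
#'
#' @param recipe A [stack_recipe].
#' @return List with `stack` (an [image_stack], channels labelled by
#'   component) and `truth` (class `synthetic_truth`: per-component truth
#'   masks, realized `fractions`, and `depth_modes` — the argmax 10-um depth
#'   bin `[lo, hi)` per component).
#' @export
generate_stack <- function(recipe) {
  if (!inherits(recipe, "stack_recipe")) abort_config("recipe must be a stack_recipe")
  d <- recipe$shape
  vs <- recipe$voxel_size
  n_vox <- prod(d)
  ext_um <- d * vs
  comps <- vapply(recipe$components, `[[`, character(1), "component")
  nC <- length(comps)
  with_seed(recipe$seed, {
    truth_masks <- list()
    for (cp in recipe$components) {
      occ <- array(FALSE, d)
      target <- as.integer(round(cp$target_fraction * n_vox))
      count <- 0L
      guard <- 0L
      while (count < target) {
        guard <- guard + 1L
        if (guard > 50000L)
          abort_config(sprintf("could not reach target fraction for '%s'", cp$component))
        r <- recipe$blob_radius_um * stats::runif(1, 0.7, 1.3)
        center <- c(draw_center_z_um(cp$depth_density, ext_um[1]),
                    stats::runif(1, 0, ext_um[2]),
                    stats::runif(1, 0, ext_um[3]))
        st <- stamp_blob(occ, center, r, vs)
        added <- length(st$new_idx)
        if (count + added > target) {
          # trim the final blob so the realized count is exact
          drop_n <- count + added - target
          drop_idx <- sample(st$new_idx, drop_n)
          st$occ[drop_idx] <- FALSE
          added <- added - drop_n
        }
        occ <- st$occ
        count <- count + added
      }
      truth_masks[[cp$component]] <- component_mask(occ, component = cp$component,
                                                   method = "truth")
    }
    delta <- recipe$foreground - recipe$background
    signals <- lapply(truth_masks, function(m) delta * (m$occupancy * 1))
    bleed <- recipe$bleed %||% diag(nC)
    voxels <- array(0, c(nC, d))
    sigma_vox <- recipe$blur_sigma_um / vs
    noise_sd <- if (is.finite(recipe$snr)) delta / recipe$snr else 0
    for (i in seq_len(nC)) {
      mixed <- Reduce(`+`, Map(function(w, s) w * s, bleed[i, ], signals))
      chan <- recipe$background + mixed
      if (recipe$blur_sigma_um > 0) chan <- gauss_blur(chan, sigma_vox)
      if (noise_sd > 0) chan <- chan + stats::rnorm(n_vox, 0, noise_sd)
      voxels[i, , , ] <- pmax(chan, 0)
    }
  })
  stack <- image_stack(voxels, vs, channel_labels = comps)
  fractions <- vapply(truth_masks, function(m) mean(m$occupancy), numeric(1))
  prof <- depth_profile(truth_masks, vs, bin_width = 10)
  depth_modes <- lapply(comps, function(cp) {
    b <- which.max(prof$counts[, cp])
    c(lo_um = prof$bin_edges[b], hi_um = prof$bin_edges[b + 1])
  })
  names(depth_modes) <- comps
  truth <- structure(list(masks = truth_masks, fractions = fractions,
                          depth_modes = depth_modes),
                     class = "synthetic_truth")
  list(stack = stack, truth = truth)
}

#' Preset recipes for the low- and high-salinity depth regimes
#'
#' `"FQHC"` (low salinity): all components uniformly distributed over the
#' mid-depth of the stack with near-equal fractions — components
#' concentrated in the central region. `"SQHC"` (high salinity): bacteria
#' enriched in the surface layer (Gaussian depth density, mean 15 um, sd 5),
#' extracellular DNA enriched deep (mean 35 um, sd 5), protein and
#' polysaccharide weighted to the deep bins.
#'
#' @param name `"FQHC"` or `"SQHC"`.
#' @param seed Integer seed stored in the recipe.
#' @return A [stack_recipe] with shape (48, 64, 64) at 1 um isotropic
#'   voxels, snr 5 and 1 um blur.
#' @export
preset_recipe <- function(name = c("FQHC", "SQHC"), seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("FQHC", "SQHC"))
    abort_config(sprintf("unknown preset '%s' (use FQHC or SQHC)", name[1]))
  name <- name[1]
  shape <- c(48L, 64L, 64L)
  if (name == "FQHC") {
    mid <- list(type = "uniform", z0_um = 12, z1_um = 36)
    comps <- list(
      list(component = "protein",        target_fraction = 0.05, depth_density = mid),
      list(component = "polysaccharide", target_fraction = 0.05, depth_density = mid),
      list(component = "lipid",          target_fraction = 0.04, depth_density = mid),
      list(component = "nucleic_acid",   target_fraction = 0.04, depth_density = mid),
      list(component = "all_bacteria",   target_fraction = 0.05, depth_density = mid))
  } else {
    comps <- list(
      list(component = "protein",        target_fraction = 0.05,
           depth_density = list(type = "gaussian", mean_um = 38, sd_um = 8)),
      list(component = "polysaccharide", target_fraction = 0.06,
           depth_density = list(type = "gaussian", mean_um = 40, sd_um = 8)),
      list(component = "lipid",          target_fraction = 0.03,
           depth_density = list(type = "gaussian", mean_um = 36, sd_um = 7)),
      list(component = "nucleic_acid",   target_fraction = 0.04,
           depth_density = list(type = "gaussian", mean_um = 35, sd_um = 5)),
      list(component = "all_bacteria",   target_fraction = 0.05,
           depth_density = list(type = "gaussian", mean_um = 15, sd_um = 5)))
  }
  stack_recipe(shape = shape, voxel_size = c(1, 1, 1), components = comps,
               blob_radius_um = 3, snr = 5, blur_sigma_um = 1, seed = seed)
}

#' Generate a synthetic EEM matrix from Gaussian peaks
#'
#' @param peaks List of peak specs `list(ex_nm =, em_nm =, height =,
#'   sd_nm =)`; centers must lie exactly on the grid.
#' @param noise_sd Gaussian noise sd (intensity units; 0 = noiseless).
#' @param seed Integer seed.
#' @param grid List with `ex_nm`, `em_nm` (default [eem_default_grid()]).
#' @param label Optional condition tag.
#' @return An [eem_matrix]; intensities clipped at 0.
#' @export
generate_eem <- function(peaks = list(), noise_sd = 0, seed = 1L,
                         grid = eem_default_grid(), label = NULL) {
  ex <- grid$ex_nm; em <- grid$em_nm
  M <- matrix(0, length(ex), length(em))
  for (p in peaks) {
    p <- as.list(p)
    if (!(p$ex_nm %in% ex) || !(p$em_nm %in% em))
      abort_config(sprintf("peak center (%g, %g) is not on the grid", p$ex_nm, p$em_nm))
    sd <- p$sd_nm %||% 10
    EX <- matrix(ex, length(ex), length(em))
    EM <- matrix(em, length(ex), length(em), byrow = TRUE)
    M <- M + p$height * exp(-((EX - p$ex_nm)^2 + (EM - p$em_nm)^2) / (2 * sd^2))
  }
  if (noise_sd > 0) {
    M <- M + with_seed(seed, matrix(stats::rnorm(length(M), 0, noise_sd),
                                    nrow(M), ncol(M)))
  }
  eem_matrix(ex, em, pmax(M, 0), label = label)
}
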