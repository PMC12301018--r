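# Volume extraction, mass estimation from a measured biofilm mass,
# depth-resolved composition profiles, and representative elementary volume
# (REV) analysis.
#
# Mass model: with m the measured biofilm mass and V its imaged volume, a
# component occupying volume V_I carries mass EPS_I = m * V_I / V, and with
# V_B the bacterial volume the total EPS mass is EPS_II = m * (V - V_B) / V.
# Both are ratio estimators, so they are invariant to rescaling all volumes
# by a common factor.

#' Fluorescent volume of a component mask
#'
#' @param mask A [component_mask].
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return Volume in um^3: foreground voxel count times voxel volume.
#' @export
component_volume <- function(mask, voxel_size) {
  if (!inherits(mask, "component_mask")) abort_validation("mask must be a component_mask")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    abort_validation("voxel_size must be three positive values")
  sum(mask$occupancy) * prod(voxel_size)
}

slice_hull_area <- function(slice, dy, dx) {
  pts <- which(slice, arr.ind = TRUE)          # (y, x) voxel indices
  if (nrow(pts) == 0) return(0)
  # each voxel contributes its four corners so single voxels have area
  yy <- c(pts[, 1] - 1, pts[, 1] - 1, pts[, 1], pts[, 1]) * dy
  xx <- c(pts[, 2] - 1, pts[, 2], pts[, 2] - 1, pts[, 2]) * dx
  h <- grDevices::chull(xx, yy)
  px <- xx[h]; py <- yy[h]
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

#' Total biofilm volume from component masks
#'
#' `"union"` (the default) takes the voxelwise OR of all masks — a
#' conservative, reproducible delimitation of the biofilm body.
#' `"convex_envelope"` sums the areas of the per-z-slice 2D convex hulls of
#' the union, approximating a filled biofilm body including unstained
#' interstitial space; it is always at least the union volume.
#'
#' @param masks List of [component_mask] objects sharing one shape.
#' @param strategy `"union"` or `"convex_envelope"`.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return Volume V in um^3.
#' @export
total_biofilm_volume <- function(masks, strategy = c("union", "convex_envelope"),
                                 voxel_size = c(1, 1, 1)) {
  strategy <- match.arg(strategy)
  if (length(masks) == 0) abort_empty("no masks supplied")
  mask_shape_check(masks)
  voxel_size <- as.numeric(voxel_size)
  union <- Reduce(`|`, lapply(masks, `[[`, "occupancy"))
  if (!any(union)) abort_empty("all masks are empty; total volume undefined")
  if (strategy == "union") return(sum(union) * prod(voxel_size))
  d <- dim(union)
  areas <- vapply(seq_len(d[1]), function(z)
    slice_hull_area(union[z, , ], voxel_size[2], voxel_size[3]), numeric(1))
  sum(areas) * voxel_size[1]
}

#' Mass of one EPS component from its volume fraction
#'
#' `EPS_I = m * V_I / V`.
#'
#' @param m Biofilm mass in mg.
#' @param V Total biofilm volume in um^3 (must be positive).
#' @param V_I Component volume in um^3, `0 <= V_I <= V`.
#' @return Component mass in mg.
#' @export
eps_component_mass <- function(m, V, V_I) {
  if (!is.finite(V) || V <= 0) abort_division("total volume V must be positive")
  if (m < 0) abort_validation("mass m must be non-negative")
  if (V_I < 0 || V_I > V) abort_validation("V_I must satisfy 0 <= V_I <= V")
  m * V_I / V
}

#' Total EPS mass from the bacterial volume
#'
#' `EPS_II = m * (V - V_B) / V`: everything in the biofilm body that is not
#' bacterial cells is counted as extracellular matrix.
#'
#' @param m Biofilm mass in mg.
#' @param V Total biofilm volume in um^3 (must be positive).
#' @param V_B Bacterial volume in um^3, `0 <= V_B <= V`.
#' @return Total EPS mass in mg (`<= m`).
#' @export
eps_total_mass <- function(m, V, V_B) {
  if (!is.finite(V) || V <= 0) abort_division("total volume V must be positive")
  if (m < 0) abort_validation("mass m must be non-negative")
  if (V_B < 0 || V_B > V) abort_validation("V_B must satisfy 0 <= V_B <= V")
  m * (V - V_B) / V
}

#' Assemble the full per-field quantification
#'
#' Computes V (via [total_biofilm_volume()] over all masks), per-component
#' volumes V_I, the bacterial volume V_B, and the component and total EPS
#' masses.
#'
#' @param masks Named list of [component_mask] objects (components among
#'   protein, polysaccharide, nucleic_acid, lipid, all_bacteria,
#'   dead_bacteria).
#' @param m_mg Measured biofilm mass in mg.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param strategy Total-volume strategy, see [total_biofilm_volume()].
#' @param bacteria Which mask defines V_B: `"all_bacteria"` (default) or
#'   `"live"` (all minus dead).
#' @return An object of class `biofilm_quant` with fields `m`, `V`, `V_I`
#'   (named), `V_B`, `EPS_I` (named), `EPS_II`.
#' @export
biofilm_quant <- function(masks, m_mg, voxel_size,
                          strategy = c("union", "convex_envelope"),
                          bacteria = c("all_bacteria", "live")) {
  strategy <- match.arg(strategy)
  bacteria <- match.arg(bacteria)
  if (m_mg < 0) abort_validation("m_mg must be non-negative")
  V <- total_biofilm_volume(masks, strategy, voxel_size)
  eps_here <- intersect(eps_components, names(masks))
  V_I <- vapply(masks[eps_here], component_volume, numeric(1), voxel_size = voxel_size)
  V_B <- 0
  if ("all_bacteria" %in% names(masks)) {
    if (bacteria == "all_bacteria" || !"dead_bacteria" %in% names(masks)) {
      V_B <- component_volume(masks[["all_bacteria"]], voxel_size)
    } else {
      live <- masks[["all_bacteria"]]$occupancy & !masks[["dead_bacteria"]]$occupancy
      V_B <- sum(live) * prod(as.numeric(voxel_size))
    }
  }
  V_B <- min(V_B, V)
  EPS_I <- vapply(V_I, function(v) eps_component_mass(m_mg, V, min(v, V)), numeric(1))
  structure(list(m = m_mg, V = V, V_I = V_I, V_B = V_B,
                 EPS_I = EPS_I, EPS_II = eps_total_mass(m_mg, V, V_B)),
            class = "biofilm_quant")
}

#' @export
print.biofilm_quant <- function(x, ...) {
  cat(sprintf("<biofilm_quant> m = %.4g mg, V = %.6g um^3, V_B = %.6g um^3, EPS_II = %.4g mg\n",
              x$m, x$V, x$V_B, x$EPS_II))
  for (cp in names(x$V_I)) {
    cat(sprintf("  %-14s V_I = %.6g um^3 (%.1f%%), EPS_I = %.4g mg\n",
                cp, x$V_I[[cp]], 100 * x$V_I[[cp]] / x$V, x$EPS_I[[cp]]))
  }
  invisible(x)
}

#' @export
as.data.frame.biofilm_quant <- function(x, ...) {
  data.frame(component = names(x$V_I),
             V_I_um3 = as.numeric(x$V_I),
             fraction = as.numeric(x$V_I) / x$V,
             EPS_I_mg = as.numeric(x$EPS_I),
             row.names = NULL)
}

#' Depth-resolved component composition profile
#'
#' Voxels are assigned to depth bins by their z-center distance from the
#' substrate face; per-bin counts are tallied per component and normalized
#' across components within each bin (each non-empty bin's proportions sum
#' to 1), matching a stacked-composition-by-depth reading. The alternative
#' normalization (within component across bins) is available via
#' `normalize = "within_component"`.
#'
#' @param masks Named list of [component_mask] objects sharing one shape.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param bin_width Depth bin width in um (default 10, the granularity at
#'   which depth enrichment is usually reported); must be `>= dz`.
#' @param origin `"substrate_at_z0"` if z = 1 is the substrate-adjacent
#'   plane, `"free_surface_at_z0"` otherwise.
#' @param normalize `"within_bin"` (default) or `"within_component"`.
#' @return An object of class `depth_profile`: `bin_edges` (length nbins+1,
#'   um), `counts` and `proportions` (nbins x components matrices).
#' @export
depth_profile <- function(masks, voxel_size, bin_width = 10,
                          origin = c("substrate_at_z0", "free_surface_at_z0"),
                          normalize = c("within_bin", "within_component")) {
  origin <- match.arg(origin)
  normalize <- match.arg(normalize)
  if (length(masks) == 0) abort_empty("no masks supplied")
  mask_shape_check(masks)
  voxel_size <- as.numeric(voxel_size)
  if (bin_width <= 0) abort_config("bin_width must be positive")
  if (bin_width < voxel_size[1])
    abort_config(sprintf("bin_width (%g um) must be at least the z-spacing (%g um)",
                         bin_width, voxel_size[1]))
  d <- dim(masks[[1]]$occupancy)
  nz <- d[1]; dz <- voxel_size[1]
  depth <- if (origin == "substrate_at_z0") (seq_len(nz) - 0.5) * dz
           else (nz - seq_len(nz) + 0.5) * dz
  nbins <- ceiling(nz * dz / bin_width)
  binidx <- pmin(floor(depth / bin_width) + 1L, nbins)
  comps <- names(masks) %||% paste0("component", seq_along(masks))
  counts <- matrix(0, nrow = nbins, ncol = length(masks),
                   dimnames = list(NULL, comps))
  for (k in seq_along(masks)) {
    zcounts <- rowSums(masks[[k]]$occupancy, dims = 1L)
    counts[, k] <- as.numeric(tapply(zcounts, binidx, sum)[as.character(seq_len(nbins))])
  }
  counts[is.na(counts)] <- 0
  proportions <- counts
  if (normalize == "within_bin") {
    tot <- rowSums(counts)
    nzb <- tot > 0
    proportions[nzb, ] <- counts[nzb, , drop = FALSE] / tot[nzb]
    proportions[!nzb, ] <- 0
  } else {
    ctot <- colSums(counts)
    for (k in seq_along(ctot)) {
      proportions[, k] <- if (ctot[k] > 0) counts[, k] / ctot[k] else 0
    }
  }
  structure(list(bin_edges = seq(0, nbins * bin_width, by = bin_width),
                 counts = counts, proportions = proportions,
                 bin_width = bin_width, origin = origin, normalize = normalize),
            class = "depth_profile")
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  nb <- nrow(x$counts)
  comps <- colnames(x$counts)
  data.frame(
    bin_lo_um = rep(x$bin_edges[seq_len(nb)], times = length(comps)),
    bin_hi_um = rep(x$bin_edges[-1], times = length(comps)),
    component = rep(comps, each = nb),
    count = as.vector(x$counts),
    proportion = as.vector(x$proportions),
    row.names = NULL)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d bins of %g um, components: %s\n",
              nrow(x$counts), x$bin_width, paste(colnames(x$counts), collapse = ", ")))
  print(utils::head(as.data.frame(x), 12))
  invisible(x)
}

#' Representative elementary volume (REV) analysis
#'
#' For each cubic subvolume edge length, draws `n_samples` random
#' axis-aligned subvolumes (with replacement, seeded) and measures the
#' component volume fraction in each; the coefficient of variation across
#' samples quantifies how representative that size is. The REV size is the
#' smallest size whose CV falls at or below `cv_tol`.
#'
#' @param mask A [component_mask].
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param sizes_um Strictly increasing cubic edge lengths in um; each must
#'   fit inside the mask extent on every axis.
#' @param n_samples Subvolumes per size (>= 2, default 20).
#' @param cv_tol CV tolerance defining the REV (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `rev_result`: `subvolume_sizes`, `estimates`
#'   (sizes x samples), `mean`, `cv`, `rev_size_um` (`NA` if no size
#'   qualifies).
#' @export
rev_analysis <- function(mask, voxel_size, sizes_um, n_samples = 20L,
                         cv_tol = 0.05, seed = 1L) {
  if (!inherits(mask, "component_mask")) abort_validation("mask must be a component_mask")
  voxel_size <- as.numeric(voxel_size)
  sizes_um <- as.numeric(sizes_um)
  if (length(sizes_um) == 0 || any(diff(sizes_um) <= 0))
    abort_config("sizes_um must be strictly increasing")
  if (n_samples < 2) abort_config("n_samples must be >= 2")
  d <- dim(mask$occupancy)
  ext_um <- d * voxel_size
  if (any(sizes_um > min(ext_um) + 1e-9))
    abort_config(sprintf("subvolume size %g um exceeds the mask extent (%g um)",
                         max(sizes_um), min(ext_um)))
  occ <- mask$occupancy
  estimates <- matrix(NA_real_, nrow = length(sizes_um), ncol = n_samples)
  with_seed(seed, {
    for (si in seq_along(sizes_um)) {
      nvox <- pmax(1L, pmin(as.integer(round(sizes_um[si] / voxel_size)), d))
      for (rep_i in seq_len(n_samples)) {
        o <- vapply(1:3, function(ax)
          sample.int(d[ax] - nvox[ax] + 1L, 1L), integer(1))
        sub <- occ[o[1]:(o[1] + nvox[1] - 1L),
                   o[2]:(o[2] + nvox[2] - 1L),
                   o[3]:(o[3] + nvox[3] - 1L)]
        estimates[si, rep_i] <- mean(sub)
      }
    }
  })
  means <- rowMeans(estimates)
  sds <- apply(estimates, 1L, stats::sd)
  cv <- ifelse(means > 0, sds / means, NA_real_)
  qual <- which(!is.na(cv) & cv <= cv_tol)
  structure(list(subvolume_sizes = sizes_um, estimates = estimates,
                 mean = means, cv = cv, cv_tol = cv_tol,
                 rev_size_um = if (length(qual)) sizes_um[min(qual)] else NA_real_),
            class = "rev_result")
}

#' @export
as.data.frame.rev_result <- function(x, ...) {
  data.frame(size_um = x$subvolume_sizes, mean = x$mean, cv = x$cv,
             row.names = NULL)
}

#' @export
print.rev_result <- function(x, ...) {
  cat(sprintf("<rev_result> cv_tol = %g, REV size = %s um\n", x$cv_tol,
              format(x$rev_size_um)))
  print(as.data.frame(x))
  invisible(x)
}
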