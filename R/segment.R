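# Threshold segmentation, binarization, mask cleanup, component assignment
# under the five-stain scheme, spectral cross-talk checking, and k-means
# clustering of depth layers.

#' Otsu threshold of a 3D volume
#'
#' Computed on the full 3D histogram (256 bins after min-max scaling) so that
#' one threshold applies to the whole stack and depth profiles from different
#' z-planes stay comparable.
#'
#' @param volume 3D intensity array.
#' @return Threshold on the original intensity scale.
#' @export
otsu_threshold <- function(volume) {
  lo <- min(volume); hi <- max(volume)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    abort_degenerate("intensity histogram is degenerate (constant volume); Otsu is undefined")
  nb <- 256L
  scaled <- (as.vector(volume) - lo) / (hi - lo)
  bins <- pmin(floor(scaled * nb), nb - 1L)
  h <- tabulate(bins + 1L, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(nb) - 0.5) / nb
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)               # threshold after bin k
  t01 <- k / nb
  lo + t01 * (hi - lo)
}

#' Threshold-segment a volume into a binary component mask
#'
#' Binarization rule: a voxel is foreground iff its intensity is `>=` the
#' threshold. The threshold actually used is always recorded on the mask for
#' provenance.
#'
#' @param volume 3D intensity array `(z, y, x)`.
#' @param method `"otsu"` or `"manual"`.
#' @param manual_t Threshold intensity; must be supplied iff
#'   `method = "manual"`.
#' @param component Optional component name attached to the mask.
#' @return A [component_mask].
#' @export
threshold_segment <- function(volume, method = c("otsu", "manual"),
                              manual_t = NULL, component = NA_character_) {
  method <- match.arg(method)
  if (length(dim(volume)) != 3L) abort_validation("volume must be a 3D array")
  if (method == "manual" && is.null(manual_t))
    abort_config("manual thresholding requires manual_t")
  if (method == "otsu" && !is.null(manual_t))
    abort_config("manual_t must not be supplied with method = 'otsu'")
  t <- if (method == "otsu") otsu_threshold(volume) else as.numeric(manual_t)
  component_mask(volume >= t, component = component,
                 threshold_used = t, method = method)
}

# connectivity offsets: positive half-space only (each undirected neighbor
# pair is visited once)
conn_offsets <- function(connectivity) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dz) + abs(g$dy) + abs(g$dx) == 1L, ]
  else if (connectivity != 26L) abort_config("connectivity must be 6 or 26")
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) | (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, , drop = FALSE])
}

# Label connected components of a logical (z,y,x) array. Returns an integer
# array, 0 = background. Built on igraph's component search.
label_components <- function(occ, connectivity = 26L) {
  d <- dim(occ)
  fg <- which(occ)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  rank <- integer(prod(d))
  rank[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- conn_offsets(connectivity)
  e1 <- integer(0); e2 <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nz <- co[, 1] + offs[i, 1]; ny <- co[, 2] + offs[i, 2]; nx <- co[, 3] + offs[i, 3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
    if (!any(ok)) next
    nlin <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
    both <- occ[nlin]
    if (!any(both)) next
    e1 <- c(e1, rank[fg[ok][both]])
    e2 <- c(e2, rank[nlin[both]])
  }
  g <- igraph::make_graph(edges = as.vector(rbind(e1, e2)), n = length(fg),
                          directed = FALSE)
  membership <- igraph::components(g)$membership
  lab[fg] <- as.integer(membership)
  lab
}

#' Remove small objects and fill internal cavities in a mask
#'
#' Objects are 26-connected foreground components; components with fewer than
#' `min_object_voxels` voxels are removed. Hole filling closes background
#' cavities (6-connected background components not reaching the stack
#' border).
#'
#' @param mask A [component_mask].
#' @param min_object_voxels Minimum object size to keep (0 = keep all).
#' @param fill_holes Fill enclosed 3D cavities.
#' @param connectivity Foreground connectivity, 26 (default) or 6.
#' @return The cleaned [component_mask].
#' @export
clean_mask <- function(mask, min_object_voxels = 0L, fill_holes = FALSE,
                       connectivity = 26L) {
  if (!inherits(mask, "component_mask")) abort_validation("mask must be a component_mask")
  if (min_object_voxels < 0) abort_config("min_object_voxels must be >= 0")
  occ <- mask$occupancy
  if (min_object_voxels > 0L && any(occ)) {
    lab <- label_components(occ, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_voxels)
    occ <- array(lab %in% keep & lab > 0L, dim(occ))
  }
  if (fill_holes && any(occ)) {
    bg <- !occ
    blab <- label_components(bg, 6L)        # complement connectivity of 26 is 6
    d <- dim(occ)
    border <- unique(c(blab[c(1, d[1]), , ], blab[, c(1, d[2]), ], blab[, , c(1, d[3])]))
    border <- border[border > 0L]
    holes <- bg & !(blab %in% border)
    occ <- occ | array(holes, d)
  }
  component_mask(occ, component = mask$component,
                 threshold_used = mask$threshold_used, method = mask$method)
}

bfq_components <- c("protein", "polysaccharide", "nucleic_acid", "lipid",
                    "all_bacteria", "dead_bacteria")
eps_components <- c("protein", "polysaccharide", "nucleic_acid", "lipid")

#' Fluorophore-to-component channel map
#'
#' @param entries A data.frame or list of lists with fields `fluorophore`,
#'   `excitation_nm` (numeric vector), `emission_nm` (numeric vector),
#'   `component` (one of protein, polysaccharide, nucleic_acid, lipid,
#'   all_bacteria, dead_bacteria), and `stain_mode` (`"mixed"` or
#'   `"single"`).
#' @return An object of class `channel_map` (a list of validated entries).
#' @export
channel_map <- function(entries) {
  if (is.data.frame(entries)) entries <- split(entries, seq_len(nrow(entries)))
  entries <- lapply(entries, function(e) {
    e <- as.list(e)
    ex <- unlist(e$excitation_nm); em <- unlist(e$emission_nm)
    if (length(ex) == 0 || length(em) == 0)
      abort_config("excitation and emission wavelength lists must be non-empty")
    if (any(ex < 200 | ex > 700) || any(em < 200 | em > 700))
      abort_config("wavelengths must lie in [200, 700] nm")
    if (!e$component %in% bfq_components)
      abort_config(sprintf("unknown component '%s'", e$component))
    if (!(e$stain_mode %||% "mixed") %in% c("mixed", "single"))
      abort_config("stain_mode must be 'mixed' or 'single'")
    list(fluorophore = as.character(e$fluorophore), excitation_nm = as.numeric(ex),
         emission_nm = as.numeric(em), component = as.character(e$component),
         stain_mode = as.character(e$stain_mode %||% "mixed"))
  })
  comps <- vapply(entries, `[[`, character(1), "component")
  if (anyDuplicated(comps)) abort_config("components must be unique across entries")
  structure(entries, class = "channel_map")
}

#' The five-dye staining scheme used for sewer-biofilm imaging
#'
#' Calcofluor White (polysaccharides), FITC (proteins), Nile Red (lipids),
#' Rhodamine (all bacteria) and propidium iodide (dead bacteria), with their
#' published excitation/emission maxima. Proteins, polysaccharides and
#' nucleic-acid dyes are applied as a mixture; lipid and bacterial dyes are
#' applied singly.
#'
#' @return A [channel_map] with five entries.
#' @export
default_channel_map <- function() {
  channel_map(list(
    list(fluorophore = "CalcofluorWhite", excitation_nm = c(385, 395, 405),
         emission_nm = c(437, 440, 445), component = "polysaccharide",
         stain_mode = "mixed"),
    list(fluorophore = "FITC", excitation_nm = c(490, 494),
         emission_nm = c(520, 525), component = "protein", stain_mode = "mixed"),
    list(fluorophore = "NileRed", excitation_nm = c(515, 555, 559),
         emission_nm = c(590, 640), component = "lipid", stain_mode = "single"),
    list(fluorophore = "Rhodamine", excitation_nm = 550,
         emission_nm = 573, component = "all_bacteria", stain_mode = "single"),
    list(fluorophore = "PI", excitation_nm = c(305, 536, 538),
         emission_nm = 617, component = "dead_bacteria", stain_mode = "single")
  ))
}

#' Check fluorophore pairs for emission cross-talk
#'
#' Each fluorophore's emission band is the `[min, max]` envelope of its
#' listed emission maxima, dilated by `overlap_margin_nm` on both sides.
#' Every unordered pair whose dilated bands intersect is flagged. An empty
#' result means the dye set is spectrally separable at that margin.
#'
#' @param map A [channel_map].
#' @param overlap_margin_nm Dilation margin in nm (default 10).
#' @return A data.frame with columns `stain_a`, `stain_b`, `overlap_lo_nm`,
#'   `overlap_hi_nm`, sorted and order-invariant.
#' @export
crosstalk_check <- function(map, overlap_margin_nm = 10) {
  if (!inherits(map, "channel_map")) map <- channel_map(map)
  if (overlap_margin_nm < 0) abort_config("overlap_margin_nm must be >= 0")
  n <- length(map)
  out <- list()
  if (n >= 2) {
    bands <- lapply(map, function(e)
      c(min(e$emission_nm) - overlap_margin_nm, max(e$emission_nm) + overlap_margin_nm))
    names <- vapply(map, `[[`, character(1), "fluorophore")
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lo <- max(bands[[i]][1], bands[[j]][1])
        hi <- min(bands[[i]][2], bands[[j]][2])
        if (lo <= hi) {
          pair <- sort(c(names[i], names[j]))
          out[[length(out) + 1L]] <- data.frame(
            stain_a = pair[1], stain_b = pair[2],
            overlap_lo_nm = lo, overlap_hi_nm = hi,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stain_a = character(0), stain_b = character(0),
               overlap_lo_nm = numeric(0), overlap_hi_nm = numeric(0))
  res <- res[order(res$stain_a, res$stain_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Segment all channels and assign voxels to biofilm components
#'
#' Each mapped channel is thresholded independently (Otsu by default,
#' per-component manual overrides via `thresholds`). Voxels positive in more
#' than one EPS channel (protein/polysaccharide/nucleic_acid/lipid) are
#' assigned to the channel with the higher per-channel z-score, so that each
#' voxel belongs to at most one EPS component. Bacterial channels are never
#' competed against EPS channels: the staining scheme applies them to
#' coexist with the matrix. When both bacterial masks are present, the
#' dead-bacteria (PI) mask is intersected with the all-bacteria mask and the
#' number of PI-only voxels is reported via a message.
#'
#' A channel with constant intensity (e.g. an all-zero stack) yields an
#' empty mask with a message rather than a degenerate-histogram error, so a
#' blank acquisition degrades gracefully.
#'
#' @param stack An [image_stack] whose `channel_labels` contain, for each map
#'   entry, either the fluorophore name or the component name.
#' @param map A [channel_map].
#' @param thresholds Optional named list `component -> threshold` of manual
#'   intensity thresholds.
#' @return Named list of [component_mask] objects, one per mapped component.
#' @export
assign_components <- function(stack, map = default_channel_map(), thresholds = NULL) {
  if (!inherits(stack, "image_stack")) abort_validation("stack must be an image_stack")
  if (!inherits(map, "channel_map")) map <- channel_map(map)
  masks <- list()
  zscores <- list()
  for (e in map) {
    ch <- match(e$fluorophore, stack$channel_labels)
    if (is.na(ch)) ch <- match(e$component, stack$channel_labels)
    if (is.na(ch))
      abort_config(sprintf("no stack channel for fluorophore '%s' / component '%s'",
                           e$fluorophore, e$component))
    vol <- get_channel(stack, ch)
    manual <- thresholds[[e$component]]
    m <- if (!is.null(manual)) {
      threshold_segment(vol, "manual", manual_t = manual, component = e$component)
    } else {
      tryCatch(threshold_segment(vol, "otsu", component = e$component),
               bfq_degenerate_error = function(err) {
                 message(sprintf("channel '%s' is constant; producing an empty %s mask",
                                 e$fluorophore, e$component))
                 component_mask(array(FALSE, dim(vol)), component = e$component,
                                threshold_used = NA_real_, method = "otsu")
               })
    }
    masks[[e$component]] <- m
    sdv <- stats::sd(vol)
    zscores[[e$component]] <- if (is.na(sdv) || sdv == 0) array(0, dim(vol))
                              else (vol - mean(vol)) / sdv
  }
  eps_here <- intersect(eps_components, names(masks))
  if (length(eps_here) >= 2) {
    occs <- lapply(masks[eps_here], `[[`, "occupancy")
    npos <- Reduce(`+`, lapply(occs, `*`, 1L))
    conflict <- which(npos >= 2L)
    if (length(conflict)) {
      zmat <- vapply(eps_here, function(cp) {
        z <- zscores[[cp]][conflict]
        z[!occs[[cp]][conflict]] <- -Inf     # only positive channels compete
        z
      }, numeric(length(conflict)))
      if (is.null(dim(zmat))) zmat <- matrix(zmat, nrow = 1L)
      winner <- max.col(zmat, ties.method = "first")
      for (k in seq_along(eps_here)) {
        cp <- eps_here[k]
        lose <- conflict[winner != k]
        occ <- masks[[cp]]$occupancy
        occ[lose] <- FALSE
        masks[[cp]] <- component_mask(occ, component = cp,
                                      threshold_used = masks[[cp]]$threshold_used,
                                      method = masks[[cp]]$method)
      }
    }
  }
  if (all(c("all_bacteria", "dead_bacteria") %in% names(masks))) {
    dead <- masks[["dead_bacteria"]]$occupancy
    alln <- masks[["all_bacteria"]]$occupancy
    pi_only <- sum(dead & !alln)
    if (pi_only > 0)
      message(sprintf("%d PI-positive voxels outside the all-bacteria mask were dropped", pi_only))
    masks[["dead_bacteria"]] <- component_mask(
      dead & alln, component = "dead_bacteria",
      threshold_used = masks[["dead_bacteria"]]$threshold_used,
      method = masks[["dead_bacteria"]]$method)
  }
  masks
}

#' Cluster depth bins by composition with k-means
#'
#' The feature of each non-empty depth bin is its composition vector (the
#' per-component proportions from [depth_profile()]). Clustering uses
#' standard k-means with `n_restarts` seeded restarts, so a fixed seed
#' reproduces labels exactly.
#'
#' @param profile A `depth_profile` object.
#' @param k Number of clusters, `1 <= k <=` number of non-empty bins.
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 10).
#' @return An object of class `layer_clustering`: `k`, `labels` (per depth
#'   bin; `NA` for empty bins), `centers` (k x components), `inertia` (total
#'   within-cluster sum of squares).
#' @export
kmeans_layers <- function(profile, k, seed = 1L, n_restarts = 10L) {
  if (!inherits(profile, "depth_profile")) abort_validation("profile must be a depth_profile")
  nonempty <- which(rowSums(profile$counts) > 0)
  if (k < 1 || k > length(nonempty))
    abort_config(sprintf("k must be between 1 and the number of non-empty bins (%d)",
                         length(nonempty)))
  feats <- profile$proportions[nonempty, , drop = FALSE]
  fit <- with_seed(seed, stats::kmeans(feats, centers = k, nstart = n_restarts,
                                       iter.max = 100L))
  labels <- rep(NA_integer_, nrow(profile$counts))
  labels[nonempty] <- fit$cluster
  structure(list(k = as.integer(k), labels = labels, centers = fit$centers,
                 inertia = fit$tot.withinss),
            class = "layer_clustering")
}
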