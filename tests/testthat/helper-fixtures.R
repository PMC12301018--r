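# Shared fixtures and independent oracles used across the suite.

# digitized sphere mask of radius r voxels centered in an n^3 grid
make_sphere_mask <- function(r, n = 2 * r + 6, component = "sphere") {
  g <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(g^2, g^2, `+`), g^2, `+`)
  component_mask(array(d2 <= r^2, c(n, n, n)), component = component,
                 method = "manual")
}

# random 0/1 mask
make_random_mask <- function(dim3, p = 0.3, seed = 1, component = "rand") {
  occ <- with_seed_test(seed, array(stats::runif(prod(dim3)) < p, dim3))
  component_mask(occ, component = component, method = "manual")
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force voxel count by explicit triple loop (oracle for component_volume)
brute_force_count <- function(occ) {
  d <- dim(occ)
  n <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (occ[z, y, x]) n <- n + 1L
  }
  n
}

# independent per-voxel reimplementation of the EPS-channel precedence rule
# (oracle for assign_components): each channel thresholded at its own
# threshold, conflicts resolved by the larger z-score
brute_force_assign <- function(vols, thresholds) {
  d <- dim(vols[[1]])
  zs <- lapply(vols, function(v) (v - mean(v)) / stats::sd(v))
  out <- lapply(vols, function(v) array(FALSE, d))
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    pos <- names(vols)[vapply(names(vols), function(cp)
      vols[[cp]][z, y, x] >= thresholds[[cp]], logical(1))]
    if (length(pos) == 0) next
    if (length(pos) == 1) { out[[pos]][z, y, x] <- TRUE; next }
    scores <- vapply(pos, function(cp) zs[[cp]][z, y, x], numeric(1))
    win <- pos[which.max(scores)]
    out[[win]][z, y, x] <- TRUE
  }
  out
}

# shoelace polygon area (oracle for convex-envelope slices)
shoelace_area <- function(px, py) {
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# pairwise interval-intersection oracle for crosstalk_check
crosstalk_oracle <- function(map, margin) {
  nm <- vapply(map, `[[`, character(1), "fluorophore")
  pairs <- character(0)
  for (i in seq_along(map)) for (j in seq_along(map)) {
    if (i >= j) next
    a <- range(map[[i]]$emission_nm) + c(-margin, margin)
    b <- range(map[[j]]$emission_nm) + c(-margin, margin)
    if (max(a[1], b[1]) <= min(a[2], b[2]))
      pairs <- c(pairs, paste(sort(c(nm[i], nm[j])), collapse = "|"))
  }
  sort(pairs)
}

# tiny two-component stack with disjoint supports, used in several tests
tiny_two_channel_stack <- function() {
  d <- c(8L, 8L, 8L)
  a <- array(10, d); b <- array(10, d)
  a[2:4, 2:4, 2:4] <- 200     # protein block
  b[5:7, 5:7, 5:7] <- 180     # lipid block
  v <- array(0, c(2, d))
  v[1, , , ] <- a; v[2, , , ] <- b
  image_stack(v, c(1, 1, 1), c("protein", "lipid"))
}

simple_map <- function(components) {
  channel_map(lapply(components, function(cp)
    list(fluorophore = cp, excitation_nm = 300, emission_nm = 400,
         component = cp, stain_mode = "single")))
}
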