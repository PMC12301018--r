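test_that("component volume is voxel count times voxel volume", {
  occ <- array(FALSE, c(10, 10, 10)); occ[1:10, 1:10, 1:10][1:1000] <- TRUE
  m <- component_mask(occ, "x", method = "manual")
  expect_equal(component_volume(m, c(1.0, 0.5, 0.5)), 250)
  empty <- component_mask(array(FALSE, c(4, 4, 4)), "e", method = "manual")
  expect_equal(component_volume(empty, c(1, 1, 1)), 0)
  rnd <- make_random_mask(c(16, 16, 16), p = 0.35, seed = 6)
  expect_equal(component_volume(rnd, c(0.5, 0.4, 0.3)),
               brute_force_count(rnd$occupancy) * 0.5 * 0.4 * 0.3)
})

test_that("total volume: union additivity and convex envelope vs slice-hull oracle", {
  d <- c(5, 16, 16)
  a <- array(FALSE, d); a[, 1:4, 1:4] <- TRUE          # 16 voxels per slice
  b <- array(FALSE, d); b[, 13:16, 13:16] <- TRUE
  ma <- component_mask(a, "a", method = "manual")
  mb <- component_mask(b, "b", method = "manual")
  expect_equal(total_biofilm_volume(list(ma), "union", c(1, 1, 1)),
               component_volume(ma, c(1, 1, 1)))
  expect_equal(total_biofilm_volume(list(ma, mb), "union", c(1, 1, 1)),
               5 * 32)
  hull <- total_biofilm_volume(list(ma, mb), "convex_envelope", c(1, 1, 1))
  expect_gte(hull, 5 * 32)
  # analytic slice hull: 16x16 square minus two 12x12/2 corner triangles
  expect_equal(hull, 5 * (256 - 144))
  expect_error(total_biofilm_volume(list(), "union"), class = "bfq_empty_input_error")
  empty <- component_mask(array(FALSE, d), "e", method = "manual")
  expect_error(total_biofilm_volume(list(empty), "union"),
               class = "bfq_empty_input_error")
})

test_that("convex envelope of a random blob matches an independent hull-area oracle", {
  m <- make_sphere_mask(6, n = 16)
  vox <- c(1, 0.5, 0.5)
  hull <- total_biofilm_volume(list(m), "convex_envelope", vox)
  oracle <- 0
  for (z in 1:16) {
    pts <- which(m$occupancy[z, , ], arr.ind = TRUE)
    if (nrow(pts) == 0) next
    yy <- c(pts[, 1] - 1, pts[, 1] - 1, pts[, 1], pts[, 1]) * vox[2]
    xx <- c(pts[, 2] - 1, pts[, 2], pts[, 2] - 1, pts[, 2]) * vox[3]
    h <- grDevices::chull(xx, yy)
    oracle <- oracle + shoelace_area(xx[h], yy[h]) * vox[1]
  }
  expect_equal(hull, oracle, tolerance = 1e-12)
})

test_that("EPS mass formulas obey their defining identities and limits", {
  expect_equal(eps_component_mass(10, 100, 30), 3.0)
  expect_equal(eps_component_mass(10, 50, 0), 0)
  expect_equal(eps_component_mass(10, 50, 50), 10)
  expect_equal(eps_total_mass(12, 100, 25), 9.0)
  expect_equal(eps_total_mass(12, 100, 100), 0)
  expect_equal(eps_total_mass(12, 100, 0), 12)
  expect_error(eps_component_mass(10, 0, 0), class = "bfq_division_error")
  expect_error(eps_component_mass(10, 100, 101), class = "bfq_validation_error")
  expect_error(eps_total_mass(10, 100, 101), class = "bfq_validation_error")
})

test_that("mass estimates are invariant to rescaling all volumes", {
  for (s in c(1e-3, 1, 1e6)) {
    expect_equal(eps_component_mass(7, 120 * s, 42 * s), eps_component_mass(7, 120, 42))
    expect_equal(eps_total_mass(7, 120 * s, 30 * s), eps_total_mass(7, 120, 30))
  }
})

test_that("component masses conserve total mass for disjoint masks", {
  d <- c(12, 12, 12)
  masks <- list()
  slabs <- list(protein = 1:3, polysaccharide = 4:6, lipid = 7:8,
                all_bacteria = 9:12)
  for (cp in names(slabs)) {
    occ <- array(FALSE, d); occ[slabs[[cp]], , ] <- TRUE
    masks[[cp]] <- component_mask(occ, cp, method = "manual")
  }
  q <- biofilm_quant(masks, m_mg = 20, voxel_size = c(1, 1, 1))
  expect_lte(sum(q$EPS_I), q$m + 1e-12)
  expect_equal(q$EPS_II, eps_total_mass(q$m, q$V, q$V_B))
  for (cp in names(q$V_I)) {
    expect_equal(q$EPS_I[[cp]], q$m * q$V_I[[cp]] / q$V)
  }
  # disjoint slabs: masses proportional to slab thickness
  expect_equal(as.numeric(q$EPS_I["protein"]), 20 * 3 / 12)
  expect_equal(q$EPS_II, 20 * 8 / 12)
})

test_that("depth profile normalizes within bins and conserves counts", {
  d <- c(25, 6, 6)
  occ <- array(FALSE, d); occ[6:15, , ] <- TRUE
  m <- component_mask(occ, "protein", method = "manual")
  prof <- depth_profile(list(protein = m), c(2, 1, 1), bin_width = 10)
  nonzero <- rowSums(prof$counts) > 0
  expect_true(all(prof$proportions[nonzero, "protein"] == 1))
  expect_true(all(prof$proportions[!nonzero, ] == 0))
  expect_equal(sum(prof$counts[, "protein"]), sum(occ))
  # all-empty masks: all-zero profile
  e <- component_mask(array(FALSE, d), "lipid", method = "manual")
  prof0 <- depth_profile(list(lipid = e), c(1, 1, 1), bin_width = 10)
  expect_true(all(prof0$counts == 0) && all(prof0$proportions == 0))
  expect_error(depth_profile(list(protein = m), c(2, 1, 1), bin_width = 1),
               class = "bfq_config_error")
})

test_that("depth origin flips which physical face is depth zero", {
  d <- c(20, 4, 4)
  occ <- array(FALSE, d); occ[1:5, , ] <- TRUE   # first z-planes
  m <- component_mask(occ, "all_bacteria", method = "manual")
  sub <- depth_profile(list(all_bacteria = m), c(1, 1, 1), 10, origin = "substrate_at_z0")
  free <- depth_profile(list(all_bacteria = m), c(1, 1, 1), 10, origin = "free_surface_at_z0")
  expect_equal(which.max(sub$counts[, 1]), 1L)
  expect_equal(which.max(free$counts[, 1]), 2L)
  expect_equal(sum(sub$counts), sum(free$counts))
})

test_that("REV analysis: trivial limits and config validation", {
  full <- component_mask(array(TRUE, c(32, 32, 32)), "x", method = "manual")
  res <- rev_analysis(full, c(1, 1, 1), sizes_um = c(4, 8, 16), n_samples = 5, seed = 2)
  expect_true(all(res$estimates == 1))
  expect_true(all(res$cv == 0))
  expect_equal(res$rev_size_um, 4)
  # subvolume equal to the full extent reproduces the global fraction exactly
  rnd <- make_random_mask(c(16, 16, 16), p = 0.5, seed = 8)
  res2 <- rev_analysis(rnd, c(1, 1, 1), sizes_um = 16, n_samples = 3, seed = 1)
  expect_true(all(res2$estimates == mean(rnd$occupancy)))
  expect_equal(res2$cv, 0)
  expect_error(rev_analysis(rnd, c(1, 1, 1), sizes_um = c(8, 64), n_samples = 3),
               class = "bfq_config_error")
  expect_error(rev_analysis(rnd, c(1, 1, 1), sizes_um = 8, n_samples = 1),
               class = "bfq_config_error")
  # seeded reproducibility
  a <- rev_analysis(rnd, c(1, 1, 1), sizes_um = c(4, 8), n_samples = 6, seed = 5)
  b <- rev_analysis(rnd, c(1, 1, 1), sizes_um = c(4, 8), n_samples = 6, seed = 5)
  expect_identical(a$estimates, b$estimates)
})
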