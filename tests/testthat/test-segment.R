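test_that("Otsu separates a synthetic blob field from background (Dice > 0.99)", {
  truth <- make_sphere_mask(8, n = 24)$occupancy
  vol <- with_seed_test(2, {
    v <- array(stats::rnorm(length(truth), 10, 2), dim(truth))
    v[truth] <- stats::rnorm(sum(truth), 200, 10)
    pmax(v, 0)
  })
  m <- threshold_segment(vol, "otsu", component = "protein")
  expect_gt(dice_coef(m$occupancy, truth), 0.99)
  expect_identical(m$method, "otsu")
  expect_true(is.finite(m$threshold_used))
})

test_that("manual thresholding obeys its contract and degenerate Otsu errors", {
  vol <- array(stats::runif(4^3) + 0.5, c(4, 4, 4))
  m <- threshold_segment(vol, "manual", manual_t = 0)
  expect_true(all(m$occupancy))
  expect_error(threshold_segment(vol, "manual"), class = "bfq_config_error")
  expect_error(threshold_segment(array(5, c(4, 4, 4)), "otsu"),
               class = "bfq_degenerate_error")
})

test_that("raising a manual threshold never increases mask volume", {
  vol <- with_seed_test(3, array(stats::runif(12^3) * 100, c(12, 12, 12)))
  vols <- vapply(seq(0, 100, by = 10), function(t)
    sum(threshold_segment(vol, "manual", manual_t = t)$occupancy), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("clean_mask removes small objects and fills cavities by exact counts", {
  occ <- array(FALSE, c(16, 16, 16))
  occ[2:3, 2:3, 2:3] <- TRUE                        # 8-voxel object
  occ[8:15, 8:15, 8:15] <- TRUE                     # 512-voxel object
  m <- component_mask(occ, "x", method = "manual")
  expect_identical(clean_mask(m, 0)$occupancy, occ)
  kept <- clean_mask(m, 10)$occupancy
  expect_equal(sum(kept), 512)
  expect_false(any(kept[2:3, 2:3, 2:3]))
  # hollow shell: cavity refilled exactly
  shell <- array(FALSE, c(14, 14, 14))
  shell[3:11, 3:11, 3:11] <- TRUE
  cavity <- array(FALSE, c(14, 14, 14))
  cavity[5:9, 5:9, 5:9] <- TRUE
  hollow <- component_mask(shell & !cavity, "x", method = "manual")
  filled <- clean_mask(hollow, 0, fill_holes = TRUE)
  expect_equal(sum(filled$occupancy), sum(shell))
  expect_equal(sum(filled$occupancy) - sum(hollow$occupancy), sum(cavity))
})

test_that("cross-talk flags for the five-dye scheme match the interval oracle", {
  map <- default_channel_map()
  res <- crosstalk_check(map, overlap_margin_nm = 10)
  got <- sort(paste(res$stain_a, res$stain_b, sep = "|"))
  expect_identical(got, crosstalk_oracle(map, 10))
  # the five-dye scheme at 10 nm: Nile Red collides with both PI and Rhodamine
  expect_setequal(got, c("NileRed|PI", "NileRed|Rhodamine"))
  # symmetric in entry order
  res_rev <- crosstalk_check(channel_map(rev(unclass(map))), overlap_margin_nm = 10)
  expect_identical(res, res_rev)
})

test_that("cross-talk base cases: single entry, identical dyes, margin sweep", {
  single <- channel_map(list(list(fluorophore = "FITC", excitation_nm = 490,
                                  emission_nm = c(520, 525), component = "protein",
                                  stain_mode = "mixed")))
  expect_equal(nrow(crosstalk_check(single, 10)), 0)
  twin <- channel_map(list(
    list(fluorophore = "A", excitation_nm = 490, emission_nm = 520,
         component = "protein", stain_mode = "single"),
    list(fluorophore = "B", excitation_nm = 490, emission_nm = 520,
         component = "lipid", stain_mode = "single")))
  expect_equal(nrow(crosstalk_check(twin, 0)), 1)
  # oracle agreement across margins
  map <- default_channel_map()
  for (margin in c(0, 5, 20, 50)) {
    res <- crosstalk_check(map, margin)
    expect_identical(sort(paste(res$stain_a, res$stain_b, sep = "|")),
                     crosstalk_oracle(map, margin))
  }
})

test_that("component assignment matches the per-voxel precedence oracle", {
  d <- c(10, 10, 10)
  vols <- with_seed_test(9, list(
    protein = array(stats::rnorm(prod(d), 50, 30), d),
    lipid = array(stats::rnorm(prod(d), 60, 25), d)))
  vols <- lapply(vols, pmax, 0)
  v <- array(0, c(2, d)); v[1, , , ] <- vols$protein; v[2, , , ] <- vols$lipid
  st <- image_stack(v, c(1, 1, 1), c("protein", "lipid"))
  th <- list(protein = 70, lipid = 75)
  masks <- assign_components(st, simple_map(c("protein", "lipid")), thresholds = th)
  oracle <- brute_force_assign(vols, th)
  expect_identical(masks$protein$occupancy, oracle$protein)
  expect_identical(masks$lipid$occupancy, oracle$lipid)
  # no voxel in more than one EPS component
  expect_false(any(masks$protein$occupancy & masks$lipid$occupancy))
})

test_that("disjoint channels reduce to single-channel segmentations; zero stacks give empty masks", {
  st <- tiny_two_channel_stack()
  masks <- assign_components(st, simple_map(c("protein", "lipid")))
  solo_p <- threshold_segment(get_channel(st, "protein"), "otsu")
  solo_l <- threshold_segment(get_channel(st, "lipid"), "otsu")
  expect_identical(masks$protein$occupancy, solo_p$occupancy)
  expect_identical(masks$lipid$occupancy, solo_l$occupancy)
  zero <- image_stack(array(0, c(2, 4, 4, 4)), c(1, 1, 1), c("protein", "lipid"))
  expect_message(zm <- assign_components(zero, simple_map(c("protein", "lipid"))),
                 "constant")
  expect_false(any(zm$protein$occupancy))
  expect_false(any(zm$lipid$occupancy))
  expect_error(assign_components(st, simple_map(c("protein", "nucleic_acid"))),
               class = "bfq_config_error")
})

test_that("dead bacteria are intersected with the all-bacteria mask", {
  d <- c(6, 6, 6)
  va <- array(10, d); va[1:3, , ] <- 200        # all bacteria shallow half
  vd <- array(10, d); vd[3:4, , ] <- 200        # PI straddles the boundary
  v <- array(0, c(2, d)); v[1, , , ] <- va; v[2, , , ] <- vd
  st <- image_stack(v, c(1, 1, 1), c("all_bacteria", "dead_bacteria"))
  expect_message(
    masks <- assign_components(st, simple_map(c("all_bacteria", "dead_bacteria"))),
    "PI-positive")
  expect_true(all(masks$dead_bacteria$occupancy[masks$dead_bacteria$occupancy] &
                  masks$all_bacteria$occupancy[masks$dead_bacteria$occupancy]))
  expect_equal(sum(masks$dead_bacteria$occupancy), 36)  # only z = 3 survives
})

test_that("k-means layer clustering recovers two composition regimes", {
  # 8 bins: first 4 dominated by component 1, last 4 by component 2
  occ1 <- array(FALSE, c(40, 8, 8)); occ1[1:20, , 1:7] <- TRUE
  occ1[21:40, , 1] <- TRUE
  occ2 <- array(FALSE, c(40, 8, 8)); occ2[21:40, , 2:8] <- TRUE
  occ2[1:20, , 8] <- TRUE
  masks <- list(protein = component_mask(occ1, "protein", method = "manual"),
                lipid = component_mask(occ2, "lipid", method = "manual"))
  prof <- depth_profile(masks, c(1, 1, 1), bin_width = 5)
  cl <- kmeans_layers(prof, k = 2, seed = 42)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[8])
  # exhaustive-enumeration oracle: best 2-partition by within-SS
  feats <- prof$proportions
  best <- NULL; best_ss <- Inf
  for (code in 0:(2^8 - 1)) {
    lab <- as.integer(intToBits(code))[1:8]
    if (length(unique(lab)) != 2) next
    ss <- sum(vapply(0:1, function(g) {
      rows <- feats[lab == g, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows))^2)
    }, numeric(1)))
    if (ss < best_ss) { best_ss <- ss; best <- lab }
  }
  same <- all((cl$labels - 1) == best) || all((cl$labels - 1) == (1 - best))
  expect_true(same)
  expect_equal(cl$inertia, best_ss, tolerance = 1e-9)
})

test_that("k-means respects k bounds and seeding", {
  occ <- array(FALSE, c(30, 6, 6)); occ[1:30, 1:3, ] <- TRUE
  masks <- list(protein = component_mask(occ, "protein", method = "manual"))
  prof <- depth_profile(masks, c(1, 1, 1), bin_width = 10)
  one <- kmeans_layers(prof, k = 1, seed = 1)
  expect_true(all(one$labels[!is.na(one$labels)] == 1))
  expect_equal(as.numeric(one$centers), unname(colMeans(prof$proportions)))
  expect_error(kmeans_layers(prof, k = 5, seed = 1), class = "bfq_config_error")
  # reproducibility under a fixed seed
  occ2 <- array(FALSE, c(30, 6, 6)); occ2[1:10, 4:6, ] <- TRUE; occ2[21:30, 4:5, ] <- TRUE
  masks$lipid <- component_mask(occ2, "lipid", method = "manual")
  prof2 <- depth_profile(masks, c(1, 1, 1), bin_width = 5)
  a <- kmeans_layers(prof2, k = 3, seed = 7)
  b <- kmeans_layers(prof2, k = 3, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
})
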