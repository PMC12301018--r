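test_that("EEM delimited-text round trip is exact and bad grids fail", {
  eem <- generate_eem(list(list(ex_nm = 275, em_nm = 335, height = 100, sd_nm = 12)),
                      noise_sd = 1, seed = 3, label = "FQHC")
  f <- withr::local_tempfile(fileext = ".csv")
  write_eem(eem, f)
  back <- read_eem(f, label = "FQHC")
  expect_equal(back$ex_nm, eem$ex_nm)
  expect_equal(back$em_nm, eem$em_nm)
  expect_equal(back$intensity, eem$intensity, tolerance = 0)
  # drop one emission column -> non-uniform grid -> format error
  lines <- readLines(f)
  broken <- vapply(strsplit(lines, ","), function(p) paste(p[-5], collapse = ","),
                   character(1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(broken, f2)
  expect_error(read_eem(f2), class = "bfq_format_error")
})

test_that("negative EEM cells are clipped to zero with a logged count", {
  eem <- generate_eem(list(), noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_eem(eem, f)
  lines <- readLines(f)
  parts <- strsplit(lines[2], ",")[[1]]
  parts[3] <- "-3"
  lines[2] <- paste(parts, collapse = ",")
  writeLines(lines, f)
  expect_message(back <- read_eem(f), "clipped 1 negative")
  expect_equal(back$intensity[1, 2], 0)
  expect_true(all(back$intensity >= 0))
})

test_that("scatter masking zeroes the Rayleigh diagonals and spares far peaks", {
  grid <- eem_default_grid()
  flat <- eem_matrix(grid$ex_nm, grid$em_nm,
                     matrix(1, length(grid$ex_nm), length(grid$em_nm)))
  m0 <- mask_scatter(flat, 0, 0)
  EX <- matrix(grid$ex_nm, length(grid$ex_nm), length(grid$em_nm))
  EM <- matrix(grid$em_nm, length(grid$ex_nm), length(grid$em_nm), byrow = TRUE)
  expect_true(all(m0$intensity[EM == EX] == 0))
  expect_true(all(m0$intensity[EM == 2 * EX] == 0))
  expect_true(all(m0$intensity[EM != EX & EM != 2 * EX] == 1))
  m10 <- mask_scatter(flat, 10, 0)
  expect_true(all(m10$intensity[abs(EM - EX) <= 10] == 0))
  expect_true(all(m10$intensity[abs(EM - EX) > 10 & EM != 2 * EX] == 1))
  # a protein-like peak far from both diagonals is untouched
  pk <- generate_eem(list(list(ex_nm = 275, em_nm = 335, height = 50, sd_nm = 8)))
  masked <- mask_scatter(pk, 15, 15)
  expect_equal(masked$intensity[pk$ex_nm == 275, pk$em_nm == 335],
               pk$intensity[pk$ex_nm == 275, pk$em_nm == 335])
})

test_that("peak detection finds injected maxima and respects prominence", {
  one <- generate_eem(list(list(ex_nm = 275, em_nm = 335, height = 100, sd_nm = 10)))
  pks <- detect_peaks(one, 0.1)
  expect_equal(nrow(pks), 1)
  expect_equal(pks$ex_nm, 275)
  expect_equal(pks$em_nm, 335)
  expect_equal(pks$intensity, 100)
  flat <- eem_matrix(one$ex_nm, one$em_nm, matrix(0, length(one$ex_nm), length(one$em_nm)))
  expect_equal(nrow(detect_peaks(flat, 0.1)), 0)
  two <- generate_eem(list(list(ex_nm = 250, em_nm = 300, height = 100, sd_nm = 8),
                           list(ex_nm = 350, em_nm = 450, height = 10, sd_nm = 8)))
  expect_equal(nrow(detect_peaks(two, 0.5)), 1)
  both <- detect_peaks(two, 0.05)
  expect_equal(nrow(both), 2)
  expect_true(all(diff(both$intensity) <= 0))
  # invariance to uniform scaling
  scaled <- eem_matrix(two$ex_nm, two$em_nm, two$intensity * 37)
  p1 <- detect_peaks(two, 0.05); p2 <- detect_peaks(scaled, 0.05)
  expect_equal(p1[c("ex_nm", "em_nm")], p2[c("ex_nm", "em_nm")])
  expect_equal(p2$intensity / p1$intensity, rep(37, 2))
})

test_that("peaks classify into the protein-like windows", {
  pks <- data.frame(ex_nm = c(275, 280, 225, 350, 225),
                    em_nm = c(335, 350, 300, 450, 310),
                    intensity = c(5, 4, 3, 2, 1), region = NA_character_)
  out <- classify_peaks(pks, b_tol_nm = 5)
  expect_equal(out$region, c("A", "A", "B", "other", "other"))
  # idempotent and permutation-invariant
  expect_equal(classify_peaks(out)$region, out$region)
  perm <- classify_peaks(pks[c(3, 1, 5, 2, 4), ])
  expect_equal(perm$region, c("B", "A", "other", "A", "other"))
})

test_that("condition comparison reports per-region ratios and absences", {
  peaks <- list(list(ex_nm = 275, em_nm = 335, height = 100, sd_nm = 10),
                list(ex_nm = 225, em_nm = 300, height = 60, sd_nm = 8))
  ref <- generate_eem(peaks)
  same <- compare_eems(ref, ref)
  expect_equal(same$ratio, c(1, 1))
  halfA <- generate_eem(list(list(ex_nm = 275, em_nm = 335, height = 50, sd_nm = 10),
                             list(ex_nm = 225, em_nm = 300, height = 60, sd_nm = 8)))
  cmp <- compare_eems(ref, halfA)
  expect_equal(cmp$ratio[cmp$region == "A"], 0.5, tolerance = 1e-6)
  expect_equal(cmp$ratio[cmp$region == "B"], 1.0, tolerance = 1e-6)
  noB <- generate_eem(list(list(ex_nm = 275, em_nm = 335, height = 100, sd_nm = 10)))
  cmp2 <- compare_eems(ref, noB)
  expect_equal(cmp2$status[cmp2$region == "B"], "absent_in_test")
  expect_true(is.na(cmp2$ratio[cmp2$region == "B"]))
  other_grid <- eem_matrix(seq(200, 400, 10), seq(220, 500, 10),
                           matrix(0, 21, 29))
  expect_error(compare_eems(ref, other_grid), class = "bfq_validation_error")
})
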