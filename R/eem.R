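# 3D excitation-emission matrix (EEM) analysis: parsing rectangular
# wavelength grids, Rayleigh-scatter masking, local-maximum peak detection,
# and classification into the protein-like regions: region A
# (Ex 275-280 nm / Em 325-350 nm, tryptophan-like) and region B
# (Ex 225 nm / Em 300 nm, tyrosine-like).

#' Excitation-emission matrix
#'
#' @param ex_nm Strictly increasing excitation grid with constant step
#'   (typically 200-400 nm, step 5).
#' @param em_nm Strictly increasing emission grid with constant step
#'   (typically 220-500 nm, step 5).
#' @param intensity Non-negative matrix, `length(ex_nm)` x `length(em_nm)`.
#' @param label Optional condition tag (e.g. `"FQHC"`, `"SQHC"`).
#' @return An object of class `eem_matrix`.
#' @export
eem_matrix <- function(ex_nm, em_nm, intensity, label = NULL) {
  ex_nm <- as.numeric(ex_nm); em_nm <- as.numeric(em_nm)
  check_grid <- function(g, what) {
    if (length(g) < 2) abort_format(sprintf("%s grid needs at least 2 points", what))
    st <- diff(g)
    if (any(st <= 0)) abort_format(sprintf("%s grid must be strictly increasing", what))
    if (max(st) - min(st) > 1e-6 * mean(st))
      abort_format(sprintf("%s grid step is not uniform", what))
  }
  check_grid(ex_nm, "excitation")
  check_grid(em_nm, "emission")
  intensity <- as.matrix(intensity)
  dimnames(intensity) <- NULL
  if (!all(dim(intensity) == c(length(ex_nm), length(em_nm))))
    abort_validation("intensity must be length(ex_nm) x length(em_nm)")
  if (any(intensity < 0)) abort_validation("intensity must be non-negative")
  structure(list(ex_nm = ex_nm, em_nm = em_nm, intensity = intensity,
                 label = label),
            class = "eem_matrix")
}

#' The standard acquisition grid: Ex 200-400 nm, Em 220-500 nm, step 5 nm
#' @return List with `ex_nm` and `em_nm` vectors.
#' @export
eem_default_grid <- function() {
  list(ex_nm = seq(200, 400, by = 5), em_nm = seq(220, 500, by = 5))
}

#' @export
print.eem_matrix <- function(x, ...) {
  cat(sprintf("<eem_matrix>%s Ex %g-%g nm (step %g), Em %g-%g nm (step %g), max intensity %.4g\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              min(x$ex_nm), max(x$ex_nm), x$ex_nm[2] - x$ex_nm[1],
              min(x$em_nm), max(x$em_nm), x$em_nm[2] - x$em_nm[1],
              max(x$intensity)))
  invisible(x)
}

sniff_sep <- function(line) {
  counts <- c(`\t` = lengths(regmatches(line, gregexpr("\t", line))),
              `,` = lengths(regmatches(line, gregexpr(",", line))),
              `;` = lengths(regmatches(line, gregexpr(";", line))))
  if (max(counts) == 0) return(" ")
  names(counts)[which.max(counts)]
}

#' Read an EEM grid from delimited text
#'
#' Layout: header row of emission wavelengths, header column of excitation
#' wavelengths, intensities in the body. Separator (tab, comma, semicolon or
#' whitespace) is sniffed from the first line. Negative intensities (common
#' after blank subtraction) are clipped to 0 and the clip count is reported
#' via a message.
#'
#' @param path File path.
#' @param label Optional condition tag.
#' @return An [eem_matrix].
#' @export
read_eem <- function(path, label = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- sniff_sep(first)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, sep = if (sep == " ") "" else sep,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort_format(sprintf("cannot parse EEM table: %s", conditionMessage(e))))
  m <- suppressWarnings(apply(as.matrix(tab), c(1, 2), as.numeric))
  em <- m[1, -1]
  ex <- m[-1, 1]
  intensity <- m[-1, -1, drop = FALSE]
  if (anyNA(em) || anyNA(ex) || anyNA(intensity))
    abort_format("EEM table contains non-numeric or missing cells")
  nneg <- sum(intensity < 0)
  if (nneg > 0) {
    message(sprintf("clipped %d negative EEM intensities to 0", nneg))
    intensity[intensity < 0] <- 0
  }
  eem_matrix(ex, em, intensity, label = label)
}

#' Write an EEM grid as delimited text (round-trips with [read_eem()])
#'
#' @param eem An [eem_matrix].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return The path, invisibly.
#' @export
write_eem <- function(eem, path, sep = ",") {
  if (!inherits(eem, "eem_matrix")) abort_validation("eem must be an eem_matrix")
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(c("", fmt(eem$em_nm)), collapse = sep)
  rows <- vapply(seq_along(eem$ex_nm), function(i)
    paste(c(fmt(eem$ex_nm[i]), fmt(eem$intensity[i, ])), collapse = sep),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Zero out Rayleigh scatter bands
#'
#' First-order scatter lies along em = ex, second-order along em = 2*ex;
#' both bands (plus a half-width in nm) are set to zero before peak picking.
#'
#' @param eem An [eem_matrix].
#' @param order1_width_nm Half-width of the em = ex band (default 15).
#' @param order2_width_nm Half-width of the em = 2*ex band (default 15).
#' @return The masked [eem_matrix].
#' @export
mask_scatter <- function(eem, order1_width_nm = 15, order2_width_nm = 15) {
  if (!inherits(eem, "eem_matrix")) abort_validation("eem must be an eem_matrix")
  if (order1_width_nm < 0 || order2_width_nm < 0)
    abort_config("scatter band widths must be >= 0")
  EX <- matrix(eem$ex_nm, nrow = length(eem$ex_nm), ncol = length(eem$em_nm))
  EM <- matrix(eem$em_nm, nrow = length(eem$ex_nm), ncol = length(eem$em_nm),
               byrow = TRUE)
  bad <- abs(EM - EX) <= order1_width_nm | abs(EM - 2 * EX) <= order2_width_nm
  intensity <- eem$intensity
  intensity[bad] <- 0
  eem_matrix(eem$ex_nm, eem$em_nm, intensity, label = eem$label)
}

#' Detect fluorescence peaks on an EEM grid
#'
#' A peak is a grid cell strictly greater than its 8 neighbors with
#' intensity at least `min_prominence` times the global maximum. Prominence
#' is relative because EEM intensities are reported in arbitrary units, so
#' detection is invariant to uniform intensity scaling. Apply
#' [mask_scatter()] first.
#'
#' @param eem An [eem_matrix] (scatter-masked).
#' @param min_prominence Fraction of the global maximum in (0, 1].
#' @return Data.frame of class `eem_peaks` with columns `ex_nm`, `em_nm`,
#'   `intensity`, `region` (`NA` until [classify_peaks()]), sorted by
#'   decreasing intensity. Empty for an all-zero matrix.
#' @export
detect_peaks <- function(eem, min_prominence = 0.1) {
  if (!inherits(eem, "eem_matrix")) abort_validation("eem must be an eem_matrix")
  if (min_prominence <= 0 || min_prominence > 1)
    abort_config("min_prominence must be in (0, 1]")
  M <- eem$intensity
  gmax <- max(M)
  empty <- data.frame(ex_nm = numeric(0), em_nm = numeric(0),
                      intensity = numeric(0), region = character(0))
  class(empty) <- c("eem_peaks", "data.frame")
  if (gmax <= 0) return(empty)
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(-Inf, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- M
  ismax <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (M > P[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj])
  }
  hit <- which(ismax & M >= min_prominence * gmax & M > 0, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- data.frame(ex_nm = eem$ex_nm[hit[, 1]], em_nm = eem$em_nm[hit[, 2]],
                    intensity = M[hit], region = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eem_peaks", "data.frame")
  out
}

#' Classify EEM peaks into protein-like regions A and B
#'
#' Region A: Ex in 275-280 nm and Em in 325-350 nm (tryptophan-like).
#' Region B: Ex = 225 nm and Em = 300 nm within `b_tol_nm` (the region is
#' reported as a point, so the tolerance defaults to one 5-nm grid step).
#' Everything else is `"other"`. Pure function of peak coordinates:
#' idempotent and permutation-invariant.
#'
#' @param peaks An `eem_peaks` data.frame from [detect_peaks()].
#' @param b_tol_nm Tolerance around the region-B point (default 5).
#' @return The peaks with `region` set to `"A"`, `"B"` or `"other"`.
#' @export
classify_peaks <- function(peaks, b_tol_nm = 5) {
  if (nrow(peaks) == 0) return(peaks)
  inA <- peaks$ex_nm >= 275 & peaks$ex_nm <= 280 &
         peaks$em_nm >= 325 & peaks$em_nm <= 350
  inB <- abs(peaks$ex_nm - 225) <= b_tol_nm & abs(peaks$em_nm - 300) <= b_tol_nm
  peaks$region <- ifelse(inA, "A", ifelse(inB, "B", "other"))
  peaks
}

#' Compare peak intensities between two conditions
#'
#' Detects and classifies peaks in both matrices and reports, per region,
#' the ratio of the test peak intensity to the reference peak intensity
#' (the strongest peak in the region on each side). A region absent from
#' one side is reported as absent, not as zero.
#'
#' @param reference,test [eem_matrix] objects on identical grids.
#' @param min_prominence Passed to [detect_peaks()].
#' @param b_tol_nm Passed to [classify_peaks()].
#' @param regions Regions to compare (default A and B).
#' @return Data.frame with `region`, `ref_intensity`, `test_intensity`,
#'   `ratio`, `status`.
#' @export
compare_eems <- function(reference, test, min_prominence = 0.1, b_tol_nm = 5,
                         regions = c("A", "B")) {
  if (!inherits(reference, "eem_matrix") || !inherits(test, "eem_matrix"))
    abort_validation("reference and test must be eem_matrix objects")
  if (!isTRUE(all.equal(reference$ex_nm, test$ex_nm)) ||
      !isTRUE(all.equal(reference$em_nm, test$em_nm)))
    abort_validation("reference and test EEMs are on different grids")
  pk <- function(eem) classify_peaks(detect_peaks(eem, min_prominence), b_tol_nm)
  pr <- pk(reference); pt <- pk(test)
  best <- function(p, r) {
    sel <- p[p$region == r, , drop = FALSE]
    if (nrow(sel) == 0) NA_real_ else sel$intensity[1]
  }
  out <- do.call(rbind, lapply(regions, function(r) {
    a <- best(pr, r); b <- best(pt, r)
    status <- if (is.na(a) && is.na(b)) "absent_in_both"
              else if (is.na(a)) "absent_in_reference"
              else if (is.na(b)) "absent_in_test"
              else "present"
    data.frame(region = r, ref_intensity = a, test_intensity = b,
               ratio = if (status == "present") b / a else NA_real_,
               status = status, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
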