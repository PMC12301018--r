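# Iso-surface extraction at 0.5 occupancy by marching tetrahedra on the
# Kuhn 6-tetrahedron decomposition of each dual cube (cube corners = voxel
# centers of the zero-padded mask). The decomposition is translation-
# consistent, so shared cube faces triangulate identically and the surface is
# watertight. The enclosed volume is computed exactly for this surface: each
# tetrahedron contributes the volume of its sub-region above the 0.5
# iso-level under linear interpolation, which for binary corner values is
# 0, 1/8, 1/2, 7/8 or 1 of the tetrahedron volume depending on how many
# corners are inside.

# cube corners 1..8 as (dz, dy, dx) offsets; main diagonal is corners 1-7
mt_corner_off <- matrix(c(
  0, 0, 0,
  0, 0, 1,
  0, 1, 1,
  0, 1, 0,
  1, 0, 0,
  1, 0, 1,
  1, 1, 1,
  1, 1, 0), ncol = 3, byrow = TRUE)

# Kuhn tetrahedra around the 1-7 diagonal (corner ids into mt_corner_off)
mt_tets <- list(c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
                c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))

# triangle recipes per tetrahedron case; tet-local corners A,B,C,D = 1..4,
# vertices are midpoints of the named local edges
mt_cases <- local({
  e <- function(a, b) c(a, b)
  tri <- function(...) list(...)
  tabl <- vector("list", 15L)
  tabl[[1]]  <- tri(list(e(1, 2), e(1, 3), e(1, 4)))                       # {A}
  tabl[[2]]  <- tri(list(e(1, 2), e(2, 3), e(2, 4)))                       # {B}
  tabl[[4]]  <- tri(list(e(1, 3), e(2, 3), e(3, 4)))                       # {C}
  tabl[[8]]  <- tri(list(e(1, 4), e(2, 4), e(3, 4)))                       # {D}
  quadAB <- tri(list(e(1, 3), e(2, 3), e(2, 4)), list(e(1, 3), e(2, 4), e(1, 4)))
  quadAC <- tri(list(e(1, 2), e(2, 3), e(3, 4)), list(e(1, 2), e(3, 4), e(1, 4)))
  quadAD <- tri(list(e(1, 2), e(2, 4), e(3, 4)), list(e(1, 2), e(3, 4), e(1, 3)))
  tabl[[3]]  <- quadAB; tabl[[12]] <- quadAB                               # {A,B} / {C,D}
  tabl[[5]]  <- quadAC; tabl[[10]] <- quadAC                               # {A,C} / {B,D}
  tabl[[9]]  <- quadAD; tabl[[6]]  <- quadAD                               # {A,D} / {B,C}
  tabl[[7]]  <- tabl[[8]]                                                  # {A,B,C}
  tabl[[11]] <- tabl[[4]]                                                  # {A,B,D}
  tabl[[13]] <- tabl[[2]]                                                  # {A,C,D}
  tabl[[14]] <- tabl[[1]]                                                  # {B,C,D}
  tabl
})

mt_frac_by_npos <- c(0, 1 / 8, 1 / 2, 7 / 8, 1)

# Core mesher. occ: logical (z,y,x). Returns vertices/faces in voxel-center
# coordinates (z,y,x order, units of voxels) plus the enclosed volume in
# voxel units.
mesh_from_mask <- function(occ) {
  d <- dim(occ)
  pz <- d[1] + 2L; py <- d[2] + 2L; px <- d[3] + 2L
  P <- array(0, c(pz, py, px))
  P[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- occ * 1
  cd <- c(pz - 1L, py - 1L, px - 1L)       # cube grid dims
  corner_vals <- lapply(seq_len(8L), function(ci) {
    o <- mt_corner_off[ci, ]
    as.vector(P[(1L + o[1]):(cd[1] + o[1]),
                (1L + o[2]):(cd[2] + o[2]),
                (1L + o[3]):(cd[3] + o[3])])
  })
  s <- Reduce(`+`, corner_vals)
  vol <- sum(s == 8)                       # fully interior cubes
  mixed <- which(s > 0 & s < 8)
  v1l <- list(); v2l <- list(); v3l <- list()
  if (length(mixed)) {
    base <- arrayInd(mixed, cd)            # n x 3 cube base (z,y,x)
    M <- vapply(corner_vals, function(v) v[mixed], numeric(length(mixed)))
    if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
    bitw <- c(1, 2, 4, 8)
    for (tet in mt_tets) {
      vals <- M[, tet, drop = FALSE]
      cs <- as.integer(vals %*% bitw)
      npos <- vals %*% rep(1, 4)
      vol <- vol + sum(mt_frac_by_npos[npos + 1]) / 6
      for (cc in unique(cs)) {
        if (cc == 0L || cc == 15L) next
        rows <- which(cs == cc)
        recipes <- mt_cases[[cc]]
        pos_local <- which(bitwAnd(cc, c(1L, 2L, 4L, 8L)) > 0)
        pos_off <- colMeans(mt_corner_off[tet[pos_local], , drop = FALSE])
        pmean <- sweep(base[rows, , drop = FALSE], 2L, pos_off, `+`)
        for (recipe in recipes) {
          mids <- lapply(recipe, function(edge) {
            o <- (mt_corner_off[tet[edge[1]], ] + mt_corner_off[tet[edge[2]], ]) / 2
            sweep(base[rows, , drop = FALSE], 2L, o, `+`)
          })
          a <- mids[[1]]; b <- mids[[2]]; cmat <- mids[[3]]
          # orient so the normal points away from the interior
          u <- b - a; w <- cmat - a
          nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                       u[, 3] * w[, 1] - u[, 1] * w[, 3],
                       u[, 1] * w[, 2] - u[, 2] * w[, 1])
          ref <- (a + b + cmat) / 3 - pmean
          flip <- rowSums(nrm * ref) < 0
          if (any(flip)) {
            tmp <- b[flip, , drop = FALSE]
            b[flip, ] <- cmat[flip, , drop = FALSE]
            cmat[flip, ] <- tmp
          }
          v1l[[length(v1l) + 1L]] <- a
          v2l[[length(v2l) + 1L]] <- b
          v3l[[length(v3l) + 1L]] <- cmat
        }
      }
    }
  }
  if (length(v1l)) {
    V1 <- do.call(rbind, v1l); V2 <- do.call(rbind, v2l); V3 <- do.call(rbind, v3l)
    # padded point p corresponds to voxel center (p - 1.5) in voxel units
    allv <- rbind(V1, V2, V3) - 1.5
    key <- paste(allv[, 1] * 2, allv[, 2] * 2, allv[, 3] * 2)
    uk <- !duplicated(key)
    verts <- allv[uk, , drop = FALSE]
    idx <- match(key, key[uk])
    nt <- nrow(V1)
    faces <- cbind(idx[seq_len(nt)], idx[nt + seq_len(nt)], idx[2 * nt + seq_len(nt)])
  } else {
    verts <- matrix(numeric(0), ncol = 3)
    faces <- matrix(integer(0), ncol = 3)
  }
  list(vertices = verts, faces = faces, volume_vox = vol)
}

write_mesh_file <- function(vertices, faces, path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "stl", "ply"))
    abort_config(sprintf("unsupported mesh format '.%s' (use .obj, .stl or .ply)", ext))
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", vertices[, 1], vertices[, 2], vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(vertices)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", vertices[, 1], vertices[, 2], vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  } else {
    writeLines("solid biofilmq", con)
    for (i in seq_len(nrow(faces))) {
      v <- vertices[faces[i, ], , drop = FALSE]
      n <- c((v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) - (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
             (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) - (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
             (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) - (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1]))
      nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
      writeLines(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
      writeLines("  outer loop", con)
      writeLines(sprintf("    vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(c("  endloop", "endfacet"), con)
    }
    writeLines("endsolid biofilmq", con)
  }
  invisible(path)
}

#' Export a component mask as a triangulated iso-surface mesh
#'
#' Extracts the 0.5-occupancy iso-surface of a binary component mask by
#' marching tetrahedra and writes it as an ASCII OBJ, STL or PLY file (chosen
#' by extension). Vertex coordinates are in micrometers, `(x, y, z)` order.
#' The enclosed volume of the iso-surface is computed exactly and converges
#' to the voxel-count volume as structures grow.
#'
#' @param mask A non-empty [component_mask].
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param path Output path ending in `.obj`, `.stl` or `.ply`, or `NULL` to
#'   skip writing.
#' @return An object of class `mesh_surface`: `vertices` (n x 3, um),
#'   `faces` (m x 3 vertex indices), `enclosed_volume` (um^3).
#' @export
export_mesh <- function(mask, voxel_size, path = NULL) {
  if (!inherits(mask, "component_mask")) abort_validation("mask must be a component_mask")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    abort_validation("voxel_size must be three positive values (dz, dy, dx)")
  if (!any(mask$occupancy)) abort_empty("mask is empty; nothing to mesh")
  m <- mesh_from_mask(mask$occupancy)
  # scale (z,y,x) voxel coords to um and reorder to (x,y,z)
  vz <- m$vertices[, 1] * voxel_size[1]
  vy <- m$vertices[, 2] * voxel_size[2]
  vx <- m$vertices[, 3] * voxel_size[3]
  vertices <- cbind(x = vx, y = vy, z = vz)
  volume <- m$volume_vox * prod(voxel_size)
  if (!is.null(path)) write_mesh_file(vertices, m$faces, path)
  structure(list(vertices = vertices, faces = m$faces, enclosed_volume = volume),
            class = "mesh_surface")
}

#' @export
print.mesh_surface <- function(x, ...) {
  cat(sprintf("<mesh_surface> %d vertices, %d faces, enclosed volume %.6g um^3\n",
              nrow(x$vertices), nrow(x$faces), x$enclosed_volume))
  invisible(x)
}
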