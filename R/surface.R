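# Isosurface extraction and surface-area estimation for binary masks.
#
# The raw segmentation boundary is a staircase: the area of any unsmoothed
# isosurface mesh extracted from a binary grid overestimates the area of a
# smooth object by a systematic, orientation-dependent factor (about +9% for
# a digital sphere, independent of resolution). The corrected estimator used
# here keeps every mesh vertex where the extraction put it and instead
# weights each facet's area by the projection of its facet normal onto a
# smoothly estimated surface normal: for a planar patch of any orientation
# the weighted sum equals the true area exactly (vector-area identity),
# while near sharp edges, where no coherent smooth normal exists, an
# orientation-coherence factor blends the weight back to 1 so axis-aligned
# faces and corners keep their exact staircase area.

# --- separable Gaussian smoothing on a 3D array (sigma in voxels) ---------
gauss_kernel_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-0.5 * (x / sigma)^2)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + x
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])   # renormalise at the borders
  }
  K
}

gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    K <- gauss_kernel_matrix(d[ax], sigma)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- K %*% matrix(m, nrow = dm[1])
    dim(m) <- dm
    arr <- aperm(m, order(perm))
  }
  arr
}

# --- exact factor-2 trilinear upsampling (size 2n-1; node j at coord j/2) --
upsample2 <- function(arr) {
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    d <- dim(m)
    out <- array(0, c(2 * d[1] - 1, d[2], d[3]))
    out[seq(1, 2 * d[1] - 1, by = 2), , ] <- m
    out[seq(2, 2 * d[1] - 2, by = 2), , ] <-
      0.5 * (m[-d[1], , , drop = FALSE] + m[-1, , , drop = FALSE])
    arr <- aperm(out, order(perm))
  }
  arr
}

# --- central-difference gradient (per mm) ---------------------------------
gradient3 <- function(arr, spacing) {
  g <- vector("list", 3)
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * spacing[ax]
    idx <- function(which) {
      args <- c(list(arr), lapply(d, seq_len), list(drop = FALSE))
      args[[ax + 1L]] <- which
      do.call(`[`, args)
    }
    perm <- c(ax, setdiff(1:3, ax))
    denom_arr <- aperm(array(denom, c(n, d[-ax])), order(perm))
    g[[ax]] <- (idx(ip) - idx(im)) / denom_arr
  }
  g
}

# --- vectorised trilinear interpolation (0-based query coords) ------------
interp3 <- function(arr, pts) {
  d <- dim(arr)
  x <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  y <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  z <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  (1 - fx) * ((1 - fy) * ((1 - fz) * at(x0, y0, z0) + fz * at(x0, y0, z0 + 1)) +
              fy * ((1 - fz) * at(x0, y0 + 1, z0) + fz * at(x0, y0 + 1, z0 + 1))) +
  fx * ((1 - fy) * ((1 - fz) * at(x0 + 1, y0, z0) + fz * at(x0 + 1, y0, z0 + 1)) +
        fy * ((1 - fz) * at(x0 + 1, y0 + 1, z0) + fz * at(x0 + 1, y0 + 1, z0 + 1)))
}

# --- marching tetrahedra (Kuhn 6-tet decomposition, conforming) -----------
# Returns an (ntri x 9) matrix of triangle vertex coordinates in 0-based
# voxel index units of `field`. Crossings are linearly interpolated at
# `level`; triangles are wound so their normals point towards low field
# values (outward for an inside-high indicator).
mt_triangles <- function(field, level = 0.5) {
  d <- dim(field)
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  inside <- field > level
  cnt <- array(0L, c(nx, ny, nz))
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (q in seq_len(8)) {
    c0 <- corners[q, ]
    cnt <- cnt + inside[(1:nx) + c0[1], (1:ny) + c0[2], (1:nz) + c0[3]]
  }
  mixed <- which(cnt > 0L & cnt < 8L)
  if (length(mixed) == 0L)
    return(matrix(numeric(0), ncol = 9))
  mi <- arrayInd(mixed, c(nx, ny, nz)) - 1L   # 0-based cell origins
  ox <- mi[, 1]; oy <- mi[, 2]; oz <- mi[, 3]
  val_at <- function(c0)
    field[cbind(ox + c0[1] + 1L, oy + c0[2] + 1L, oz + c0[3] + 1L)]

  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tris <- vector("list", 6L * 28L)   # 6 tets x (14 configs x <= 2 triangles)
  ti <- 0L
  for (pi in seq_len(nrow(perms))) {
    ax <- perms[pi, ]
    path <- matrix(0L, 4, 3)
    for (s in 1:3) {
      path[s + 1, ] <- path[s, ]
      path[s + 1, ax[s]] <- path[s + 1, ax[s]] + 1L
    }
    tv <- lapply(1:4, function(s) val_at(path[s, ]))
    tin <- lapply(tv, function(v) v > level)
    cfg <- tin[[1]] + 2L * tin[[2]] + 4L * tin[[3]] + 8L * tin[[4]]
    pos <- lapply(1:4, function(s)
      cbind(ox + path[s, 1], oy + path[s, 2], oz + path[s, 3]))
    crossing <- function(i, j, sel) {
      vi <- tv[[i]][sel]; vj <- tv[[j]][sel]
      t <- (level - vi) / (vj - vi)
      pos[[i]][sel, , drop = FALSE] +
        t * (pos[[j]][sel, , drop = FALSE] - pos[[i]][sel, , drop = FALSE])
    }
    orient <- function(v1, v2, v3, ref) {
      # wind so normals point away from the inside reference corner
      n <- vcross(v2 - v1, v3 - v1)
      cen <- (v1 + v2 + v3) / 3
      bad <- rowSums(n * (ref - cen)) > 0
      if (any(bad)) {
        tmp <- v2[bad, , drop = FALSE]
        v2[bad, ] <- v3[bad, , drop = FALSE]
        v3[bad, ] <- tmp
      }
      cbind(v1, v2, v3)
    }
    for (cfgval in 1:14) {
      sel <- which(cfg == cfgval)
      if (length(sel) == 0L) next
      ins <- which(bitwAnd(cfgval, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      ref <- pos[[ins[1]]][sel, , drop = FALSE]
      if (length(ins) == 1L || length(outs) == 1L) {
        a <- if (length(ins) == 1L) ins[1] else outs[1]
        oth <- setdiff(1:4, a)
        v1 <- crossing(a, oth[1], sel)
        v2 <- crossing(a, oth[2], sel)
        v3 <- crossing(a, oth[3], sel)
        ti <- ti + 1L; tris[[ti]] <- orient(v1, v2, v3, ref)
      } else {
        q1 <- crossing(ins[1], outs[1], sel)
        q2 <- crossing(ins[1], outs[2], sel)
        q3 <- crossing(ins[2], outs[2], sel)
        q4 <- crossing(ins[2], outs[1], sel)
        ti <- ti + 1L; tris[[ti]] <- orient(q1, q2, q3, ref)
        ti <- ti + 1L; tris[[ti]] <- orient(q1, q3, q4, ref)
      }
    }
  }
  do.call(rbind, tris[seq_len(ti)])
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Extract the boundary surface mesh of a hematoma mask
#'
#' Extracts the level-0.5 isosurface of the binary mask as a triangle mesh
#' (marching tetrahedra on a conforming Kuhn decomposition of an exactly
#' twice-refined trilinear grid, i.e. the chorded trilinear isosurface). The
#' mask is padded by one layer of background before extraction so surfaces
#' touching the grid boundary are closed. No mesh smoothing or decimation is
#' applied.
#'
#' @param mask a [hematoma_mask].
#' @return A list with `vertices` (ntri x 9 matrix: the three vertices of
#'   each triangle, physical mm coordinates), `areas` (per-triangle areas,
#'   mm^2) and `normals` (per-triangle unit facet normals, outward).
#' @export
surface_mesh <- function(mask, pad = 3L) {
  stopifnot(inherits(mask, "hematoma_mask"))
  if (sum(mask$data) == 0L)
    stop("empty mask: no surface to extract", call. = FALSE)
  sp <- mask$spacing
  m <- pad_array(mask$data, pad)
  tri <- mt_triangles(upsample2(m), 0.5) / 2    # back to voxel units
  v1 <- tri[, 1:3]; v2 <- tri[, 4:6]; v3 <- tri[, 7:9]
  scale <- function(v) sweep(v, 2, sp, `*`)
  e1 <- scale(v2 - v1); e2 <- scale(v3 - v1)
  cr <- vcross(e1, e2)
  a <- 0.5 * sqrt(rowSums(cr^2))
  keep <- a > 1e-14
  tri <- tri[keep, , drop = FALSE]
  cr <- cr[keep, , drop = FALSE]
  a <- a[keep]
  nrm <- cr / sqrt(rowSums(cr^2))
  # physical coordinates relative to the unpadded grid
  phys <- tri
  for (b in c(0, 3, 6))
    phys[, b + (1:3)] <- sweep(
      sweep(tri[, b + (1:3), drop = FALSE], 2, pad, `-`), 2, sp, `*`) +
      matrix(mask$origin, nrow(tri), 3, byrow = TRUE)
  list(vertices = phys, voxel_vertices = tri, areas = a, normals = nrm,
       pad = pad, spacing = sp)
}

pad_array <- function(m, pad) {
  d <- dim(m)
  out <- array(0, d + 2 * pad)
  out[pad + (1:d[1]), pad + (1:d[2]), pad + (1:d[3])] <- m
  out
}

# Corrected area: normal-projection weights blended by orientation
# coherence. sigma (voxels) sets the scale of the normal estimate; power
# controls how sharply the correction is switched off where the normal
# field is incoherent (edges, corners).
surface_area_impl <- function(mask, method = c("corrected", "raw"),
                              sigma = 1.5, power = 8, pad = 3L) {
  method <- match.arg(method)
  mesh <- surface_mesh(mask, pad = pad)
  raw <- sum(mesh$areas)
  if (method == "raw") return(raw)
  sp <- mask$spacing
  m <- pad_array(mask$data, pad)
  f <- gauss_smooth3(m, sigma)
  g <- gradient3(f, sp)
  gnorm <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  gs <- lapply(g, gauss_smooth3, sigma = sigma)
  coh <- sqrt(gs[[1]]^2 + gs[[2]]^2 + gs[[3]]^2) /
    pmax(gauss_smooth3(gnorm, sigma), 1e-12)
  coh[coh > 1] <- 1; coh[coh < 0] <- 0
  tri <- mesh$voxel_vertices
  cen <- (tri[, 1:3] + tri[, 4:6] + tri[, 7:9]) / 3
  nvec <- cbind(interp3(g[[1]], cen), interp3(g[[2]], cen),
                interp3(g[[3]], cen))
  nn <- sqrt(rowSums(nvec^2))
  nvec <- nvec / pmax(nn, 1e-30)
  cc <- pmin(pmax(interp3(coh, cen), 0), 1)
  dot <- abs(rowSums(nvec * mesh$normals))
  w <- 1 + cc^power * (dot - 1)
  sum(mesh$areas * w)
}
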