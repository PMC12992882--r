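# Triangulated isosurface of a binary mask (iso-level 0.5, vertices at edge
# midpoints). The per-configuration triangle table is derived at first use
# by marching-squares contouring of the six cube faces and stitching the
# face segments into closed, consistently oriented loops; ambiguous faces
# (two diagonal inside-corners) always keep the inside corners separated,
# a rule that depends only on the face's own corner values, so adjacent
# cubes agree and the global mesh is watertight.

# corner i sits at offset (i&1, (i>>1)&1, (i>>2)&1); edges/faces fixed below
mc_env <- new.env(parent = emptyenv())

mc_tables <- function() {
  if (!is.null(mc_env$table)) return(mc_env)
  corn <- t(vapply(0:7, function(i) {
    c(bitwAnd(i, 1L), bitwAnd(bitwShiftR(i, 1L), 1L), bitwAnd(bitwShiftR(i, 2L), 1L))
  }, numeric(3)))
  edges <- NULL
  for (a in 0:6) for (b in (a + 1):7) {
    if (sum(bitwAnd(bitwXor(a, b), c(1L, 2L, 4L)) != 0L) == 1L) {
      edges <- rbind(edges, c(a, b))
    }
  }
  faces <- list(c(0, 2, 6, 4), c(1, 5, 7, 3), c(0, 4, 5, 1),
                c(2, 3, 7, 6), c(0, 1, 3, 2), c(4, 6, 7, 5))
  # orient every face counter-clockwise as seen from outside the cube
  for (fi in seq_along(faces)) {
    p <- corn[faces[[fi]] + 1L, ]
    n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    if (sum(n * (colMeans(p) - 0.5)) < 0) faces[[fi]] <- rev(faces[[fi]])
  }
  eid <- function(a, b) {
    which(edges[, 1] == min(a, b) & edges[, 2] == max(a, b))
  }
  mids <- (corn[edges[, 1] + 1L, ] + corn[edges[, 2] + 1L, ]) / 2

  face_segments <- function(bits, face) {
    p0 <- corn[face[1] + 1L, ]
    u <- corn[face[2] + 1L, ] - p0
    v <- corn[face[4] + 1L, ] - p0
    to2 <- function(q) c(sum((q - p0) * u), sum((q - p0) * v))
    fedges <- lapply(1:4, function(k) c(face[k], face[(k %% 4) + 1]))
    crossing <- Filter(function(fe) bits[fe[1] + 1L] != bits[fe[2] + 1L], fedges)
    pos <- face[bits[face + 1L] == 1L]
    orient <- function(eA, eB, pc) {
      A <- to2((corn[eA[1] + 1L, ] + corn[eA[2] + 1L, ]) / 2)
      B <- to2((corn[eB[1] + 1L, ] + corn[eB[2] + 1L, ]) / 2)
      C <- to2(corn[pc + 1L, ])
      cr <- (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])
      if (cr > 0) c(eid(eA[1], eA[2]), eid(eB[1], eB[2]))
      else c(eid(eB[1], eB[2]), eid(eA[1], eA[2]))
    }
    if (length(crossing) == 2L) {
      list(orient(crossing[[1]], crossing[[2]], pos[1]))
    } else if (length(crossing) == 4L) {
      lapply(pos, function(pc) {
        adj <- Filter(function(fe) pc %in% fe, crossing)
        orient(adj[[1]], adj[[2]], pc)
      })
    } else {
      list()
    }
  }

  # triangles are emitted as precomputed vertex offsets within the unit
  # cube; loops longer than 3 are fanned from their centroid, which makes
  # the triangulation (hence area and enclosed volume) exactly invariant
  # under the 48 cube symmetries
  config_tris <- function(cfg) {
    bits <- as.integer(bitwAnd(bitwShiftR(cfg, 0:7), 1L))
    empty <- list(o1 = matrix(0, 0, 3), o2 = matrix(0, 0, 3), o3 = matrix(0, 0, 3))
    if (sum(bits) %in% c(0L, 8L)) return(empty)
    segs <- list()
    for (f in faces) segs <- c(segs, face_segments(bits, f))
    starts <- vapply(segs, `[`, 1L, 1L)
    nxt <- integer(12)
    nxt[starts] <- vapply(segs, `[`, 1L, 2L)
    o1 <- o2 <- o3 <- NULL
    visited <- logical(12)
    for (s in starts) {
      if (visited[s]) next
      loop <- s
      cur <- nxt[s]
      while (cur != s) {
        loop <- c(loop, cur)
        cur <- nxt[cur]
      }
      visited[loop] <- TRUE
      m <- length(loop)
      if (m < 3) next
      pts <- mids[loop, , drop = FALSE]
      if (m == 3) {
        # reversed winding so outward normals give positive signed volume
        o1 <- rbind(o1, pts[1, ]); o2 <- rbind(o2, pts[3, ]); o3 <- rbind(o3, pts[2, ])
      } else {
        ctr <- colMeans(pts)
        for (k in seq_len(m)) {
          k2 <- (k %% m) + 1L
          o1 <- rbind(o1, ctr); o2 <- rbind(o2, pts[k2, ]); o3 <- rbind(o3, pts[k, ])
        }
      }
    }
    if (is.null(o1)) empty else list(o1 = o1, o2 = o2, o3 = o3)
  }

  mc_env$table <- lapply(0:255, config_tris)
  mc_env$ntri <- vapply(mc_env$table, function(tt) nrow(tt$o1), 1L)
  mc_env$mids <- mids
  mc_env
}

#' Triangulated isosurface of a binary mask
#'
#' Marching-cubes style surface at iso-level 0.5 with vertices at voxel-edge
#' midpoints, in physical (mm) coordinates. Returns a triangle soup with
#' consistent outward orientation; the mesh is closed, so the signed-volume
#' sum equals the enclosed volume.
#'
#' @param mask Binary `label_volume` (or 3D array).
#' @param spacing Voxel spacing, mm (taken from `mask` when it is a volume).
#' @return List with `v1`, `v2`, `v3` (each n x 3 matrices of triangle
#'   vertex coordinates in mm).
#' @export
iso_mesh <- function(mask, spacing = NULL) {
  if (inherits(mask, "volume_grid")) {
    spacing <- mask$spacing
    mask <- mask$data
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  env <- mc_tables()
  d <- dim(mask)
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.integer(mask != 0)
  dp <- dim(p)
  dc <- dp - 1L
  sub <- function(ox, oy, oz) {
    p[(1 + ox):(dc[1] + ox), (1 + oy):(dc[2] + oy), (1 + oz):(dc[3] + oz)]
  }
  cfg <- array(0L, dc)
  for (i in 0:7) {
    cfg <- cfg + bitwShiftL(sub(bitwAnd(i, 1L), bitwAnd(bitwShiftR(i, 1L), 1L),
                                bitwAnd(bitwShiftR(i, 2L), 1L)), i)
  }
  act <- which(cfg > 0L & cfg < 255L)
  if (length(act) == 0) {
    z <- matrix(numeric(0), 0, 3)
    return(list(v1 = z, v2 = z, v3 = z))
  }
  cfg_act <- cfg[act]
  ai <- arrayInd(act, dc)
  # cell origin in original-volume voxel coordinates (1-based centers):
  # padded cell (i,j,k) corner 0 sits at original voxel index (i-1, j-1, k-1)
  org <- ai - 1 # corner-0 center in original 1-based voxel coordinates
  v1 <- v2 <- v3 <- vector("list", 256)
  for (v in sort(unique(cfg_act))) {
    tri <- env$table[[v + 1L]]
    nt <- nrow(tri$o1)
    if (nt == 0) next
    sel <- org[cfg_act == v, , drop = FALSE]
    n <- nrow(sel)
    rep_org <- sel[rep(seq_len(n), each = nt), , drop = FALSE]
    rep_tri <- rep(seq_len(nt), times = n)
    v1[[v + 1L]] <- rep_org + tri$o1[rep_tri, , drop = FALSE]
    v2[[v + 1L]] <- rep_org + tri$o2[rep_tri, , drop = FALSE]
    v3[[v + 1L]] <- rep_org + tri$o3[rep_tri, , drop = FALSE]
  }
  scale_rows <- function(m) sweep(m, 2, spacing, `*`)
  list(v1 = scale_rows(do.call(rbind, v1[!vapply(v1, is.null, TRUE)])),
       v2 = scale_rows(do.call(rbind, v2[!vapply(v2, is.null, TRUE)])),
       v3 = scale_rows(do.call(rbind, v3[!vapply(v3, is.null, TRUE)])))
}

mesh_area_volume <- function(mesh) {
  e1 <- mesh$v2 - mesh$v1
  e2 <- mesh$v3 - mesh$v1
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(cx^2))) / 2
  vol <- sum((mesh$v1[, 1] * (mesh$v2[, 2] * mesh$v3[, 3] - mesh$v2[, 3] * mesh$v3[, 2]) -
              mesh$v1[, 2] * (mesh$v2[, 1] * mesh$v3[, 3] - mesh$v2[, 3] * mesh$v3[, 1]) +
              mesh$v1[, 3] * (mesh$v2[, 1] * mesh$v3[, 2] - mesh$v2[, 2] * mesh$v3[, 1]))) / 6
  list(area = area, volume = vol)
}
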