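#' Specification of a synthetic face surface
#'
#' Describes a template-like open facial shell used in place of a 3D scan: a
#' smooth convex dome facing +Z with a Gaussian nose ridge, a nasal-root
#' depression and a chin protrusion. All lengths in millimetres. Defaults are
#' adult-face scale; the default vertex budget matches a typical
#' template-registered scan resolution.
#'
#' @param target_vertex_count desired number of vertices (the realized count
#'   is within 2 per cent; minimum 16).
#' @param face_width,face_height,face_depth overall extents (mm).
#' @param nose_height protrusion of the nose ridge above the dome (mm).
#' @param nose_width lateral width scale of the nose ridge (mm).
#' @param chin_protrusion height of the chin bump (mm).
#' @param seed integer seed for the small surface jitter that breaks the
#'   perfect regularity of the generating grid.
#' @return an object of class `synthetic_face_spec`.
#' @export
synthetic_face_spec <- function(target_vertex_count = 5303,
                                face_width = 140, face_height = 180,
                                face_depth = 70, nose_height = 22,
                                nose_width = 32, chin_protrusion = 12,
                                seed = 1L) {
  geom <- c(target_vertex_count, face_width, face_height, face_depth,
            nose_height, nose_width, chin_protrusion)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric parameters must be strictly positive")
  if (target_vertex_count < 16)
    stop("target_vertex_count must be at least 16")
  structure(list(target_vertex_count = as.integer(target_vertex_count),
                 face_width = face_width, face_height = face_height,
                 face_depth = face_depth, nose_height = nose_height,
                 nose_width = nose_width, chin_protrusion = chin_protrusion,
                 seed = as.integer(seed)),
            class = "synthetic_face_spec")
}

# Height field of the generating surface at (x, y); vectorized.
# x: lateral (+x is the subject's left), y: vertical (+y up), z: out of face.
face_height_field <- function(x, y, spec) {
  w <- spec$face_width; h <- spec$face_height
  dome <- spec$face_depth * cos(pi * x / w) * cos(pi * y / h)
  sx <- spec$nose_width / 4
  nose <- spec$nose_height * exp(-x^2 / (2 * sx^2) - (y - 0.02 * h)^2 / (2 * (0.16 * h)^2))
  root <- -0.45 * spec$nose_height *
    exp(-x^2 / (2 * (1.2 * sx)^2) - (y - 0.22 * h)^2 / (2 * (0.05 * h)^2))
  chin <- spec$chin_protrusion *
    exp(-x^2 / (2 * (0.14 * w)^2) - (y + 0.38 * h)^2 / (2 * (0.07 * h)^2))
  dome + nose + root + chin
}

# Grid dimensions whose product is closest to the target count, with the
# column/row ratio following the face aspect ratio.
face_grid_dims <- function(spec) {
  aspect <- spec$face_height / spec$face_width
  nc0 <- max(4, round(sqrt(spec$target_vertex_count / aspect)))
  best <- NULL
  for (nc in max(4, nc0 - 3):(nc0 + 3)) {
    nr <- max(4, round(spec$target_vertex_count / nc))
    err <- abs(nc * nr - spec$target_vertex_count)
    if (is.null(best) || err < best$err) best <- list(nc = nc, nr = nr, err = err)
  }
  best
}

#' Generate a synthetic face surface
#'
#' Builds a structured grid over the generating height field (see
#' [synthetic_face_spec()]), triangulates it with +Z-facing winding, applies a
#' small seeded jitter to interior vertices (so the mesh is not perfectly
#' regular, as a registered scan never is), and places the landmarks
#' `sellion`, `pronasale`, `promentale`, `left_cheek`, `right_cheek` at the
#' extrema of the generating function. Generation is bit-identical for equal
#' spec (including seed).
#'
#' @param spec a [synthetic_face_spec()].
#' @return a [tri_mesh()] with landmarks; the outer rectangle edge is the open
#'   boundary that the face model clamps.
#' @export
#' @examples
#' face <- generate_synthetic_face(synthetic_face_spec(target_vertex_count = 400))
#' face
generate_synthetic_face <- function(spec) {
  if (!inherits(spec, "synthetic_face_spec")) stop("`spec` must be a synthetic_face_spec")
  dims <- face_grid_dims(spec)
  nc <- dims$nc; nr <- dims$nr
  xs <- seq(-spec$face_width / 2, spec$face_width / 2, length.out = nc)
  ys <- seq(-spec$face_height / 2, spec$face_height / 2, length.out = nr)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)  # column-fastest in x
  x <- g$x; y <- g$y
  nvert <- nc * nr
  # interior-vertex jitter: at most 15% of a grid cell, tangentially, plus a
  # sub-0.1 mm normal perturbation; keeps triangles non-degenerate
  interior <- !(x %in% xs[c(1, nc)] | y %in% ys[c(1, nr)])
  set.seed(spec$seed)
  dx <- stats::runif(nvert, -1, 1) * 0.15 * diff(xs[1:2]) * interior
  dy <- stats::runif(nvert, -1, 1) * 0.15 * diff(ys[1:2]) * interior
  dz <- stats::runif(nvert, -1, 1) * 0.08 * interior
  x <- x + dx; y <- y + dy
  z <- face_height_field(x, y, spec) + dz
  verts <- cbind(x, y, z)
  dimnames(verts) <- NULL

  # triangulate the grid; CCW seen from +Z
  i <- rep(seq_len(nc - 1), nr - 1)
  j <- rep(seq_len(nr - 1), each = nc - 1)
  v00 <- (j - 1) * nc + i
  v10 <- v00 + 1L
  v01 <- v00 + nc
  v11 <- v01 + 1L
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  dimnames(tris) <- NULL

  lms <- synthetic_face_landmarks(verts, spec)
  tri_mesh(verts, tris, landmarks = lms)
}

# Landmarks at extrema of the generating function, snapped to mesh vertices.
synthetic_face_landmarks <- function(verts, spec) {
  h <- spec$face_height; w <- spec$face_width
  fine_y <- seq(-0.45 * h, 0.45 * h, length.out = 2000)
  mid <- face_height_field(rep(0, 2000), fine_y, spec)
  pron_y <- fine_y[which.max(mid)]
  # sellion: the midline local minimum between nose peak and forehead
  above <- fine_y > pron_y & fine_y < 0.35 * h
  sell_y <- fine_y[above][which.min(mid[above])]
  chin_band <- fine_y < -0.25 * h
  prom_y <- fine_y[chin_band][which.max(mid[chin_band])]
  targets <- rbind(pronasale = c(0, pron_y),
                   sellion = c(0, sell_y),
                   promentale = c(0, prom_y),
                   left_cheek = c(0.30 * w, 0.02 * h),
                   right_cheek = c(-0.30 * w, 0.02 * h))
  idx <- apply(targets, 1, function(t)
    which.min((verts[, 1] - t[1])^2 + (verts[, 2] - t[2])^2))
  stats::setNames(as.integer(idx), rownames(targets))
}

#' Default mask reference loop for a face
#'
#' Builds an ordered closed loop of reference points that traces a medical
#' mask's contact footprint on a face: nasal root at the top, nose/cheek
#' sides, chin sides and chin bottom. Each point sits at the face surface
#' plus a normal-direction (`+Z`) clearance, so the sampled mask floats just
#' off the skin before being pushed on.
#'
#' @param mesh a [tri_mesh()] with the synthetic-face landmarks.
#' @param n_points 8 (commercial-mask baseline) or 12 (adds points at the
#'   nasal-root and lip sides, where an 8-point loop tends to bridge over
#'   high-curvature regions).
#' @param clearance gap between the loop and the face surface (mm).
#' @return numeric matrix (`n_points` x 3) of reference points, ordered
#'   counter-clockwise, forming a closed loop.
#' @export
mask_reference_points <- function(mesh, n_points = 8, clearance = 2) {
  if (!n_points %in% c(8L, 12L)) stop("`n_points` must be 8 or 12")
  lm <- mesh$landmarks
  need <- c("sellion", "pronasale", "promentale")
  if (is.null(lm) || !all(need %in% names(lm)))
    stop("mesh lacks the landmarks ", paste(need, collapse = ", "))
  v <- mesh$vertices
  top_y <- v[lm[["sellion"]], 2]
  bot_y <- v[lm[["promentale"]], 2] - 6
  cx <- 0
  cy <- (top_y + bot_y) / 2
  ry <- (top_y - bot_y) / 2
  rx <- 0.58 * ry
  base_ang <- c(90, 145, 180, 215, 270, 325, 0, 35)
  extra_ang <- c(112, 68, 250, 290)  # nasal-root sides, chin/lip sides
  ang <- if (n_points == 8L) base_ang else sort(c(base_ang, extra_ang))
  # keep the loop ordered counter-clockwise starting at the top point
  ang <- ang[order((ang - 90) %% 360)]
  th <- ang * pi / 180
  px <- cx + rx * cos(th)
  py <- cy + ry * sin(th)
  pz <- surface_height_at(mesh, px, py) + clearance
  pts <- cbind(px, py, pz)
  dimnames(pts) <- NULL
  pts
}

# Surface height z(x, y) by inverse-distance interpolation over the nearest
# mesh vertices in the XY plane.
surface_height_at <- function(mesh, x, y, k = 4L) {
  v <- mesh$vertices
  vapply(seq_along(x), function(i) {
    d2 <- (v[, 1] - x[i])^2 + (v[, 2] - y[i])^2
    nn <- order(d2)[seq_len(k)]
    w <- 1 / pmax(d2[nn], 1e-12)
    sum(w * v[nn, 3]) / sum(w)
  }, numeric(1))
}
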