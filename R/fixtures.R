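# Synthetic skull-like fixtures. The stand-in is a two-shell ellipsoid: a
# closed outer shell (the visible external surface) plus a disjoint interior
# shell playing the role of the internal bone structures that the external
# surface extraction must suppress. The fixture frame follows the package's
# Natural-Head-Position convention: z up, y anterior, x left-to-right, and the
# geometry is exactly mirror-symmetric about x = 0 so the mirror completion
# baseline is applicable.

#' Parameters for the synthetic skull fixture
#'
#' @param outer_radii three ellipsoid semi-axes in mm (x, y, z).
#' @param shell_thickness required clearance between outer and inner shell (mm).
#' @param inner_shell_scale inner shell size as a fraction of the outer.
#' @param jaw add a symmetric lower-anterior protrusion (maxilla/mandible
#'   stand-in) to the outer shell.
#' @param subdivision_level integer controlling mesh resolution; vertex count
#'   grows as `4^level` (level 6 lands in the 250k-400k range typical of
#'   CT-segmented skull meshes).
#' @param seed integer; fixture generation is deterministic given the params.
#' @return An object of class `skull_fixture_params`.
#' @export
skull_fixture_params <- function(outer_radii = c(90, 110, 80), shell_thickness = 6,
                                 inner_shell_scale = 0.6, jaw = TRUE,
                                 subdivision_level = 3, seed = 1) {
  if (any(outer_radii <= shell_thickness) || shell_thickness <= 0)
    stop("need radii > shell_thickness > 0", call. = FALSE)
  if (inner_shell_scale <= 0 || inner_shell_scale >= 1)
    stop("inner_shell_scale must be in (0, 1)", call. = FALSE)
  if (inner_shell_scale > 1 - shell_thickness / min(outer_radii))
    stop("inner shell intersects the outer shell", call. = FALSE)
  structure(list(outer_radii = as.numeric(outer_radii),
                 shell_thickness = shell_thickness,
                 inner_shell_scale = inner_shell_scale,
                 jaw = isTRUE(jaw),
                 subdivision_level = as.integer(subdivision_level),
                 seed = as.integer(seed)),
            class = "skull_fixture_params")
}

# Closed UV-sphere ellipsoid: n x n grid plus two pole vertices, every edge
# shared by exactly two triangles. The longitude grid is symmetric under
# x -> -x when n is even.
ellipsoid_shell <- function(radii, n) {
  theta <- seq_len(n - 1) * pi / n          # interior latitudes
  phi <- (seq_len(n) - 1) * 2 * pi / n
  st <- sin(theta); ct <- cos(theta)
  ring <- function(i) cbind(radii[1] * st[i] * cos(phi),
                            radii[2] * st[i] * sin(phi),
                            radii[3] * ct[i])
  verts <- do.call(rbind, lapply(seq_len(n - 1), ring))
  north <- c(0, 0, radii[3]); south <- c(0, 0, -radii[3])
  verts <- rbind(verts, north, south)
  ni <- nrow(verts) - 1L  # north index
  si <- nrow(verts)       # south index
  idx <- function(i, j) (i - 1L) * n + ((j - 1L) %% n) + 1L
  faces <- vector("list", n + 1L)
  faces[[1]] <- cbind(ni, idx(1, seq_len(n)), idx(1, seq_len(n) + 1))
  for (i in seq_len(n - 2)) {
    a <- idx(i, seq_len(n));     b <- idx(i, seq_len(n) + 1)
    c_ <- idx(i + 1, seq_len(n)); d <- idx(i + 1, seq_len(n) + 1)
    faces[[i + 1L]] <- rbind(cbind(a, c_, b), cbind(b, c_, d))
  }
  faces[[n]] <- cbind(si, idx(n - 1, seq_len(n) + 1), idx(n - 1, seq_len(n)))
  list(vertices = verts, faces = do.call(rbind, faces))
}

# Smooth symmetric lower-anterior bump standing in for the maxilla/mandible:
# vertices in the anterior-inferior octant are pushed down and forward with a
# C1 falloff, preserving x-symmetry and watertightness.
apply_jaw <- function(verts, radii) {
  y <- verts[, 2] / radii[2]
  z <- verts[, 3] / radii[3]
  wy <- pmax(0, (y - 0.25) / 0.75)
  wz <- pmax(0, (-z - 0.1) / 0.9)
  w <- wy * wz
  verts[, 2] <- verts[, 2] + 0.3 * radii[2] * w
  verts[, 3] <- verts[, 3] - 0.6 * radii[3] * w
  verts
}

#' Generate a synthetic two-shell skull mesh
#'
#' @param params a [skull_fixture_params()].
#' @return A [triangle_mesh()] with two connected components (outer shell and
#'   interior shell); the outer shell is watertight and mirror-symmetric about
#'   x = 0.
#' @export
make_synthetic_skull <- function(params = skull_fixture_params()) {
  stopifnot(inherits(params, "skull_fixture_params"))
  n <- 6L * 2L^params$subdivision_level
  outer <- ellipsoid_shell(params$outer_radii, n)
  if (params$jaw) outer$vertices <- apply_jaw(outer$vertices, params$outer_radii)
  inner <- ellipsoid_shell(params$outer_radii * params$inner_shell_scale, n)
  verts <- rbind(outer$vertices, inner$vertices)
  faces <- rbind(outer$faces, inner$faces + nrow(outer$vertices))
  mesh <- triangle_mesh(verts, faces)
  attr(mesh, "outer_vertex_count") <- nrow(outer$vertices)
  mesh
}

#' Uniform spherical shell cloud
#'
#' `n` points uniform on the sphere of the given radius, with outward unit
#' normals attached.
#'
#' @param n point count.
#' @param radius sphere radius (mm).
#' @param seed RNG seed.
#' @return A [point_cloud()].
#' @export
make_shell_cloud <- function(n, radius, seed = 1) {
  with_seed(seed, {
    g <- matrix(rnorm(3 * n), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    point_cloud(g * radius, g)
  })
}

euler_rotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rigidly transformed (and optionally noised) copy of a cloud
#'
#' Test driver for the alignment module: returns the original cloud, the
#' moved copy, and the applied transform as ground truth.
#'
#' @param cloud a [point_cloud()].
#' @param rotation Euler angles (radians) about x, y, z, applied as Rz Ry Rx.
#' @param translation length-3 vector (mm).
#' @param noise_sd per-coordinate Gaussian noise sd (mm) added to the copy.
#' @param seed RNG seed for the noise.
#' @return list(source = cloud, target = moved copy, transform = [rigid_transform()]).
#' @export
make_transformed_pair <- function(cloud, rotation = c(0, 0, 0),
                                  translation = c(0, 0, 0), noise_sd = 0, seed = 1) {
  stopifnot(inherits(cloud, "point_cloud"))
  tr <- rigid_transform(euler_rotation(rotation), translation)
  target <- apply_transform(cloud, tr)
  if (noise_sd > 0) {
    target$points <- target$points + with_seed(seed,
      matrix(rnorm(length(target$points), sd = noise_sd), ncol = 3))
  }
  list(source = cloud, target = target, transform = tr)
}
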