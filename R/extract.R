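# External-surface extraction: orthographic depth snapshots from 10 virtual
# cameras (8 azimuthal at 45 degree steps plus parietal and basilar),
# back-projection of every foreground pixel into the common world frame, and
# Poisson-disk simplification of the merged cloud. Because only the depth
# buffer's nearest hits are back-projected, interior structures hidden by the
# closed outer surface never enter the cloud.

#' Orthographic camera view
#'
#' @param rotation 3x3 matrix whose rows are the camera axes (right, up,
#'   forward) in world coordinates.
#' @param position camera position (world, mm).
#' @param extent c(width, height) of the orthographic frame (mm).
#' @param image_size c(H, W) in pixels.
#' @param label view name.
#' @return An object of class `camera_view`.
#' @export
camera_view <- function(rotation, position, extent, image_size, label = "") {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 || abs(det(rotation) - 1) > 1e-9)
    stop("camera rotation must be orthonormal with det +1", call. = FALSE)
  if (any(extent <= 0) || any(image_size <= 0))
    stop("extents and image size must be positive", call. = FALSE)
  structure(list(rotation = rotation, position = as.numeric(position),
                 extent = as.numeric(extent), image_size = as.integer(image_size),
                 label = label),
            class = "camera_view")
}

look_at <- function(forward, position, extent, image_size, label) {
  zc <- forward / sqrt(sum(forward^2))
  up <- if (abs(zc[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  xc <- crossv(up, zc); xc <- xc / sqrt(sum(xc^2))
  yc <- crossv(zc, xc)
  camera_view(rbind(xc, yc, zc), position, extent, image_size, label)
}

#' Generate the 10 standard snapshot views
#'
#' Eight azimuthal cameras rotating around the vertical (z) axis in 45 degree
#' steps, plus a parietal (top, looking down) and a basilar (bottom, looking
#' up) view. All are orthographic, centred on the bounding-box centre, with
#' frame extents fitting the bounding sphere with a 5% margin.
#'
#' @param mesh_bounds 2x3 matrix: rows are the min and max corners (mm).
#' @param image_size pixels per side (square frames), default 1024.
#' @return List of 10 [camera_view()] objects.
#' @export
generate_views <- function(mesh_bounds, image_size = 1024) {
  b <- as.matrix(mesh_bounds)
  if (any(b[2, ] <= b[1, ])) stop("degenerate (zero-volume) bounds", call. = FALSE)
  center <- colMeans(b)
  r_bs <- sqrt(sum(((b[2, ] - b[1, ]) / 2)^2))
  ext <- rep(2 * r_bs * 1.05, 2)
  dist <- 1.5 * r_bs * 1.05
  views <- vector("list", 10L)
  az <- (0:7) * 45
  for (i in seq_along(az)) {
    a <- az[i] * pi / 180
    fwd <- c(cos(a), sin(a), 0)
    views[[i]] <- look_at(fwd, center - fwd * dist, ext, c(image_size, image_size),
                          sprintf("azimuth_%03d", az[i]))
  }
  views[[9]] <- look_at(c(0, 0, -1), center + c(0, 0, dist), ext,
                        c(image_size, image_size), "parietal")
  views[[10]] <- look_at(c(0, 0, 1), center - c(0, 0, dist), ext,
                         c(image_size, image_size), "basilar")
  views
}

mesh_bounds <- function(mesh) {
  rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}

#' Render an orthographic depth map
#'
#' Software z-buffer rasterization: each pixel carries the depth (mm along the
#' view direction) of the nearest mesh intersection through the pixel centre,
#' `NA` for background, plus the id of the winning triangle.
#'
#' @param mesh a [triangle_mesh()].
#' @param view a [camera_view()].
#' @return An object of class `depth_map`: list(depth, tri, view).
#' @export
render_depth <- function(mesh, view) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(view, "camera_view"))
  out <- cpp_render_depth(mesh$vertices, mesh$faces, view$rotation, view$position,
                          view$extent[1], view$extent[2],
                          view$image_size[2], view$image_size[1])
  structure(list(depth = out$depth, tri = out$tri, view = view), class = "depth_map")
}

#' Back-project a depth map into a world-frame point cloud
#'
#' One 3-d point per foreground pixel, expressed in the common world frame.
#' When the source mesh is supplied, each point inherits the unit normal of
#' the triangle it was rendered from, flipped to face the camera; otherwise
#' normals are the reversed view direction (provisional).
#'
#' @param depth_map a `depth_map` from [render_depth()].
#' @param mesh optional source [triangle_mesh()] for normal transfer.
#' @return A [point_cloud()]; empty (with a warning) for an all-background map.
#' @export
backproject_depth <- function(depth_map, mesh = NULL) {
  stopifnot(inherits(depth_map, "depth_map"))
  v <- depth_map$view
  H <- v$image_size[1]; W <- v$image_size[2]
  fg <- which(!is.na(depth_map$depth))
  if (!length(fg)) {
    warning("all-background depth map: empty cloud")
    return(point_cloud(matrix(numeric(0), ncol = 3)))
  }
  ij <- arrayInd(fg, c(H, W))
  xc <- v$extent[1] * ((ij[, 2] - 0.5) / W - 0.5)
  yc <- v$extent[2] * ((ij[, 1] - 0.5) / H - 0.5)
  zc <- depth_map$depth[fg]
  pts <- sweep(cbind(xc, yc, zc) %*% v$rotation, 2, v$position, "+")
  if (!is.null(mesh)) {
    tid <- depth_map$tri[fg]
    fn <- face_normals(mesh)[tid, , drop = FALSE]
    flip <- as.numeric(fn %*% v$rotation[3, ]) > 0
    fn[flip, ] <- -fn[flip, , drop = FALSE]
    normals <- fn
  } else {
    normals <- matrix(rep(-v$rotation[3, ], length(fg)), ncol = 3, byrow = TRUE)
  }
  point_cloud(pts, normals)
}

face_normals <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Extract the external surface cloud of a skull mesh
#'
#' Renders the 10 standard views, back-projects every foreground pixel with
#' normals transferred from the source triangles, merges the 10 clouds, and
#' Poisson-disk simplifies the result to `target_points`.
#'
#' @param mesh a [triangle_mesh()].
#' @param image_size snapshot resolution (pixels per side), default 1024.
#' @param target_points simplified cloud size, default 40000.
#' @param seed RNG seed for the Poisson-disk pass.
#' @return A [point_cloud()] with normals; attribute `merged_points` records
#'   the pre-simplification merged cloud size.
#' @export
extract_external_surface <- function(mesh, image_size = 1024,
                                     target_points = 40000, seed = 1) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  views <- generate_views(mesh_bounds(mesh), image_size)
  clouds <- lapply(views, function(v) backproject_depth(render_depth(mesh, v), mesh))
  pts <- do.call(rbind, lapply(clouds, function(c) c$points))
  nrm <- do.call(rbind, lapply(clouds, function(c) c$normals))
  if (!nrow(pts)) stop("extraction error: mesh has no visible surface", call. = FALSE)
  merged <- point_cloud(pts, nrm)
  out <- if (nrow(pts) > target_points)
    poisson_disk_sample(merged, target_points, seed = seed) else merged
  attr(out, "merged_points") <- nrow(pts)
  out
}

#' Poisson-disk simplification
#'
#' Greedy dart-throwing sample elimination: points are visited in a seeded
#' random order and accepted iff no previously accepted point lies within a
#' radius r, which is auto-tuned by bisection so the accepted count lands
#' within 2% of `target`. The output is a subset of the input with minimum
#' pairwise distance >= r.
#'
#' @param cloud a [point_cloud()] with at least `target` points.
#' @param target requested output size.
#' @param seed RNG seed (visit order).
#' @return A [point_cloud()]; attribute `radius` carries the tuned r.
#' @export
poisson_disk_sample <- function(cloud, target, seed = 1) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (target > n) stop("target larger than input cloud", call. = FALSE)
  if (target == n) return(cloud)
  ord <- with_seed(seed, sample.int(n))
  bb <- apply(cloud$points, 2, range)
  lo <- 0
  hi <- sqrt(sum((bb[2, ] - bb[1, ])^2)) / max(1, target)^(1/3)
  count_at <- function(r) length(cpp_poisson_disk(cloud$points, r, ord))
  while (count_at(hi) > target && hi < 1e9) hi <- hi * 2
  best <- NULL
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    sel <- cpp_poisson_disk(cloud$points, mid, ord)
    k <- length(sel)
    if (abs(k - target) <= 0.02 * target) { best <- list(sel = sel, r = mid); break }
    if (k > target) lo <- mid else hi <- mid
    if (is.null(best) || abs(k - target) < abs(length(best$sel) - target))
      best <- list(sel = sel, r = mid)
  }
  idx <- sort(best$sel)
  out <- point_cloud(cloud$points[idx, , drop = FALSE],
                     if (!is.null(cloud$normals)) cloud$normals[idx, , drop = FALSE])
  attr(out, "radius") <- best$r
  out
}

#' Resample a cloud to a fixed size
#'
#' Farthest-point sampling (deterministic given `start = seed mod size`) or
#' seeded uniform sampling; used to feed completion backends that require a
#' fixed input size.
#'
#' @param cloud a [point_cloud()].
#' @param n output size (<= cloud size).
#' @param method "fps" or "random".
#' @param seed RNG seed / fps start index.
#' @return A [point_cloud()] of exactly `n` points.
#' @export
resample <- function(cloud, n, method = c("fps", "random"), seed = 1) {
  stopifnot(inherits(cloud, "point_cloud"))
  method <- match.arg(method)
  size <- n_points(cloud)
  if (n > size) stop("n larger than cloud size", call. = FALSE)
  if (n == size) return(cloud)
  idx <- if (method == "fps") {
    cpp_fps(cloud$points, n, (seed %% size) + 1L)
  } else {
    with_seed(seed, sample.int(size, n))
  }
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$normals)) cloud$normals[idx, , drop = FALSE])
}
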