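# Rigid alignment: least-squares landmark fit (cross-covariance SVD with a
# reflection guard) followed by point-to-point ICP refinement.

kabsch_fit <- function(src, ref) {
  cs <- colMeans(src); cr <- colMeans(ref)
  h <- crossprod(sweep(src, 2, cs), sweep(ref, 2, cr))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(rot, as.numeric(cr - rot %*% cs))
}

#' Least-squares rigid landmark alignment
#'
#' Finds the rotation + translation minimising the sum of squared distances
#' between the transformed source landmarks and the reference landmarks
#' (no scaling, no reflection). Exact to machine precision for noise-free
#' correspondences.
#'
#' @param source,reference [landmark_set()] objects.
#' @return A [rigid_transform()].
#' @export
kabsch_align <- function(source, reference) {
  stopifnot(inherits(source, "landmark_set"), inherits(reference, "landmark_set"))
  kabsch_fit(source$matrix, reference$matrix)
}

#' Point-to-point ICP refinement
#'
#' Full-correspondence iterative closest point: at each iteration every source
#' point is matched to its nearest reference point and the rigid least-squares
#' fit is applied. The RMS closest-point residual is non-increasing across
#' iterations; iteration stops at `max_iter` or when the residual improves by
#' less than `tol`.
#'
#' @param source,reference [point_cloud()] objects (non-empty).
#' @param init initial [rigid_transform()].
#' @param max_iter iteration cap.
#' @param tol residual-improvement stopping threshold (mm).
#' @param max_dist optional correspondence rejection gate (mm); pairs farther
#'   apart are dropped from the fit (default: no gate).
#' @return A [rigid_transform()] with attribute `residuals` (RMS per iteration).
#' @export
icp_refine <- function(source, reference, init = rigid_transform(),
                       max_iter = 50, tol = 1e-6, max_dist = Inf) {
  stopifnot(inherits(source, "point_cloud"), inherits(reference, "point_cloud"))
  if (n_points(source) == 0L || n_points(reference) == 0L)
    stop("ICP requires non-empty clouds", call. = FALSE)
  cur <- init
  resid <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    moved <- transform_points(source$points, cur)
    nn <- cpp_knn(reference$points, moved, 1L)
    keep <- nn$dist[, 1] <= max_dist
    if (sum(keep) < 3L) stop("too few ICP correspondences under max_dist", call. = FALSE)
    rms <- sqrt(mean(nn$dist[keep, 1]^2))
    resid <- c(resid, rms)
    if (prev - rms < tol) break
    prev <- rms
    step <- kabsch_fit(moved[keep, , drop = FALSE],
                       reference$points[nn$idx[keep, 1], , drop = FALSE])
    cur <- compose_transforms(step, cur)
  }
  attr(cur, "residuals") <- resid
  cur
}

transform_points <- function(points, t) {
  sweep(points %*% t(t$rotation), 2, t$translation, "+")
}

#' Apply a rigid transform to a cloud or mesh
#'
#' Points map as `p -> R p + t`; normals are rotated only.
#'
#' @param geometry a [point_cloud()] or [triangle_mesh()].
#' @param t a [rigid_transform()].
#' @return The transformed object, same class as the input.
#' @export
apply_transform <- function(geometry, t) {
  stopifnot(inherits(t, "rigid_transform"))
  if (inherits(geometry, "point_cloud")) {
    nm <- geometry$normals
    if (!is.null(nm)) nm <- nm %*% t(t$rotation)
    point_cloud(transform_points(geometry$points, t), nm)
  } else if (inherits(geometry, "triangle_mesh")) {
    nm <- geometry$vertex_normals
    if (!is.null(nm)) nm <- nm %*% t(t$rotation)
    triangle_mesh(transform_points(geometry$vertices, t), geometry$faces, nm)
  } else stop("apply_transform expects a point_cloud or triangle_mesh", call. = FALSE)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Read a labelled landmark file (JSON)
#'
#' Expected schema: `{"frontozygomatic_left": [x,y,z],
#' "frontozygomatic_right": [x,y,z], "basion": [x,y,z]}`.
#'
#' @param path JSON file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  doc <- jsonlite::fromJSON(path)
  for (f in c("frontozygomatic_left", "frontozygomatic_right", "basion"))
    if (is.null(doc[[f]])) stop(sprintf("landmark file missing '%s'", f), call. = FALSE)
  landmark_set(doc$frontozygomatic_left, doc$frontozygomatic_right, doc$basion)
}
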