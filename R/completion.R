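# Pluggable completion backends and the region-retention merge. Backends
# operate entirely in normalized space: a normalized partial cloud of the
# backend's declared input size goes in, a normalized completed cloud comes
# out. Neural completion networks plug in through the stored-prediction
# adapter; the package ships a classical mirror baseline and a passthrough
# stub. After completion only the points inside the (dilated) defect cuboid
# are retained and concatenated with the partial input; the merged cloud
# carries normals only on the partial part.

#' Completion backend contract
#'
#' @param name backend label.
#' @param fn function(cloud, sample_id, params) returning a normalized
#'   completed [point_cloud()].
#' @param input_points required input size (`NA` = any).
#' @param output_points declared output size (`NA` = backend-dependent).
#' @return An object of class `completion_backend`.
#' @export
completion_backend <- function(name, fn, input_points = NA, output_points = NA) {
  stopifnot(is.function(fn))
  structure(list(name = name, fn = fn,
                 input_points = input_points, output_points = output_points),
            class = "completion_backend")
}

#' Run a completion backend
#'
#' Validates the backend's size contract on both sides: the partial cloud must
#' already be resampled to `input_points`, and the output must have
#' `output_points` points when the backend declares a fixed size.
#'
#' @param backend a [completion_backend()].
#' @param partial_norm normalized partial [point_cloud()].
#' @param sample_id optional id, used by stored-prediction backends.
#' @param params optional [normalization_params()] (the mirror baseline uses
#'   them to locate the anatomical sagittal plane in normalized space).
#' @return Normalized completed [point_cloud()].
#' @export
complete <- function(backend, partial_norm, sample_id = NULL, params = NULL) {
  stopifnot(inherits(backend, "completion_backend"),
            inherits(partial_norm, "point_cloud"))
  if (!is.na(backend$input_points) && n_points(partial_norm) != backend$input_points)
    stop(sprintf("backend '%s' requires %d input points, got %d",
                 backend$name, backend$input_points, n_points(partial_norm)),
         call. = FALSE)
  out <- backend$fn(partial_norm, sample_id, params)
  if (!inherits(out, "point_cloud"))
    stop(sprintf("backend '%s' did not return a point_cloud", backend$name), call. = FALSE)
  if (!is.na(backend$output_points) && n_points(out) != backend$output_points)
    stop(sprintf("backend '%s' declared %d output points but produced %d",
                 backend$name, backend$output_points, n_points(out)), call. = FALSE)
  out
}

#' Passthrough backend (stub)
#'
#' Returns the partial cloud unchanged; useful as a null baseline (it leaves
#' the defect region empty).
#' @return A [completion_backend()].
#' @export
backend_passthrough <- function() {
  completion_backend("passthrough", function(cloud, sample_id, params) cloud)
}

#' Mirror a cloud about a sagittal plane
#'
#' The classical mirroring baseline: the output is the union of the input and
#' its reflection about the plane `x = plane_x`; reflected normals have their
#' x component negated. Only applicable to unilateral defects — a defect
#' crossing the symmetry plane cannot be filled by reflection.
#'
#' @param cloud a [point_cloud()].
#' @param plane_x x coordinate of the mirror plane (same units as the cloud).
#' @return A [point_cloud()] with `2 * n` points.
#' @export
mirror_complete <- function(cloud, plane_x = 0) {
  stopifnot(inherits(cloud, "point_cloud"))
  refl <- cloud$points
  refl[, 1] <- 2 * plane_x - refl[, 1]
  nm <- NULL
  if (!is.null(cloud$normals)) {
    rn <- cloud$normals
    rn[, 1] <- -rn[, 1]
    nm <- rbind(cloud$normals, rn)
  }
  point_cloud(rbind(cloud$points, refl), nm)
}

#' Mirror baseline backend
#'
#' Mirrors about the anatomical sagittal plane of the aligned frame (world
#' x = 0), which in normalized coordinates sits at `-centroid_x / m`; without
#' normalization params it mirrors about normalized x = 0.
#' @return A [completion_backend()].
#' @export
backend_mirror <- function() {
  completion_backend("mirror", function(cloud, sample_id, params) {
    plane_x <- if (!is.null(params)) -params$centroid[1] / params$m else 0
    mirror_complete(cloud, plane_x)
  })
}

#' Stored-prediction backend
#'
#' Adapter for externally computed completions (e.g. trained neural networks):
#' serves `<dir>/<sample_id>.ply` (normalized coordinates) for each sample.
#'
#' @param dir prediction directory.
#' @return A [completion_backend()].
#' @export
load_predictions <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("I/O error: no such directory '%s'", dir), call. = FALSE)
  completion_backend(paste0("files:", dir), function(cloud, sample_id, params) {
    if (is.null(sample_id)) stop("file backend requires a sample_id", call. = FALSE)
    path <- file.path(dir, paste0(sample_id, ".ply"))
    if (!file.exists(path))
      stop(sprintf("missing prediction for sample '%s' (%s)", sample_id, path),
           call. = FALSE)
    read_cloud(path)
  })
}

#' Retain the completed points inside the defect region
#'
#' Same boundary-inclusive containment rule as [apply_defect()], with the
#' cuboid optionally dilated by `margin` mm on all sides (default 0: exactly
#' the defective region).
#'
#' @param completed a [point_cloud()] (same units as the defect spec).
#' @param defect a [defect_spec()].
#' @param margin dilation (mm), default 0.
#' @return A [point_cloud()].
#' @export
extract_defect_region <- function(completed, defect, margin = 0) {
  stopifnot(inherits(completed, "point_cloud"), inherits(defect, "defect_spec"))
  if (n_points(completed) == 0L) return(completed)
  dil <- defect
  dil$base_side <- defect$base_side + 2 * margin
  dil$height <- defect$height + 2 * margin
  keep <- cuboid_mask(completed$points, dil)
  point_cloud(completed$points[keep, , drop = FALSE],
              if (!is.null(completed$normals)) completed$normals[keep, , drop = FALSE])
}

#' Concatenate the partial input with the retained defect points
#'
#' The partial points keep their inherited normals; the appended defect points
#' carry all-`NA` normal rows, flagging them for estimation downstream.
#'
#' @param partial [point_cloud()] with normals (inherited from the mesh).
#' @param defect_points [point_cloud()] retained by [extract_defect_region()].
#' @return A [point_cloud()] of `n_partial + n_defect` points.
#' @export
merge_completion <- function(partial, defect_points) {
  stopifnot(inherits(partial, "point_cloud"), inherits(defect_points, "point_cloud"))
  pts <- rbind(partial$points, defect_points$points)
  pn <- partial$normals
  if (is.null(pn) && n_points(partial) > 0L)
    pn <- matrix(NA_real_, n_points(partial), 3)
  nm <- rbind(pn, matrix(NA_real_, n_points(defect_points), 3))
  point_cloud(pts, nm)
}
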