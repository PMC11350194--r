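# Fixed-scale normalization into the completion backend's input range.
# Both the partial and (when available) the complete cloud are centred on the
# centroid of the PARTIAL cloud — the only centroid available at deployment —
# and divided by a constant scale m shared across all skulls (default 155 mm,
# the maximum per-cloud scale over the reference training set). A fixed m
# keeps corresponding anatomy at the same normalized scale regardless of
# defect size, unlike per-cloud (ShapeNet-style) max-norm scaling.

#' Normalize a partial/complete cloud pair
#'
#' `p' = (p - centroid(partial)) / m` applied to both clouds. The complete
#' cloud may be absent (deployment mode). Returns the parameters needed for
#' exact inversion. Coordinates exceeding \[-1, 1\] after scaling trigger a
#' warning, not an error.
#'
#' @param partial non-empty [point_cloud()] (mm).
#' @param complete optional [point_cloud()] (mm).
#' @param m fixed scale (mm), default 155.
#' @return list(partial, complete, params = [normalization_params()]).
#' @export
normalize_pair <- function(partial, complete = NULL, m = 155) {
  stopifnot(inherits(partial, "point_cloud"))
  if (n_points(partial) == 0L) stop("empty partial cloud", call. = FALSE)
  if (!is.finite(m) || m <= 0) stop("m must be positive", call. = FALSE)
  centroid <- colMeans(partial$points)
  params <- normalization_params(centroid, m)
  scale_one <- function(cloud) {
    if (is.null(cloud)) return(NULL)
    out <- point_cloud(sweep(cloud$points, 2, centroid) / m, cloud$normals)
    if (max(abs(out$points)) > 1)
      warning("normalized coordinates exceed [-1, 1] (cloud larger than m)")
    out
  }
  list(partial = scale_one(partial), complete = scale_one(complete), params = params)
}

#' Invert the normalization
#'
#' Exact inverse `p = p' * m + centroid`; normals are unchanged (directions
#' are invariant under uniform scaling and translation).
#'
#' @param cloud a normalized [point_cloud()].
#' @param params the [normalization_params()] returned by [normalize_pair()].
#' @return A [point_cloud()] in mm.
#' @export
denormalize <- function(cloud, params) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(params, "normalization_params"))
  point_cloud(sweep(cloud$points * params$m, 2, params$centroid, "+"), cloud$normals)
}

#' Maximum per-cloud scale over a training set
#'
#' For each cloud: the maximum point norm after subtracting that cloud's own
#' centroid; returns the maximum over clouds. Using this value as the fixed
#' scale guarantees every normalized training coordinate lies in \[-1, 1\].
#'
#' @param clouds list of [point_cloud()] objects.
#' @return Scale in mm.
#' @export
compute_training_scale <- function(clouds) {
  if (!length(clouds)) stop("need at least one cloud", call. = FALSE)
  max(vapply(clouds, function(cl) {
    stopifnot(inherits(cl, "point_cloud"))
    centred <- sweep(cl$points, 2, colMeans(cl$points))
    sqrt(max(rowSums(centred^2)))
  }, 0.0))
}

#' Read/write normalization parameters (JSON)
#' @param path JSON path.
#' @return [normalization_params()] for the reader.
#' @export
read_norm_params <- function(path) {
  doc <- jsonlite::fromJSON(path)
  normalization_params(doc$centroid, doc$m)
}

#' @rdname read_norm_params
#' @param params a [normalization_params()].
#' @export
write_norm_params <- function(params, path) {
  jsonlite::write_json(list(centroid = params$centroid, m = params$m), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a defect spec (JSON)
#' @param path JSON path.
#' @return [defect_spec()] for the reader.
#' @export
read_defect_spec <- function(path) {
  doc <- jsonlite::fromJSON(path)
  defect_spec(doc$center, doc$base_side, doc$height)
}

#' @rdname read_defect_spec
#' @param defect a [defect_spec()].
#' @export
write_defect_spec <- function(defect, path) {
  jsonlite::write_json(list(center = defect$center, base_side = defect$base_side,
                            height = defect$height), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
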