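# Virtual defect injection: axis-aligned square-base cuboids with side and
# height uniform in [30, 100] mm, centred on a random cloud point drawn from a
# quality-score-dependent region. The region presets are fractions of the
# cloud's bounding box and approximate the anatomy: the splanchnocranium
# (facial skeleton, lower anterior) for quality score 4 and the
# maxilla/mandible band for quality score 5; scores 2-3 use the whole cloud.

region_presets <- list(
  whole            = list(z = c(0, 1),      y = c(0, 1)),
  splanchnocranium = list(z = c(0, 0.45),   y = c(0.5, 1)),
  maxilla_mandible = list(z = c(0, 0.30),   y = c(0.5, 1)),
  orbit            = list(z = c(0.40, 0.60), y = c(0.6, 1))
)

#' Defect placement region for a quality score
#'
#' Scores 2-3 place defects anywhere on the cloud; score 4 targets the
#' splanchnocranium; score 5 the maxilla/mandible band. Score 1 scans are
#' discarded upstream and rejected here.
#'
#' @param qs quality score in \{2,3,4,5\}.
#' @return A [region_spec()].
#' @export
region_for_quality <- function(qs) {
  if (length(qs) != 1L || !qs %in% 2:5)
    stop("quality score must be one of 2, 3, 4, 5", call. = FALSE)
  name <- switch(as.character(qs), "2" = "whole", "3" = "whole",
                 "4" = "splanchnocranium", "5" = "maxilla_mandible")
  p <- region_presets[[name]]
  region_spec(name, z_lo = p$z[1], z_hi = p$z[2], y_lo = p$y[1], y_hi = p$y[2])
}

#' Named region preset
#' @param name one of "whole", "splanchnocranium", "maxilla_mandible", "orbit".
#' @return A [region_spec()].
#' @export
region_preset <- function(name) {
  p <- region_presets[[name]]
  if (is.null(p)) stop(sprintf("unknown region preset '%s'", name), call. = FALSE)
  region_spec(name, z_lo = p$z[1], z_hi = p$z[2], y_lo = p$y[1], y_hi = p$y[2])
}

region_mask <- function(cloud, region) {
  bb <- apply(cloud$points, 2, range)
  zf <- (cloud$points[, 3] - bb[1, 3]) / max(bb[2, 3] - bb[1, 3], 1e-12)
  yf <- (cloud$points[, 2] - bb[1, 2]) / max(bb[2, 2] - bb[1, 2], 1e-12)
  zf >= region$z_lo & zf <= region$z_hi & yf >= region$y_lo & yf <= region$y_hi
}

#' Sample a random cuboid defect
#'
#' The centre is drawn uniformly among the cloud points inside the region;
#' base side and height are independent uniform draws in `size_range`.
#' Draws are repeated (up to `max_draws`) until the cuboid removes at least
#' `min_points` points, preventing degenerate defects in empty space.
#'
#' @param cloud a [point_cloud()].
#' @param region a [region_spec()].
#' @param seed RNG seed; the draw is deterministic given it.
#' @param size_range defect side/height range (mm), default c(30, 100).
#' @param min_points minimum removed-point count, default 100.
#' @param max_draws redraw cap, default 20.
#' @return A [defect_spec()].
#' @export
sample_defect <- function(cloud, region, seed = 1, size_range = c(30, 100),
                          min_points = 100, max_draws = 20) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(region, "region_spec"))
  mask <- region_mask(cloud, region)
  cand <- which(mask)
  if (!length(cand))
    stop(sprintf("region error: no cloud point in region '%s'", region$name), call. = FALSE)
  with_seed(seed, {
    for (draw in seq_len(max_draws)) {
      ci <- cand[sample.int(length(cand), 1L)]
      bs <- runif(1, size_range[1], size_range[2])
      ht <- runif(1, size_range[1], size_range[2])
      spec <- defect_spec(cloud$points[ci, ], bs, ht)
      if (sum(cuboid_mask(cloud$points, spec)) >= min_points) return(spec)
    }
    stop(sprintf("placement error: no defect removing >= %d points in %d draws",
                 min_points, max_draws), call. = FALSE)
  })
}

cuboid_mask <- function(points, defect) {
  h <- defect$base_side / 2
  abs(points[, 1] - defect$center[1]) <= h &
    abs(points[, 2] - defect$center[2]) <= h &
    abs(points[, 3] - defect$center[3]) <= defect$height / 2
}

#' Apply a cuboid defect to a cloud
#'
#' Boundary-inclusive containment: a point is removed iff it lies inside the
#' cuboid (|dx| <= side/2, |dy| <= side/2, |dz| <= height/2). The partial and
#' removed clouds partition the input exactly, order preserved, normals
#' carried along.
#'
#' @param cloud a [point_cloud()].
#' @param defect a [defect_spec()].
#' @return list(partial, removed) of [point_cloud()] objects.
#' @export
apply_defect <- function(cloud, defect) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(defect, "defect_spec"))
  inside <- cuboid_mask(cloud$points, defect)
  subset_cloud <- function(keep) {
    point_cloud(cloud$points[keep, , drop = FALSE],
                if (!is.null(cloud$normals)) cloud$normals[keep, , drop = FALSE])
  }
  list(partial = subset_cloud(!inside), removed = subset_cloud(inside))
}

#' Materialize the fixed validation/test defect pairs
#'
#' Applies every val/test record's stored defect and writes the partial and
#' removed clouds with deterministic filenames
#' (`<sample_id>_partial.ply`, `<sample_id>_removed.ply`); idempotent.
#'
#' @param manifest a [dataset_manifest()].
#' @param clouds named list mapping sample_id to [point_cloud()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a data.frame of written files per sample.
#' @export
build_eval_set <- function(manifest, clouds, out_dir) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  eval_recs <- Filter(function(r) r$split %in% c("val", "test"), manifest$records)
  missing <- vapply(eval_recs, function(r) is.null(clouds[[r$sample_id]]), TRUE)
  if (any(missing))
    stop(sprintf("missing clouds for: %s",
                 paste(vapply(eval_recs[missing], function(r) r$sample_id, ""),
                       collapse = ", ")), call. = FALSE)
  rows <- lapply(eval_recs, function(r) {
    pair <- apply_defect(clouds[[r$sample_id]], r$defect)
    pf <- file.path(out_dir, paste0(r$sample_id, "_partial.ply"))
    rf <- file.path(out_dir, paste0(r$sample_id, "_removed.ply"))
    write_cloud(pair$partial, pf, "ply_binary")
    write_cloud(pair$removed, rf, "ply_binary")
    data.frame(sample_id = r$sample_id, split = r$split,
               partial = pf, removed = rf, stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}

# Deterministic integer hash for per-(sample, epoch, draw) seeds; all
# arithmetic stays below 2^53 so the modular reduction is exact.
hash_seed <- function(base_seed, sample_id, epoch, draw = 1) {
  m <- 2147483647
  h <- base_seed %% m
  for (ch in utf8ToInt(sample_id)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + epoch %% m) %% m
  h <- (h * 131 + draw %% m) %% m
  as.integer(h)
}

#' Online (training-style) defect stream
#'
#' Returns a generator closure emitting `(partial, removed, spec)` for a given
#' sample and epoch. Each draw is seeded by a hash of
#' `(base_seed, sample_id, epoch, draw)`, so replaying an epoch is exact while
#' successive epochs yield fresh defects for the same sample — the online
#' augmentation used for training splits, as opposed to the fixed offline
#' val/test pairs of [build_eval_set()].
#'
#' @param clouds named list mapping sample_id to [point_cloud()].
#' @param quality_scores named integer vector (same names).
#' @param base_seed integer stream seed.
#' @return function(sample_id, epoch, draw = 1) -> list(partial, removed, spec).
#' @export
online_defect_iterator <- function(clouds, quality_scores, base_seed = 1) {
  force(clouds); force(quality_scores); force(base_seed)
  function(sample_id, epoch, draw = 1) {
    cloud <- clouds[[sample_id]]
    if (is.null(cloud)) stop(sprintf("unknown sample '%s'", sample_id), call. = FALSE)
    region <- region_for_quality(quality_scores[[sample_id]])
    spec <- sample_defect(cloud, region,
                          seed = hash_seed(base_seed, sample_id, epoch, draw))
    c(apply_defect(cloud, spec), list(spec = spec))
  }
}
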