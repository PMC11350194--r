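# Region-restricted evaluation metrics. All distances are plain (unsquared)
# Euclidean in millimetres, and evaluation always happens after
# de-normalization, restricted to the reconstructed (defect) region rather
# than the whole shape. The F-score threshold tau defaults to 3 mm.

check_nonempty <- function(...) {
  for (cl in list(...)) {
    stopifnot(inherits(cl, "point_cloud"))
    if (n_points(cl) == 0L) stop("metrics require non-empty clouds", call. = FALSE)
  }
}

#' Accuracy: mean ground-truth-to-reconstruction nearest-neighbour distance
#'
#' For each ground-truth point, the distance to its nearest reconstructed
#' point, averaged (mm). Low accuracy means the reconstruction lies close to
#' the truth.
#'
#' @param gt,rec non-empty [point_cloud()] objects (mm).
#' @return Distance in mm.
#' @export
accuracy <- function(gt, rec) {
  check_nonempty(gt, rec)
  mean(cpp_knn(rec$points, gt$points, 1L)$dist[, 1])
}

#' Completeness: mean reconstruction-to-ground-truth distance
#'
#' For each reconstructed point, the distance to its nearest ground-truth
#' point, averaged (mm). Measures how much of the output stays on the truth.
#'
#' @inheritParams accuracy
#' @return Distance in mm.
#' @export
completeness <- function(gt, rec) {
  check_nonempty(gt, rec)
  mean(cpp_knn(gt$points, rec$points, 1L)$dist[, 1])
}

#' Chamfer distance: accuracy + completeness
#' @inheritParams accuracy
#' @return Distance in mm.
#' @export
chamfer <- function(gt, rec) accuracy(gt, rec) + completeness(gt, rec)

#' Earth Mover's Distance (exact optimal assignment)
#'
#' Mean distance between corresponding points under the optimal one-to-one
#' matching. Clouds of unequal size are first equalized by seeded random
#' downsampling of the larger one; when both exceed `max_points` both are
#' downsampled to `max_points`. The assignment is solved exactly (Hungarian).
#'
#' @param p,q non-empty [point_cloud()] objects.
#' @param max_points assignment size cap, default 2048.
#' @param seed downsampling seed.
#' @return list(emd_mm, matching, n) where matching maps indices of the
#'   (possibly downsampled) `p` to `q`.
#' @export
emd <- function(p, q, max_points = 2048, seed = 1) {
  check_nonempty(p, q)
  n <- min(n_points(p), n_points(q), max_points)
  ds <- function(cl, which_seed) {
    if (n_points(cl) == n) return(cl$points)
    idx <- with_seed(which_seed, sample.int(n_points(cl), n))
    cl$points[idx, , drop = FALSE]
  }
  pp <- ds(p, seed)
  qq <- ds(q, seed + 1)
  cost2 <- outer(rowSums(pp^2), rowSums(qq^2), "+") - 2 * tcrossprod(pp, qq)
  cost2[cost2 < 0] <- 0  # guard tiny negative rounding before the sqrt
  cost <- sqrt(cost2)
  sol <- cpp_lap(cost)
  d <- sqrt(rowSums((pp - qq[sol$assignment, , drop = FALSE])^2))
  list(emd_mm = mean(d), matching = sol$assignment, n = n)
}

#' Precision, recall and F-score at threshold tau
#'
#' Precision: fraction of reconstructed points within `tau` of some
#' ground-truth point; recall: fraction of ground-truth points within `tau`
#' of some reconstructed point; F-score: their harmonic mean (0 when both
#' are 0).
#'
#' @inheritParams accuracy
#' @param tau distance threshold (mm), default 3.
#' @return list(precision, recall, fscore).
#' @export
precision_recall_fscore <- function(gt, rec, tau = 3) {
  check_nonempty(gt, rec)
  prec <- mean(cpp_knn(gt$points, rec$points, 1L)$dist[, 1] < tau)
  rec_ <- mean(cpp_knn(rec$points, gt$points, 1L)$dist[, 1] < tau)
  f <- if (prec + rec_ == 0) 0 else 2 * prec * rec_ / (prec + rec_)
  list(precision = prec, recall = rec_, fscore = f)
}

#' Evaluate a completed cloud against the ground-truth defect points
#'
#' De-normalizes the completed cloud, retains the points inside the defect
#' cuboid (margin 0), and computes all five metrics against the ground-truth
#' removed points (which are in mm and never normalized). An empty extracted
#' region yields an infinite-accuracy sentinel report with F-score 0, flagged
#' with `empty_region = TRUE`, so batch tables stay rectangular.
#'
#' @param gt_removed ground-truth removed [point_cloud()] (mm).
#' @param completed_norm completed [point_cloud()] in normalized space.
#' @param defect the [defect_spec()] (mm).
#' @param params the [normalization_params()] used for the partial cloud.
#' @param tau F-score threshold (mm), default 3.
#' @param emd_max_points assignment cap for the EMD, default 2048.
#' @param emd_seed downsampling seed for the EMD.
#' @return An object of class `metrics_report`.
#' @export
evaluate_reconstruction <- function(gt_removed, completed_norm, defect, params,
                                    tau = 3, emd_max_points = 2048, emd_seed = 1) {
  stopifnot(inherits(defect, "defect_spec"))
  if (!inherits(params, "normalization_params"))
    stop("missing normalization params", call. = FALSE)
  check_nonempty(gt_removed, completed_norm)
  completed_mm <- denormalize(completed_norm, params)
  region <- extract_defect_region(completed_mm, defect, margin = 0)
  if (n_points(region) == 0L) {
    rep <- list(accuracy_mm = Inf, completeness_mm = Inf, chamfer_mm = Inf,
                emd_mm = Inf, precision = 0, recall = 0, fscore = 0,
                tau_mm = tau, n_gt = n_points(gt_removed), n_rec = 0L,
                empty_region = TRUE)
    return(structure(rep, class = "metrics_report"))
  }
  acc <- accuracy(gt_removed, region)
  com <- completeness(gt_removed, region)
  prf <- precision_recall_fscore(gt_removed, region, tau)
  em <- emd(gt_removed, region, max_points = emd_max_points, seed = emd_seed)
  structure(list(accuracy_mm = acc, completeness_mm = com, chamfer_mm = acc + com,
                 emd_mm = em$emd_mm, precision = prf$precision,
                 recall = prf$recall, fscore = prf$fscore, tau_mm = tau,
                 n_gt = n_points(gt_removed), n_rec = n_points(region),
                 empty_region = FALSE),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report: accuracy %.4f mm, completeness %.4f mm, ",
                     "CD %.4f mm, EMD %.4f mm, F-score(%g mm) %.4f%s>\n"),
              x$accuracy_mm, x$completeness_mm, x$chamfer_mm, x$emd_mm,
              x$tau_mm, x$fscore,
              if (isTRUE(x$empty_region)) " [empty region]" else ""))
  invisible(x)
}

#' Serialize / read a metrics report (JSON, lossless)
#' @param report a `metrics_report`.
#' @param path JSON path.
#' @export
write_metrics_report <- function(report, path) {
  out <- unclass(report)
  out[vapply(out, function(v) is.numeric(v) && !is.finite(v), TRUE)] <- "Inf"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  doc <- jsonlite::fromJSON(path)
  num <- c("accuracy_mm", "completeness_mm", "chamfer_mm", "emd_mm",
           "precision", "recall", "fscore", "tau_mm")
  for (f in num) doc[[f]] <- as.numeric(doc[[f]])
  doc$n_gt <- as.integer(doc$n_gt); doc$n_rec <- as.integer(doc$n_rec)
  structure(doc, class = "metrics_report")
}
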