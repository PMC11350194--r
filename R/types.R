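#' @useDynLib skullrec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median quantile runif rnorm sd
#' @importFrom utils head
NULL

as_coord_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  dimnames(x) <- NULL
  x
}

#' Point cloud in millimetres
#'
#' An ordered set of 3-d points with optional unit normals. Coordinates are
#' millimetres throughout the package; files carry no unit metadata. Normals
#' may be missing row-wise (all-`NA` rows), which marks points whose normal is
#' still to be estimated — the state of the reconstructed region right after
#' merging a completion with the partial input.
#'
#' @param points n x 3 numeric matrix (mm).
#' @param normals optional n x 3 matrix of unit vectors; rows of `NA` allowed.
#' @return An object of class `point_cloud` with elements `points`, `normals`.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as_coord_matrix(points)
  if (!all(is.finite(points))) stop("point coordinates must be finite", call. = FALSE)
  if (!is.null(normals)) {
    normals <- as_coord_matrix(normals, "normals")
    if (nrow(normals) != nrow(points))
      stop("normals count must equal point count", call. = FALSE)
    miss <- rowSums(is.na(normals)) > 0L
    if (any(miss & rowSums(is.na(normals)) != 3L))
      stop("normal rows must be fully present or fully NA", call. = FALSE)
    if (any(!miss)) {
      len <- sqrt(rowSums(normals[!miss, , drop = FALSE]^2))
      if (any(abs(len - 1) > 1e-6))
        stop("normals must have unit length (within 1e-6)", call. = FALSE)
    }
  }
  structure(list(points = points, normals = normals), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s>\n", nrow(x$points),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

#' Triangle mesh in millimetres
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_normals optional n x 3 matrix of unit vectors.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, vertex_normals = NULL) {
  vertices <- as_coord_matrix(vertices, "vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
  if (is.null(dim(faces))) faces <- matrix(faces, ncol = 3, byrow = TRUE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range", call. = FALSE)
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
    if (any(degen)) stop("degenerate faces (repeated vertex index)", call. = FALSE)
  }
  if (!is.null(vertex_normals)) {
    vertex_normals <- as_coord_matrix(vertex_normals, "vertex_normals")
    if (nrow(vertex_normals) != nrow(vertices))
      stop("vertex_normals count must equal vertex count", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, vertex_normals = vertex_normals),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3", call. = FALSE)
  if (length(translation) != 3L) stop("translation must be length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1 (no reflection)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Anatomical landmark set for 3-point alignment
#'
#' The three landmarks used for the initial rigid alignment: the left and
#' right frontozygomatic sutures and the basion.
#'
#' @param frontozygomatic_left,frontozygomatic_right,basion length-3 points (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(frontozygomatic_left, frontozygomatic_right, basion) {
  m <- rbind(as.numeric(frontozygomatic_left),
             as.numeric(frontozygomatic_right),
             as.numeric(basion))
  if (ncol(m) != 3L || !all(is.finite(m))) stop("landmarks must be finite 3-vectors", call. = FALSE)
  area <- 0.5 * sqrt(sum(crossv(m[2, ] - m[1, ], m[3, ] - m[1, ])^2))
  if (area <= 1e-6) stop("landmarks are collinear (degenerate configuration)", call. = FALSE)
  structure(list(matrix = m,
                 labels = c("frontozygomatic_left", "frontozygomatic_right", "basion")),
            class = "landmark_set")
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Cuboid defect specification
#'
#' An axis-aligned rectangular cuboid with a square base in the axial (x-y)
#' plane and its height along z. Sampled defects have base side and height
#' uniform in \[30, 100\] mm (3-10 cm); user-supplied specs outside that range
#' are accepted with a warning.
#'
#' @param center length-3 centre (mm).
#' @param base_side square base side (mm).
#' @param height height along z (mm).
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(center, base_side, height) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite 3-vector", call. = FALSE)
  if (base_side <= 0 || height <= 0) stop("defect dimensions must be positive", call. = FALSE)
  if (base_side < 30 || base_side > 100 || height < 30 || height > 100)
    warning("defect dimensions outside the sampled 30-100 mm range")
  structure(list(center = center, base_side = as.numeric(base_side),
                 height = as.numeric(height), axis = "z"),
            class = "defect_spec")
}

#' Defect placement region
#'
#' Fractional bounds on z and y relative to a cloud's axis-aligned bounding
#' box; defect centres are drawn among the cloud points inside the region.
#'
#' @param name region label.
#' @param z_lo,z_hi,y_lo,y_hi fractional bounds in \[0, 1\].
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, z_lo = 0, z_hi = 1, y_lo = 0, y_hi = 1) {
  if (z_lo >= z_hi || y_lo >= y_hi) stop("region bounds must satisfy lo < hi", call. = FALSE)
  structure(list(name = name, z_lo = z_lo, z_hi = z_hi, y_lo = y_lo, y_hi = y_hi),
            class = "region_spec")
}

#' Normalization parameters
#'
#' Centroid of the partial cloud plus the fixed scale `m` (mm). The default
#' `m = 155` mm is the maximum per-cloud scale observed over the training
#' clouds of the reference dataset; synthetic datasets recompute it with
#' [compute_training_scale()].
#'
#' @param centroid length-3 centroid of the partial cloud (mm).
#' @param m positive scale (mm).
#' @return An object of class `normalization_params`.
#' @export
normalization_params <- function(centroid, m = 155) {
  centroid <- as.numeric(centroid)
  if (length(centroid) != 3L || !all(is.finite(centroid)))
    stop("centroid must be a finite 3-vector", call. = FALSE)
  if (!is.finite(m) || m <= 0) stop("m must be positive", call. = FALSE)
  structure(list(centroid = centroid, m = as.numeric(m)),
            class = "normalization_params")
}

#' Dataset sample record
#'
#' @param sample_id unique string id.
#' @param quality_score integer in 2..5 (score-1 scans are discarded).
#' @param split one of "train", "val", "test".
#' @param seed integer seed for this sample's defect draws.
#' @param defect optional [defect_spec()]; required for val/test records.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, quality_score, split, seed, defect = NULL) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("sample_id must be a non-empty string", call. = FALSE)
  if (!quality_score %in% 2:5)
    stop("quality_score must be in {2,3,4,5} (field 'quality_score')", call. = FALSE)
  if (!split %in% c("train", "val", "test"))
    stop("split must be train/val/test (field 'split')", call. = FALSE)
  if (split %in% c("val", "test") && is.null(defect))
    stop(sprintf("record '%s': val/test records require a fixed defect (field 'defect')",
                 sample_id), call. = FALSE)
  if (!is.null(defect) && !inherits(defect, "defect_spec"))
    stop("defect must be a defect_spec", call. = FALSE)
  structure(list(sample_id = sample_id, quality_score = as.integer(quality_score),
                 split = split, seed = as.integer(seed), defect = defect),
            class = "sample_record")
}

#' Dataset manifest
#'
#' @param records list of [sample_record()] with unique sample ids.
#' @return An object of class `dataset_manifest` with per-split counts.
#' @export
dataset_manifest <- function(records) {
  if (!length(records)) stop("manifest needs at least one record", call. = FALSE)
  ids <- vapply(records, function(r) r$sample_id, "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample_id: %s", ids[duplicated(ids)][1]), call. = FALSE)
  splits <- vapply(records, function(r) r$split, "")
  counts <- table(factor(splits, levels = c("train", "val", "test")))
  structure(list(schema_version = 1L, records = records,
                 counts = as.list(as.integer(counts)) |>
                   stats::setNames(c("train", "val", "test"))),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d records (train %d / val %d / test %d)>\n",
              length(x$records), x$counts$train, x$counts$val, x$counts$test))
  invisible(x)
}

#' Meshing parameters
#'
#' @param k_c neighbour count for PCA normal estimation (>= 3).
#' @param k_tg neighbour count for the orientation propagation graph (>= 2).
#' @param poisson_depth octree-equivalent depth: the indicator field is solved
#'   on a uniform `2^poisson_depth` grid; must lie in \[5, 12\].
#' @param trim_quantile density quantile (over the input samples) used to trim
#'   low-support vertices of the reconstructed mesh.
#' @return An object of class `meshing_params`.
#' @export
meshing_params <- function(k_c = 30, k_tg = 10, poisson_depth = 7,
                           trim_quantile = 0.01) {
  if (k_c < 3) stop("k_c must be >= 3", call. = FALSE)
  if (k_tg < 2) stop("k_tg must be >= 2", call. = FALSE)
  if (poisson_depth < 5 || poisson_depth > 12)
    stop("poisson_depth must be in [5, 12]", call. = FALSE)
  structure(list(k_c = as.integer(k_c), k_tg = as.integer(k_tg),
                 poisson_depth = as.integer(poisson_depth),
                 trim_quantile = trim_quantile),
            class = "meshing_params")
}

# Run code under a private, restored RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
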