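# Shared in-code fixtures and independent oracles (kept deliberately naive:
# all-pairs loops, exhaustive enumeration) for cross-checking the package's
# accelerated implementations.

random_cloud <- function(n, seed, scale = 100) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n, -scale, scale), ncol = 3))
}

# closed UV-sphere triangle mesh, built independently of the package fixtures
make_sphere_mesh <- function(radius = 50, n = 48) {
  theta <- seq_len(n - 1) * pi / n
  phi <- (seq_len(n) - 1) * 2 * pi / n
  ring <- function(i) cbind(radius * sin(theta[i]) * cos(phi),
                            radius * sin(theta[i]) * sin(phi),
                            radius * cos(theta[i]))
  verts <- do.call(rbind, lapply(seq_len(n - 1), ring))
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, -radius))
  ni <- nrow(verts) - 1L; si <- nrow(verts)
  idx <- function(i, j) (i - 1L) * n + ((j - 1L) %% n) + 1L
  faces <- list(cbind(ni, idx(1, 1:n), idx(1, 1:n + 1)))
  for (i in seq_len(n - 2)) {
    a <- idx(i, 1:n); b <- idx(i, 1:n + 1)
    cc <- idx(i + 1, 1:n); d <- idx(i + 1, 1:n + 1)
    faces[[i + 1L]] <- rbind(cbind(a, cc, b), cbind(b, cc, d))
  }
  faces[[n]] <- cbind(si, idx(n - 1, 1:n + 1), idx(n - 1, 1:n))
  triangle_mesh(verts, do.call(rbind, faces))
}

mesh_area <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

edge_face_counts <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - length(edge_face_counts(mesh$faces)) + nrow(mesh$faces)
}

# O(N^2) all-pairs nearest-neighbour oracle
brute_nn_dists <- function(A, B) {
  apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2))))
}

brute_accuracy <- function(gt, rec) mean(brute_nn_dists(gt$points, rec$points))
brute_completeness <- function(gt, rec) mean(brute_nn_dists(rec$points, gt$points))

# exhaustive-permutation EMD oracle (n <= 7)
brute_emd <- function(P, Q) {
  n <- nrow(P)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    d <- mean(sqrt(rowSums((P - Q[p, , drop = FALSE])^2)))
    if (d < best) best <- d
  }
  best
}

expect_cloud_equal <- function(a, b, tol = 1e-6) {
  expect_equal(nrow(a$points), nrow(b$points))
  expect_lt(max(abs(a$points - b$points)), tol)
}
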