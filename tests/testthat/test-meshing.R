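test_that("PCA normals handle planes, spheres, and match an eigen oracle", {
  set.seed(1)
  plane <- point_cloud(cbind(runif(200, -10, 10), runif(200, -10, 10), 0))
  n <- estimate_normals(plane, 15)
  expect_true(all(abs(abs(n[, 3]) - 1) < 1e-6))

  sph <- make_shell_cloud(4000, 50, seed = 2)
  ns <- estimate_normals(point_cloud(sph$points), 30)
  radial <- sph$points / 50
  expect_gte(mean(abs(rowSums(ns * radial)) >= 0.99), 0.99)

  expect_error(estimate_normals(point_cloud(diag(3)), 30), "more than")
})

test_that("per-point normals equal an independent eigen-decomposition", {
  cl <- random_cloud(400, 7, scale = 30)
  k <- 12L
  normals <- estimate_normals(cl, k)
  nn <- skullrec:::cpp_knn(cl$points, cl$points, k, TRUE)
  set.seed(8)
  for (i in sample.int(400, 100)) {
    nbr <- cl$points[nn$idx[i, ], , drop = FALSE]
    cov <- crossprod(sweep(nbr, 2, colMeans(nbr))) / k
    ev <- eigen(cov, symmetric = TRUE)
    oracle <- ev$vectors[, 3]
    cross <- skullrec:::crossv(normals[i, ], oracle)
    expect_lt(sqrt(sum(cross^2)), 1e-9)
  }
})

test_that("orientation propagation reaches near-perfect radial consistency", {
  sph <- make_shell_cloud(5000, 50, seed = 3)
  pc <- point_cloud(sph$points)
  est <- estimate_normals(pc, 30)
  ori <- orient_normals(pc, est, 10)
  radial <- sph$points / 50
  expect_gte(mean(rowSums(ori * radial) > 0), 0.999)

  # already consistent input: unchanged up to a global flip
  again <- orient_normals(pc, ori, 10)
  flips <- sign(rowSums(again * ori))
  expect_true(all(flips == flips[1]))

  # two distant clusters: per-component orientation with a warning
  far <- point_cloud(rbind(sph$points, sweep(sph$points, 2, c(1000, 0, 0), "+")))
  est2 <- rbind(est, est)
  expect_warning(ori2 <- orient_normals(far, est2, 10), "components")
  rad2 <- rbind(radial, radial)
  expect_gte(mean(rowSums(ori2 * rad2) > 0), 0.999)
})

test_that("Poisson reconstruction of a sampled sphere is accurate and watertight", {
  sph <- make_shell_cloud(10000, 50, seed = 4)
  mesh <- poisson_reconstruct(sph, poisson_depth = 7)
  expect_equal(attr(mesh, "boundary_edges"), 0L)
  expect_true(all(edge_face_counts(mesh$faces) == 2L))
  expect_equal(euler_characteristic(mesh), 2L)
  area <- mesh_area(mesh)
  expect_lt(abs(area / (4 * pi * 50^2) - 1), 0.05)
  r <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(r - 50)), 0.02 * 50)
  # mean cloud-to-mesh distance below twice the median sample spacing
  nn_self <- skullrec:::cpp_knn(sph$points, sph$points, 1L, TRUE)
  spacing <- median(nn_self$dist[, 1])
  d <- skullrec:::cpp_knn(mesh$vertices, sph$points, 1L)$dist[, 1]
  expect_lt(mean(d), 2 * spacing)
  expect_error(poisson_reconstruct(point_cloud(sph$points)), "oriented normals")
})

test_that("surface reconstruction fills missing normals and reports holes", {
  sph <- make_shell_cloud(6000, 50, seed = 5)
  half <- sph$normals
  half[1:3000, ] <- NA
  merged <- point_cloud(sph$points, half)
  mesh <- reconstruct_surface(merged, meshing_params(poisson_depth = 6))
  expect_equal(attr(mesh, "boundary_edges"), 0L)

  # a fully-normaled cloud skips estimation: identical to direct Poisson
  direct <- poisson_reconstruct(point_cloud(sph$points, sph$normals),
                                poisson_depth = 6)
  via <- reconstruct_surface(point_cloud(sph$points, sph$normals),
                             meshing_params(poisson_depth = 6), orient = FALSE)
  expect_identical(via$vertices, direct$vertices)
})
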