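test_that("the synthetic skull has two shells, symmetry, and a watertight outer surface", {
  mesh <- make_synthetic_skull(skull_fixture_params(subdivision_level = 3))
  g <- igraph::graph_from_edgelist(rbind(mesh$faces[, 1:2], mesh$faces[, 2:3]),
                                   directed = FALSE)
  expect_equal(igraph::components(g)$no, 2L)

  ov <- attr(mesh, "outer_vertex_count")
  outer_faces <- mesh$faces[mesh$faces[, 1] <= ov, , drop = FALSE]
  expect_true(all(edge_face_counts(outer_faces) == 2L))
  inner_faces <- mesh$faces[mesh$faces[, 1] > ov, , drop = FALSE]
  expect_true(all(edge_face_counts(inner_faces) == 2L))

  mirrored <- mesh$vertices
  mirrored[, 1] <- -mirrored[, 1]
  nn <- skullrec:::cpp_knn(mesh$vertices, mirrored, 1L)
  expect_lt(max(nn$dist), 1e-9)
})

test_that("the jaw protrusion extends the bounding box downward", {
  no_jaw <- make_synthetic_skull(skull_fixture_params(jaw = FALSE))
  jaw <- make_synthetic_skull(skull_fixture_params(jaw = TRUE))
  expect_lt(min(jaw$vertices[, 3]), min(no_jaw$vertices[, 3]))
})

test_that("vertex count is monotone in subdivision and hits the CT-scale range", {
  counts <- vapply(2:4, function(L)
    nrow(make_synthetic_skull(skull_fixture_params(subdivision_level = L))$vertices), 0)
  expect_true(all(diff(counts) > 0))
  hi <- make_synthetic_skull(skull_fixture_params(subdivision_level = 6))
  expect_gte(nrow(hi$vertices), 250000)
  expect_lte(nrow(hi$vertices), 400000)
})

test_that("fixture generation is deterministic and validates parameters", {
  a <- make_synthetic_skull(skull_fixture_params(seed = 3))
  b <- make_synthetic_skull(skull_fixture_params(seed = 3))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_error(skull_fixture_params(inner_shell_scale = 0.97, shell_thickness = 6),
               "intersects")
  expect_error(skull_fixture_params(shell_thickness = 0), "thickness")
})

test_that("shell clouds are on-sphere with radial normals and centred", {
  cl <- make_shell_cloud(1000, 50, seed = 4)
  expect_lt(max(abs(sqrt(rowSums(cl$points^2)) - 50)), 1e-9)
  expect_lt(max(abs(rowSums(cl$normals * cl$points / 50) - 1)), 1e-9)
  # Monte-Carlo bound on the centroid over seeds: O(r / sqrt(n))
  offs <- vapply(1:20, function(s)
    sqrt(sum(colMeans(make_shell_cloud(400, 50, seed = s)$points)^2)), 0)
  expect_lt(mean(offs), 4 * 50 / sqrt(400))
})

test_that("transformed pairs carry exact ground truth", {
  cl <- make_shell_cloud(100, 10, seed = 1)
  same <- make_transformed_pair(cl)
  expect_equal(same$target$points, cl$points)
  expect_equal(same$transform$rotation, diag(3))

  rot <- make_transformed_pair(point_cloud(rbind(c(1, 0, 0))),
                               rotation = c(0, 0, pi / 2))
  expect_equal(as.numeric(rot$target$points), c(0, 1, 0), tolerance = 1e-12)

  # noise RMS per point ~ noise_sd * sqrt(3)
  rms <- vapply(1:10, function(s) {
    p <- make_transformed_pair(make_shell_cloud(500, 30, seed = s),
                               noise_sd = 0.1, seed = s + 100)
    sqrt(mean(rowSums((p$target$points - p$source$points)^2)))
  }, 0)
  expect_equal(mean(rms), 0.1 * sqrt(3), tolerance = 0.05)
})
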