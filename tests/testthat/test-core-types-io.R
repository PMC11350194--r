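test_that("hand-written ascii PLY reads with the expected counts", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 1 2", "3 0 1 3"), f)
  mesh <- read_mesh(f)
  expect_equal(nrow(mesh$vertices), 4L)
  expect_equal(nrow(mesh$faces), 2L)
})

test_that("binary STL of a unit cube welds to 8 vertices / 12 faces", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- triangle_mesh(v, f)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path, "stl")
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 8L)
  expect_equal(nrow(back$faces), 12L)
  expect_equal(mesh_area(back), mesh_area(cube), tolerance = 1e-6)
})

test_that("degenerate mesh files are rejected as format errors", {
  f <- withr::local_tempfile(fileext = ".ply")
  file.create(f)
  expect_error(read_mesh(f), "format error")
  expect_error(read_mesh(file.path(tempdir(), "no_such.ply")), "I/O error")
})

test_that("mesh write/read round-trips across formats", {
  tet <- triangle_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)),
                       rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  for (fmt in c("ply_ascii", "ply_binary", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", sub("ply_.*", "ply", fmt)))
    write_mesh(tet, path, fmt)
    back <- read_mesh(path)
    expect_equal(back$vertices, tet$vertices, tolerance = 1e-9)
    expect_equal(back$faces, tet$faces)
  }
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tet, path, "stl")
  expect_equal(mesh_area(read_mesh(path)), mesh_area(tet), tolerance = 1e-6)
})

test_that("cloud round trips preserve points and normals per format", {
  small <- point_cloud(rbind(c(0.5, -1, 2), c(3, 4, 5), c(-6, 7, 0.25)),
                       rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  pa <- withr::local_tempfile(fileext = ".ply")
  write_cloud(small, pa, "ply_ascii")
  back <- read_cloud(pa)
  expect_equal(back$points, small$points)   # %.17g round trip is exact
  expect_equal(back$normals, small$normals)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_cloud(small, xyz, "xyz")
  back <- read_cloud(xyz)
  expect_null(back$normals)
  expect_equal(back$points, small$points)

  big <- make_shell_cloud(40000, 80, seed = 5)
  pb <- withr::local_tempfile(fileext = ".ply")
  write_cloud(big, pb, "ply_binary")
  back <- read_cloud(pb)
  expect_cloud_equal(back, big, tol = 1e-6)
  expect_lt(max(abs(back$normals - big$normals)), 1e-6)
})

test_that("NaN coordinates are a format error on read", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 nan 2"), f)
  expect_error(read_cloud(f), "format error")
})

test_that("manifest round trip is the identity and schema violations name the field", {
  recs <- list(
    sample_record("a", 3, "train", seed = 1),
    sample_record("b", 4, "val", seed = 2, defect = defect_spec(c(0, 0, 0), 50, 60)),
    sample_record("c", 5, "test", seed = 3, defect = defect_spec(c(1, 2, 3), 40, 80)))
  man <- dataset_manifest(recs)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$counts, man$counts)
  expect_equal(back$records[[2]]$defect$base_side, 50)
  expect_equal(back$records[[3]]$sample_id, "c")

  expect_error(sample_record("x", 1, "train", seed = 1), "quality_score")
  expect_error(dataset_manifest(list(recs[[1]], recs[[1]])), "duplicate sample_id")
  expect_error(sample_record("y", 3, "val", seed = 1), "defect")
})

test_that("random clouds and meshes round-trip within 1e-6 mm (property)", {
  for (seed in 1:5) {
    cl <- random_cloud(200, seed, scale = 120)
    for (fmt in c("ply_ascii", "ply_binary")) {
      p <- withr::local_tempfile(fileext = ".ply")
      write_cloud(cl, p, fmt)
      expect_cloud_equal(read_cloud(p), cl, tol = 1e-6)
    }
  }
})

test_that("type invariants are enforced by constructors", {
  expect_error(point_cloud(matrix(c(1, NA, 3), 1)), "finite")
  expect_error(point_cloud(diag(3), rbind(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               "unit length")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 1, 2))), "degenerate")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "determinant")
  expect_error(landmark_set(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
  expect_warning(defect_spec(c(0, 0, 0), 20, 50), "30-100")
})
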