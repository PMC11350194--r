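test_that("the standard snapshot set has 10 views at the expected angles", {
  bounds <- rbind(c(-90, -110, -80), c(90, 110, 80))
  views <- generate_views(bounds, image_size = 256)
  expect_length(views, 10L)
  fwd <- t(vapply(views, function(v) v$rotation[3, ], numeric(3)))
  az <- fwd[1:8, ]
  expect_true(all(abs(az[, 3]) < 1e-12))
  angles <- sort(atan2(az[, 2], az[, 1]) %% (2 * pi))
  expect_equal(angles, (0:7) * pi / 4, tolerance = 1e-9)
  expect_equal(fwd[9, ], c(0, 0, -1))   # parietal looks down
  expect_equal(fwd[10, ], c(0, 0, 1))   # basilar looks up
  expect_error(generate_views(rbind(c(0, 0, 0), c(1, 1, 0))), "degenerate")
})

test_that("every fixture vertex projects inside every view frame", {
  mesh <- make_synthetic_skull(skull_fixture_params(subdivision_level = 2))
  views <- generate_views(rbind(apply(mesh$vertices, 2, min),
                                apply(mesh$vertices, 2, max)), 128)
  for (v in views) {
    cam <- sweep(mesh$vertices, 2, v$position) %*% t(v$rotation)
    expect_true(all(abs(cam[, 1]) <= v$extent[1] / 2))
    expect_true(all(abs(cam[, 2]) <= v$extent[2] / 2))
    expect_true(all(cam[, 3] > 0))   # depths positive
  }
})

test_that("depth rendering has z-buffer nearest-hit semantics", {
  # triangle parallel to the image plane of the azimuth-0 view (x forward)
  view <- generate_views(rbind(c(-10, -10, -10), c(10, 10, 10)), 64)[[1]]
  d <- sum((c(5, 0, 0) - view$position) * view$rotation[3, ])
  tri1 <- triangle_mesh(rbind(c(5, -8, -8), c(5, 8, -8), c(5, 0, 8)), rbind(1:3))
  dm <- render_depth(tri1, view)
  covered <- dm$depth[!is.na(dm$depth)]
  expect_gt(length(covered), 50)
  expect_lt(max(abs(covered - d)), 1e-6)

  # nearer triangle wins
  both <- triangle_mesh(rbind(c(5, -8, -8), c(5, 8, -8), c(5, 0, 8),
                              c(2, -8, -8), c(2, 8, -8), c(2, 0, 8)),
                        rbind(1:3, 4:6))
  d2 <- sum((c(2, 0, 0) - view$position) * view$rotation[3, ])
  dm2 <- render_depth(both, view)
  expect_lt(max(abs(dm2$depth[!is.na(dm2$depth)] - d2)), 1e-6)
})

test_that("rendered sphere depths match the analytic ray-sphere intersection", {
  r <- 50
  mesh <- make_sphere_mesh(r, 96)
  view <- generate_views(rbind(c(-r, -r, -r), c(r, r, r)), 128)[[1]]
  dm <- render_depth(mesh, view)
  H <- view$image_size[1]; W <- view$image_size[2]
  px <- view$extent[1] / W
  fg <- which(!is.na(dm$depth))
  ij <- arrayInd(fg, c(H, W))
  xc <- view$extent[1] * ((ij[, 2] - 0.5) / W - 0.5)
  yc <- view$extent[2] * ((ij[, 1] - 0.5) / H - 0.5)
  rho2 <- xc^2 + yc^2
  cam_dist <- sqrt(sum((view$position)^2))
  keep <- rho2 < (0.8 * r)^2
  analytic <- cam_dist - sqrt(r^2 - rho2[keep])
  got <- dm$depth[fg][keep]
  # facet sagitta + slope-scaled pixel footprint bound
  slope <- sqrt(rho2[keep]) / sqrt(r^2 - rho2[keep])
  sagitta <- r * (1 - cos(pi / 96))^0 * (pi * r / 96)^2 / (2 * r)
  expect_true(all(abs(got - analytic) <= px * (1 + slope) + sagitta + 1e-6))
})

test_that("back-projection is the exact inverse of rendering", {
  view <- generate_views(rbind(c(-10, -10, -10), c(10, 10, 10)), 64)[[1]]
  tri <- triangle_mesh(rbind(c(5, -8, -8), c(5, 8, -8), c(5, 0, 8)), rbind(1:3))
  dm <- render_depth(tri, view)
  cl <- backproject_depth(dm, tri)
  expect_lt(max(abs(cl$points[, 1] - 5)), 1e-6)  # all on the triangle plane x = 5
  # normals face the camera
  expect_true(all(cl$normals %*% view$rotation[3, ] < 0))

  empty <- render_depth(triangle_mesh(rbind(c(500, 0, 0), c(501, 0, 0), c(500, 1, 0)),
                                      rbind(1:3)), view)
  expect_warning(out <- backproject_depth(empty), "empty")
  expect_equal(nrow(out$points), 0L)
})

test_that("external-surface extraction suppresses the interior shell", {
  mesh <- make_synthetic_skull(skull_fixture_params(subdivision_level = 3, jaw = FALSE))
  cloud <- extract_external_surface(mesh, image_size = 256, target_points = 5000,
                                    seed = 2)
  expect_lt(abs(nrow(cloud$points) - 5000), 0.02 * 5000 + 1)
  # implicit-surface distance proxies for the two exact ellipsoid shells
  imp_dist <- function(p, radii) {
    f <- sqrt(rowSums(p^2 / matrix(radii^2, nrow(p), 3, byrow = TRUE)))
    grad <- sqrt(rowSums((p / matrix(radii^2, nrow(p), 3, byrow = TRUE))^2)) / f
    abs(f - 1) / grad
  }
  do_ <- imp_dist(cloud$points, c(90, 110, 80))
  di_ <- imp_dist(cloud$points, c(90, 110, 80) * 0.6)
  px <- 2 * sqrt(sum(c(90, 110, 80)^2)) * 1.05 / 256
  expect_gte(mean(do_ <= px), 0.99)
  expect_lte(mean(di_ < do_), 0.001)
  # extraction is deterministic given (mesh, image_size, seed)
  again <- extract_external_surface(mesh, image_size = 256, target_points = 5000,
                                    seed = 2)
  expect_identical(cloud$points, again$points)
})

test_that("Poisson-disk sampling respects the blue-noise radius and determinism", {
  cl <- make_shell_cloud(10000, 50, seed = 3)
  expect_identical(poisson_disk_sample(cl, 10000), cl)
  sub <- poisson_disk_sample(cl, 1000, seed = 1)
  expect_lt(abs(nrow(sub$points) - 1000), 21)
  d <- as.matrix(dist(sub$points))
  diag(d) <- Inf
  min_pair <- min(d)
  hex_spacing <- sqrt(2 * 4 * pi * 50^2 / (sqrt(3) * nrow(sub$points)))
  expect_gte(min_pair, 0.7 * hex_spacing / 2)
  expect_gte(min_pair, attr(sub, "radius"))
  sub2 <- poisson_disk_sample(cl, 1000, seed = 1)
  expect_identical(sub$points, sub2$points)
  expect_error(poisson_disk_sample(cl, 20000), "target larger")
})

test_that("resampling covers fps and seeded random subsets", {
  cl <- point_cloud(cbind(c(0, 1, 2, 3), 0, 0))
  expect_identical(resample(cl, 4), cl)
  two <- resample(cl, 2, method = "fps", seed = 0)  # start index 1: an end point
  expect_setequal(two$points[, 1], c(0, 3))
  big <- make_shell_cloud(500, 20, seed = 1)
  a <- resample(big, 100, method = "random", seed = 7)
  b <- resample(big, 100, method = "random", seed = 7)
  expect_identical(a$points, b$points)
  # fps matches a brute-force farthest-point recursion on a small cloud
  small <- random_cloud(40, 3, scale = 10)
  got <- skullrec:::cpp_fps(small$points, 10L, 1L)
  sel <- 1L
  for (step in 2:10) {
    dmin <- apply(small$points, 1, function(p)
      min(colSums((t(small$points[sel, , drop = FALSE]) - p)^2)))
    sel <- c(sel, which.max(dmin))
  }
  expect_equal(as.integer(got), sel)
})
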