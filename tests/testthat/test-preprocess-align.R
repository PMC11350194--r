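test_that("landmark alignment is exact on noise-free correspondences", {
  lm <- landmark_set(c(40, 60, 10), c(-40, 60, 10), c(0, -30, -60))
  expect_equal(kabsch_align(lm, lm)$rotation, diag(3), tolerance = 1e-12)

  ang <- 30 * pi / 180
  rot <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  tr <- c(5, -3, 2)
  moved <- landmark_set(rot %*% lm$matrix[1, ] + tr,
                        rot %*% lm$matrix[2, ] + tr,
                        rot %*% lm$matrix[3, ] + tr)
  fit <- kabsch_align(lm, moved)
  expect_lt(max(abs(fit$rotation - rot)), 1e-9)
  expect_lt(max(abs(fit$translation - tr)), 1e-9)
})

test_that("landmark alignment beats a rotation-grid-search oracle under noise", {
  set.seed(42)
  base <- matrix(runif(9, -60, 60), 3)
  ang <- 0.4
  rot <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  noisy <- t(rot %*% t(base)) + c(3, -1, 2) + matrix(rnorm(9, sd = 0.5), 3)
  lm_s <- landmark_set(base[1, ], base[2, ], base[3, ])
  lm_r <- landmark_set(noisy[1, ], noisy[2, ], noisy[3, ])
  fit <- kabsch_align(lm_s, lm_r)
  rms <- function(rot, src, ref) {
    # optimal translation for a fixed rotation matches the centroids
    moved <- t(rot %*% t(src))
    moved <- sweep(moved, 2, colMeans(moved) - colMeans(ref))
    sqrt(mean(rowSums((moved - ref)^2)))
  }
  fit_rms <- rms(fit$rotation, base, noisy)
  grid <- seq(0, 2 * pi, by = 0.5 * pi / 180)
  oracle <- min(vapply(grid, function(a) {
    r <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    rms(r, base, noisy)
  }, 0))
  expect_lte(fit_rms, oracle + 1e-12)
})

test_that("collinear landmarks raise a degenerate-configuration error", {
  expect_error(landmark_set(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), "collinear")
})

test_that("ICP is exact on identical clouds and recovers a pure translation", {
  sph <- make_shell_cloud(2000, 50, seed = 1)
  same <- icp_refine(sph, sph)
  expect_lt(max(abs(same$rotation - diag(3))), 1e-9)
  expect_lt(tail(attr(same, "residuals"), 1), 1e-9)

  moved <- point_cloud(sweep(sph$points, 2, c(2, 0, 0), "+"), sph$normals)
  fit <- icp_refine(moved, sph)
  expect_lt(max(abs(fit$translation - c(-2, 0, 0))), 0.01)
  expect_true(all(diff(attr(fit, "residuals")) <= 1e-12))
})

test_that("ICP recovers random small perturbations of a fixture cloud", {
  sph <- make_shell_cloud(2000, 40, seed = 2)
  for (s in 1:5) {
    set.seed(s)
    ang <- runif(3, -5, 5) * pi / 180
    tr <- runif(3, -5, 5)
    pair <- make_transformed_pair(sph, rotation = ang, translation = tr)
    fit <- icp_refine(pair$target, sph)
    back <- apply_transform(pair$target, fit)
    expect_lt(sqrt(mean(rowSums((back$points - sph$points)^2))), 0.05)
  }
})

test_that("apply_transform preserves distances and composes", {
  cl <- random_cloud(50, 9, scale = 40)
  ident <- apply_transform(cl, rigid_transform())
  expect_equal(ident$points, cl$points)

  t1 <- rigid_transform(skullrec:::euler_rotation(c(0.3, -0.2, 0.9)), c(1, 2, 3))
  t2 <- rigid_transform(skullrec:::euler_rotation(c(-0.5, 0.1, 0.2)), c(-4, 0, 7))
  step <- apply_transform(apply_transform(cl, t1), t2)
  once <- apply_transform(cl, compose_transforms(t2, t1))
  expect_equal(step$points, once$points, tolerance = 1e-12)

  d0 <- sqrt(sum((cl$points[1, ] - cl$points[2, ])^2))
  d1 <- sqrt(sum((once$points[1, ] - once$points[2, ])^2))
  expect_equal(d0, d1, tolerance = 1e-9)
})
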