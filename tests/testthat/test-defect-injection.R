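test_that("quality scores map to the documented placement regions", {
  cl <- extract_external_surface(
    make_synthetic_skull(skull_fixture_params(subdivision_level = 3)),
    image_size = 200, target_points = 4000, seed = 1)
  r3 <- region_for_quality(3)
  expect_equal(mean(skullrec:::region_mask(cl, r3)), 1)
  m4 <- skullrec:::region_mask(cl, region_for_quality(4))
  m5 <- skullrec:::region_mask(cl, region_for_quality(5))
  expect_true(sum(m5) > 0)
  expect_true(all(which(m5) %in% which(m4)))  # qs5 band inside the qs4 band
  expect_lt(sum(m5), sum(m4))
  expect_error(region_for_quality(1), "quality score")
  expect_error(region_for_quality(6), "quality score")
})

test_that("defect sampling is seeded, in-range, and uniform in size", {
  cl <- make_shell_cloud(8000, 60, seed = 1)
  region <- region_spec("whole")
  a <- sample_defect(cl, region, seed = 5)
  b <- sample_defect(cl, region, seed = 5)
  expect_identical(a, b)
  sides <- vapply(1:2000, function(s)
    sample_defect(cl, region, seed = s)$base_side, 0)
  expect_true(all(sides >= 30 & sides <= 100))
  ks <- suppressWarnings(stats::ks.test(sides, "punif", 30, 100))
  expect_gt(ks$p.value, 0.01)
  # a single qualifying point is always the chosen centre
  lone <- point_cloud(rbind(c(0, 0, 100), matrix(rnorm(300), ncol = 3)))
  top <- region_spec("top", z_lo = 0.99, z_hi = 1)
  got <- sample_defect(lone, top, seed = 3, min_points = 1)
  expect_equal(got$center, c(0, 0, 100))
  expect_error(sample_defect(cl, region_spec("empty", z_lo = 0.999, z_hi = 1,
                                             y_lo = 0.999, y_hi = 1), seed = 1),
               "region error")
})

test_that("cuboid removal matches hand counts and brute-force containment", {
  g <- as.matrix(expand.grid(x = -2:2, y = -2:2, z = -2:2)) * 10
  cl <- point_cloud(g)
  d <- suppressWarnings(defect_spec(c(0, 0, 0), 25, 25))
  pair <- apply_defect(cl, d)
  expect_equal(nrow(pair$removed$points), 27L)
  expect_equal(nrow(pair$partial$points), 98L)

  outside <- suppressWarnings(defect_spec(c(1000, 0, 0), 40, 40))
  pair2 <- apply_defect(cl, outside)
  expect_equal(nrow(pair2$removed$points), 0L)
  expect_equal(pair2$partial$points, cl$points)

  for (s in 1:5) {
    cl <- random_cloud(2000, s, scale = 80)
    d <- sample_defect(cl, region_spec("whole"), seed = s, min_points = 1)
    pair <- apply_defect(cl, d)
    inside <- abs(cl$points[, 1] - d$center[1]) <= d$base_side / 2 &
      abs(cl$points[, 2] - d$center[2]) <= d$base_side / 2 &
      abs(cl$points[, 3] - d$center[3]) <= d$height / 2
    expect_identical(pair$removed$points, cl$points[inside, , drop = FALSE])
    expect_identical(pair$partial$points, cl$points[!inside, , drop = FALSE])
    # exact partition (multiset)
    expect_equal(nrow(pair$removed$points) + nrow(pair$partial$points), 2000L)
  }
})

test_that("offline eval pairs are idempotent and follow the manifest", {
  cl <- make_shell_cloud(4000, 80, seed = 2)
  man <- dataset_manifest(list(
    sample_record("s1", 3, "val", seed = 1,
                  defect = defect_spec(c(0, 0, 70), 60, 60)),
    sample_record("s2", 3, "train", seed = 2)))
  dir1 <- withr::local_tempdir()
  files <- build_eval_set(man, list(s1 = cl, s2 = cl), dir1)
  expect_equal(nrow(files), 1L)
  h1 <- tools::md5sum(c(files$partial, files$removed))
  build_eval_set(man, list(s1 = cl, s2 = cl), dir1)
  expect_identical(tools::md5sum(c(files$partial, files$removed)), h1)
  expect_error(build_eval_set(man, list(s2 = cl), dir1), "missing clouds.*s1")
})

test_that("the online defect stream replays exactly and varies across epochs", {
  cl <- make_shell_cloud(4000, 80, seed = 3)
  gen <- online_defect_iterator(list(a = cl), c(a = 4), base_seed = 9)
  x <- gen("a", epoch = 0)
  y <- gen("a", epoch = 0)
  expect_identical(x$spec, y$spec)
  specs <- vapply(0:199, function(e) gen("a", e)$spec$base_side, 0)
  expect_gt(length(unique(specs)), 195)
  # every defect centre obeys the sample's quality region
  m4 <- skullrec:::region_mask(cl, region_for_quality(4))
  for (e in 0:10) {
    ctr <- gen("a", e)$spec$center
    idx <- which(apply(cl$points, 1, function(p) all(p == ctr)))
    expect_true(any(m4[idx]))
  }
})
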