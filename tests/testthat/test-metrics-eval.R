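test_that("metric hand examples hold", {
  a <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
  b <- point_cloud(rbind(c(0, 0, 0)))
  expect_equal(accuracy(a, a), 0)
  expect_equal(accuracy(a, b), 0.5)
  expect_equal(completeness(a, b), 0)
  expect_equal(chamfer(a, b), 0.5)
  expect_equal(chamfer(a, a), 0)

  p <- point_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  q <- point_cloud(rbind(c(1, 0, 0), c(3, 0, 0)))
  expect_equal(emd(p, q)$emd_mm, 1.0)
  expect_equal(emd(p, p)$emd_mm, 0)

  gt <- point_cloud(rbind(c(0, 0, 0)))
  rec <- point_cloud(rbind(c(0, 0, 0), c(10, 0, 0)))
  prf <- precision_recall_fscore(gt, rec, tau = 3)
  expect_equal(prf$precision, 0.5)
  expect_equal(prf$recall, 1)
  expect_equal(prf$fscore, 2 / 3)
  same <- precision_recall_fscore(gt, gt, tau = 0.1)
  expect_equal(same$fscore, 1)
  expect_error(accuracy(point_cloud(matrix(numeric(0), ncol = 3)), a), "non-empty")
})

test_that("definitional symmetries hold on random clouds", {
  for (s in 1:5) {
    A <- random_cloud(80, s); B <- random_cloud(60, s + 50)
    expect_equal(completeness(A, B), accuracy(B, A), tolerance = 1e-12)
    expect_equal(chamfer(A, B), chamfer(B, A), tolerance = 1e-12)
    expect_gte(accuracy(A, B), 0)
    # F-score non-decreasing in tau
    taus <- c(1, 5, 20, 80, 200)
    fs <- vapply(taus, function(t) precision_recall_fscore(A, B, t)$fscore, 0)
    expect_true(all(diff(fs) >= 0))
  }
})

test_that("EMD equals the exhaustive-permutation optimum on tiny clouds", {
  for (s in 1:10) {
    n <- 2 + (s %% 6)
    P <- random_cloud(n, s, scale = 10)
    Q <- random_cloud(n, s + 100, scale = 10)
    expect_equal(emd(P, Q)$emd_mm, brute_emd(P$points, Q$points), tolerance = 1e-9)
  }
  # permutation invariance: a shuffled copy matches at zero
  P <- random_cloud(30, 1)
  perm <- point_cloud(P$points[sample.int(30), , drop = FALSE])
  expect_equal(emd(P, perm)$emd_mm, 0, tolerance = 1e-12)
})

test_that("the EMD matching is a bijection and its mean equals the value", {
  P <- random_cloud(40, 2); Q <- random_cloud(55, 3)
  r <- emd(P, Q, seed = 4)
  expect_equal(r$n, 40)
  expect_setequal(r$matching, seq_len(40))
})

test_that("evaluation de-normalizes, restricts to the region, and flags empties", {
  cl <- make_shell_cloud(6000, 80, seed = 6)
  d <- defect_spec(c(0, 0, 70), 60, 60)
  pair <- apply_defect(cl, d)
  norm <- normalize_pair(pair$partial, complete = cl, m = 155)
  # oracle backend: the normalized ground-truth complete cloud
  rep <- evaluate_reconstruction(pair$removed, norm$complete, d, norm$params,
                                 emd_max_points = 256)
  expect_equal(rep$accuracy_mm, 0, tolerance = 1e-9)
  expect_equal(rep$completeness_mm, 0, tolerance = 1e-9)
  expect_equal(rep$fscore, 1)
  expect_equal(rep$chamfer_mm, rep$accuracy_mm + rep$completeness_mm)

  # passthrough leaves the region empty
  rep2 <- evaluate_reconstruction(pair$removed, norm$partial, d, norm$params)
  expect_true(rep2$empty_region)
  expect_equal(rep2$fscore, 0)
  expect_true(is.infinite(rep2$accuracy_mm))

  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep2, f)
  back <- read_metrics_report(f)
  expect_true(is.infinite(back$accuracy_mm))
  expect_equal(back$fscore, 0)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, f2)
  back2 <- read_metrics_report(f2)
  expect_equal(back2$emd_mm, rep$emd_mm, tolerance = 1e-12)
})
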