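# Surface error metrics, the voxel criterion, normality and summaries.

test_that("identical meshes give zero error in both directions", {
  m <- random_test_mesh(subdiv = 1, seed = 6)
  for (dir in c("symmetric", "one_sided")) {
    r <- surface_error_report(m, m, direction = dir)
    expect_equal(c(r$rmse, r$asd, r$hd), c(0, 0, 0))
  }
})

test_that("a parallel offset plane yields RMSE = ASD = HD exactly", {
  patch <- mesh_flat_patch(6, 6, 1)
  lifted <- patch
  lifted$vertices[, 3] <- 1.5      # one slice thickness away
  for (dir in c("symmetric", "one_sided")) {
    r <- surface_error_report(lifted, patch, direction = dir)
    expect_equal(r$rmse, 1.5)
    expect_equal(r$asd, 1.5)
    expect_equal(r$hd, 1.5)
  }
})

test_that("error metrics match the exhaustive distance oracle", {
  for (s in 1:3) {
    a <- random_test_mesh(subdiv = 1, seed = s)          # 80 faces
    b <- random_test_mesh(subdiv = 1, seed = s + 10)
    b$vertices <- b$vertices + 0.5
    r <- surface_error_report(a, b, direction = "symmetric")
    d_ab <- brute_force_surface_distance(a$vertices, b)
    d_ba <- brute_force_surface_distance(b$vertices, a)
    dset <- c(d_ab, d_ba)
    expect_equal(r$rmse, sqrt(mean(dset^2)), tolerance = 1e-9)
    expect_equal(r$asd, mean(dset), tolerance = 1e-9)
    expect_equal(r$hd, max(dset), tolerance = 1e-9)
    expect_equal(r$per_point_errors, d_ab, tolerance = 1e-9)
  }
})

test_that("metric ordering and direction relations hold", {
  for (s in 1:5) {
    a <- random_test_mesh(subdiv = 1, seed = s)
    b <- random_test_mesh(subdiv = 1, seed = s + 20)
    sym <- surface_error_report(a, b)
    one <- surface_error_report(a, b, direction = "one_sided")
    one_rev <- surface_error_report(b, a, direction = "one_sided")
    for (r in list(sym, one, one_rev)) {
      expect_lte(r$asd, r$rmse + 1e-12)
      expect_lte(r$rmse, r$hd + 1e-12)
    }
    expect_gte(sym$hd + 1e-12, one$hd)
    expect_gte(sym$hd + 1e-12, one_rev$hd)
    expect_equal(one$hd, max(one$per_point_errors))
  }
})

test_that("error metrics are invariant under joint rigid transforms", {
  a <- random_test_mesh(subdiv = 1, seed = 2)
  b <- random_test_mesh(subdiv = 1, seed = 30)
  r0 <- surface_error_report(a, b)
  tr <- random_rigid_transform(4)
  r1 <- surface_error_report(apply_transform(a, tr), apply_transform(b, tr))
  expect_equal(c(r1$rmse, r1$asd, r1$hd), c(r0$rmse, r0$asd, r0$hd),
               tolerance = 1e-9)
})

test_that("the voxel criterion compares ASD to the largest dimension", {
  mk <- function(asd) structure(list(rmse = asd, asd = asd, hd = asd,
                                     per_point_errors = asd,
                                     direction = "symmetric"),
                                class = "surface_error_report")
  voxel <- c(0.3571, 0.3571, 1.5)
  chk <- voxel_accuracy_check(mk(0.70), voxel)
  expect_true(chk$pass)
  expect_equal(chk$margin, 0.80)
  expect_false(voxel_accuracy_check(mk(1.6), voxel)$pass)
  chk0 <- voxel_accuracy_check(mk(0), voxel)
  expect_true(chk0$pass)
  expect_equal(chk0$margin, 1.5)
  expect_error(voxel_accuracy_check(mk(1), c(1, -1, 1)), "positive")
})

test_that("mean point error maps average corresponded vectors", {
  v <- stats::runif(40)
  expect_equal(mean_point_error_map(list(v, v, v)), v)
  c_ <- 0.7
  expect_equal(mean_point_error_map(list(v, -v + 2 * c_)), rep(c_, 40))
  expect_error(mean_point_error_map(list(v, v[-1])), "shared topology")

  # generator-noise vectors: the mean stays within the CLT band
  set.seed(99)
  sigma <- 0.3571
  errs <- lapply(1:11, function(i) abs(rnorm(60, 0, sigma)))
  mu <- mean_point_error_map(errs)
  folded_mean <- sigma * sqrt(2 / pi)
  folded_sd <- sigma * sqrt(1 - 2 / pi)
  expect_true(all(abs(mu - folded_mean) < 3 * folded_sd / sqrt(11) + 0.05))
})

test_that("Shapiro-Wilk wrapper matches its contract", {
  set.seed(4)
  x <- rnorm(44)
  r <- shapiro_wilk(x)
  ref <- stats::shapiro.test(x)
  expect_equal(r$W, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_identical(r$reject, ref$p.value < 0.05)

  set.seed(8)
  u <- runif(100)
  expect_true(shapiro_wilk(u)$reject)

  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("median and range summaries are standard", {
  expect_equal(median_range_summary(c(1, 2, 3)),
               list(median = 2, min = 1, max = 3))
  expect_equal(median_range_summary(c(1, 2, 3, 4)),
               list(median = 2.5, min = 1, max = 4))
  expect_equal(median_range_summary(7), list(median = 7, min = 7, max = 7))
  expect_error(median_range_summary(numeric(0)), "empty")
})
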