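test_that("whitening contract: transformed pooled covariance is identity", {
  set.seed(41)
  tg <- make_two_groups(n_per = 150, p = 6, shift = 1, seed = 41)
  # correlate the features
  A <- matrix(rnorm(36), 6); x <- tg$x %*% A
  space <- fit_drf_space(x, tg$groups, shrinkage = 0)
  y <- drf_transform(space, x)
  resid <- y - apply(y, 2, function(col) ave(col, tg$groups))
  pooled <- crossprod(resid) / nrow(y)
  expect_lt(max(abs(pooled - diag(6))), 1e-6)
})

test_that("component ranking matches a brute-force separation ordering", {
  set.seed(43)
  n <- 60
  # five independent features with known group separations
  seps <- c(0, 3, 1, 5, 0.3)
  g <- rep(c(0, 1), each = n / 2)
  x <- sapply(seps, function(s) rnorm(n) + s * g)
  space <- fit_drf_space(x, factor(g), shrinkage = 0)
  y <- drf_transform(space, x)
  # brute force: per-component two-sample standardised mean difference
  smd <- apply(y, 2, function(col) {
    a <- col[g == 0]; b <- col[g == 1]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    abs(mean(a) - mean(b)) / sp
  })
  expect_equal(order(smd, decreasing = TRUE), seq_along(seps))
  # and the top-ranked component should align with the largest true gap
  expect_gt(smd[1], smd[2])
})

test_that("fit_drf_space validates inputs", {
  tg <- make_two_groups(n_per = 10, p = 4)
  expect_error(fit_drf_space(tg$x, tg$groups, k = 9), "exceeds")
  expect_error(fit_drf_space(tg$x, rep("a", 20)), "2 groups")
  expect_error(fit_drf_space(tg$x, rep(c("a", "b", "c"), c(18, 1, 1))),
               ">= 3 subjects")
  # duplicated feature makes the covariance singular without shrinkage
  xx <- cbind(tg$x, tg$x[, 1])
  expect_error(fit_drf_space(xx, tg$groups, shrinkage = 0), "singular")
  expect_s3_class(fit_drf_space(xx, tg$groups), "drf_space")
})

test_that("identical clouds give exactly 50", {
  set.seed(47)
  cl <- fit_cloud(matrix(rnorm(60), 20), "g")
  expect_identical(discrimination_index(cl, cl), 50)
})

test_that("index matches the closed form for equal spherical covariances", {
  k <- 3
  for (d in c(0.5, 1, 2, 4, 8)) {
    a <- structure(list(label = "a", mean = rep(0, k), cov = diag(k), n = 10),
                   class = "drfa_cloud")
    b <- structure(list(label = "b", mean = c(d, rep(0, k - 1)),
                        cov = diag(k), n = 10),
                   class = "drfa_cloud")
    expect_equal(discrimination_index(a, b),
                 50 + 50 * (1 - exp(-d^2 / 8)), tolerance = 1e-10)
  }
})

test_that("index is symmetric, bounded, and monotone in separation", {
  set.seed(53)
  last <- 50
  for (d in c(0, 0.5, 1, 2, 5, 20)) {
    a <- fit_cloud(matrix(rnorm(90), 30), "a")
    bmat <- matrix(rnorm(90), 30); bmat[, 1] <- bmat[, 1] + d
    b <- fit_cloud(bmat, "b")
    idx <- discrimination_index(a, b)
    expect_equal(idx, discrimination_index(b, a))
    expect_gte(idx, 50); expect_lte(idx, 100)
  }
  # monotone nondecreasing in mean separation at fixed covariance
  base <- fit_cloud(matrix(rnorm(90), 30), "a")
  idxs <- sapply(c(0, 0.5, 1, 2, 4), function(d) {
    shifted <- base; shifted$mean <- base$mean + c(d, 0, 0)
    discrimination_index(base, shifted)
  })
  expect_true(all(diff(idxs) >= 0))
})

test_that("widely separated groups are scored at (almost exactly) 100", {
  tg <- make_two_groups(n_per = 30, p = 5, shift = 50, seed = 59)
  space <- fit_drf_space(tg$x, tg$groups)
  y <- drf_transform(space, tg$x)
  a <- fit_cloud(y[tg$groups == "a", ], "a")
  b <- fit_cloud(y[tg$groups == "b", ], "b")
  expect_equal(discrimination_index(a, b), 100, tolerance = 0.5)
})

test_that("permutation p-values behave under null and strong separation", {
  # strong separation: observed index beats every permutation
  tg <- make_two_groups(n_per = 30, p = 5, shift = 50, seed = 61)
  d <- permutation_pvalue(tg$x, tg$groups, n_perm = 99, seed = 1)
  expect_equal(d$pvalue, 1 / 100)
  expect_error(permutation_pvalue(tg$x, tg$groups, n_perm = 0), "n_perm")
  # identical groups: p is typically large
  ps <- sapply(1:10, function(s) {
    tg0 <- make_two_groups(n_per = 12, p = 4, shift = 0, seed = 100 + s)
    permutation_pvalue(tg0$x, tg0$groups, n_perm = 60, seed = s)$pvalue
  })
  expect_gt(median(ps), 0.3)
})

test_that("permutation p at two resolutions agrees within binomial error", {
  tg <- make_two_groups(n_per = 15, p = 4, shift = 0.85, seed = 67)
  p1 <- permutation_pvalue(tg$x, tg$groups, n_perm = 400, seed = 2)$pvalue
  p2 <- permutation_pvalue(tg$x, tg$groups, n_perm = 2000, seed = 3)$pvalue
  se <- sqrt(p2 * (1 - p2) / 400)
  expect_lt(abs(p1 - p2), 3 * se + 1 / 400)
})

test_that("null permutation p-values are super-uniform", {
  n_null <- 150; n_perm <- 60
  ps <- sapply(seq_len(n_null), function(s) {
    tg <- make_two_groups(n_per = 12, p = 4, shift = 0, seed = 1000 + s)
    permutation_pvalue(tg$x, tg$groups, n_perm = n_perm, seed = s)$pvalue
  })
  # super-uniformity: P(p <= t) <= t, allowing 3 binomial SDs and the
  # 1/(n_perm + 1) resolution of the add-one estimator
  for (t in c(0.1, 0.25, 0.5)) {
    bound <- t + 3 * sqrt(t * (1 - t) / n_null) + 1 / (n_perm + 1)
    expect_lte(mean(ps <= t), bound)
  }
})

test_that("projection and rescue scores anchor at the reference clouds", {
  set.seed(71)
  n <- 30; p <- 6
  xd <- matrix(rnorm(n * p), n)                 # disease
  xc <- matrix(rnorm(n * p), n); xc[, 1:2] <- xc[, 1:2] + 4  # control
  x <- rbind(xd, xc)
  g <- factor(rep(c("dis", "ctl"), each = n))
  space <- fit_drf_space(x, g)
  y <- drf_transform(space, x)
  dcl <- fit_cloud(y[g == "dis", ], "dis")
  ccl <- fit_cloud(y[g == "ctl", ], "ctl")

  # a group drawn from the disease distribution projects onto it
  # (100 subjects so the sample mean offset stays small)
  set.seed(72)
  lowered <- matrix(rnorm(100 * p), 100)
  pr <- project_group(space, list(dis = dcl, ctl = ccl), lowered)
  expect_lt(pr$indices[["dis"]], 60)
  expect_gt(pr$indices[["ctl"]], 95)
  expect_lt(pr$distances[["dis"]], pr$distances[["ctl"]])
  expect_error(project_group(space, list(dis = dcl), matrix(0, 3, 2)),
               "feature count")

  # rescue anchors: disease mean -> 0, control mean -> 100, midpoint -> 50
  expect_equal(rescue_score(space, dcl, ccl, rbind(colMeans(xd))), 0,
               tolerance = 1e-8)
  expect_equal(rescue_score(space, dcl, ccl, rbind(colMeans(xc))), 100,
               tolerance = 1e-8)
  expect_equal(rescue_score(space, dcl, ccl,
                            rbind((colMeans(xd) + colMeans(xc)) / 2)), 50,
               tolerance = 1e-8)
  # an intermediate mixture lands strictly between the anchors
  mix <- 0.3 * colMeans(xc) + 0.7 * colMeans(xd)
  sc <- rescue_score(space, dcl, ccl, rbind(mix))
  expect_gt(sc, 5); expect_lt(sc, 95)
  expect_equal(sc, 30, tolerance = 1e-6)
  same <- dcl; same$mean <- ccl$mean
  expect_error(rescue_score(space, ccl, same, lowered), "coincide")
})
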