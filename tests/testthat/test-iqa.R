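# The no-reference metric suite against closed forms and independent
# brute-force oracles.

test_that("global contrast factor: constant image, checkerboard, dual oracle", {
  expect_identical(gcf(matrix(-0.2, 32, 32)), 0)
  # 1-px checkerboard: luminance 0/1, mean |difference| to 4-neighbours is 1
  ch <- outer(1:16, 1:16, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  l <- ((ch + 1) / 2 * 255 / 255)^2.2
  expect_equal(octsr:::local_contrast(l), 1)
  set.seed(21)
  for (i in 1:5) {
    img <- matrix(runif(64 * 64, -1, 1), 64, 64)
    expect_lt(abs(gcf(img) - gcf_oracle(img)), 1e-9)
  }
  # non-square and odd sizes agree too (block truncation convention)
  img <- matrix(runif(37 * 53, -1, 1), 37, 53)
  expect_lt(abs(gcf(img) - gcf_oracle(img)), 1e-9)
  expect_error(gcf(matrix(numeric(0), 0, 0)), "empty")
})

test_that("fast noise estimation: exact zeros and Gaussian recovery", {
  expect_lt(fne(matrix(0.4, 16, 16)), 1e-14)
  ramp <- outer(seq(-1, 1, length.out = 24), seq(-0.5, 0.5, length.out = 24), "+") / 2
  expect_lt(fne(ramp), 1e-12)
  set.seed(22)
  est <- vapply(1:10, function(i) fne(matrix(rnorm(256 * 256, sd = 0.1), 256, 256)),
                numeric(1))
  expect_gt(mean(est), 0.097)
  expect_lt(mean(est), 0.103)
  expect_error(fne(matrix(0, 2, 2)), "3x3")
})

test_that("embedding is deterministic, fixed-width and row-aligned", {
  set.seed(23)
  imgs <- lapply(1:4, function(i) matrix(runif(32 * 24, -1, 1), 32, 24))
  e1 <- embedImages(imgs)
  e2 <- embedImages(imgs)
  expect_identical(e1, e2)
  expect_identical(nrow(e1), 4L)
  ep <- embedImages(imgs[c(3, 1, 4, 2)])
  expect_equal(ep, e1[c(3, 1, 4, 2), ], ignore_attr = TRUE)
})

test_that("Frechet distance matches its closed form on Gaussians", {
  set.seed(24)
  X <- matrix(rnorm(200 * 4), 200, 4)
  expect_lt(abs(fid(X, X)), 1e-6)
  # mean offset delta along one axis, unit covariances: FID -> delta^2
  n <- 5000
  A <- matrix(rnorm(n * 4), n, 4)
  B <- matrix(rnorm(n * 4), n, 4); B[, 1] <- B[, 1] + 2
  expect_lt(abs(fid(A, B) - 4), 0.15)
  # general analytic case
  Sg <- diag(c(2, 1, 0.5, 1))
  mu <- c(1, -1, 0.5, 0)
  G <- sweep(matrix(rnorm(n * 4), n, 4) %*% diag(sqrt(diag(Sg))), 2, mu, "+")
  analytic <- sum(mu^2) + 4 + sum(diag(Sg)) - 2 * sum(sqrt(diag(Sg)))
  expect_lt(abs(fid(A, G) - analytic), 0.2)
  expect_warning(fid(matrix(rnorm(6), 3, 2) %*% matrix(1, 2, 5),
                     matrix(rnorm(15), 3, 5)), "degenerate")
})

# unbiased MMD^2 with the polynomial kernel, naive double loops
kid_oracle <- function(X, Y) {
  d <- ncol(X); m <- nrow(X); n <- nrow(Y)
  kf <- function(a, b) (sum(a * b) / d + 1)^3
  sxx <- 0; for (i in 1:m) for (j in 1:m) if (i != j) sxx <- sxx + kf(X[i, ], X[j, ])
  syy <- 0; for (i in 1:n) for (j in 1:n) if (i != j) syy <- syy + kf(Y[i, ], Y[j, ])
  sxy <- 0; for (i in 1:m) for (j in 1:n) sxy <- sxy + kf(X[i, ], Y[j, ])
  sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
}

test_that("kernel distance: kernel value, brute-force oracle, null behaviour", {
  expect_identical(octsr:::poly_kernel(matrix(1), matrix(1))[1, 1], 8)
  set.seed(25)
  X <- matrix(rnorm(12 * 3), 12, 3)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  expect_lt(abs(kid(X, Y, subsetSize = 100L, nSubsets = 1L) - kid_oracle(X, Y)),
            1e-9)
  # two halves of one sample: KID within 3x the subset-spread standard error
  Z <- matrix(rnorm(400 * 5), 400, 5)
  A <- Z[1:200, ]; B <- Z[201:400, ]
  reps <- vapply(1:20, function(s) kid(A, B, subsetSize = 50L, nSubsets = 1L,
                                       seed = s), numeric(1))
  expect_lt(abs(kid(A, B, subsetSize = 50L, nSubsets = 20L, seed = 99)),
            3 * sd(reps) / sqrt(20) + 3 * sd(reps))
  expect_error(kid(X[1:1, , drop = FALSE], Y[1:1, , drop = FALSE]), "at least 2")
})

# exhaustive ball-membership enumeration for the manifold metrics
pr_oracle <- function(R, G, k) {
  # kth smallest distance excluding self
  radii <- function(X) {
    D <- as.matrix(dist(X)); diag(D) <- Inf
    apply(D, 1, function(r) sort(r)[k])
  }
  rr <- radii(R); rg <- radii(G)
  inball <- function(P, Q, rq) vapply(seq_len(nrow(P)), function(i)
    any(sqrt(colSums((t(Q) - P[i, ])^2)) <= rq), logical(1))
  c(precision = mean(inball(G, R, rr)), recall = mean(inball(R, G, rg)))
}

dc_oracle <- function(R, G, k) {
  D <- as.matrix(dist(R)); diag(D) <- Inf
  rr <- apply(D, 1, function(r) sort(r)[k])
  cnt <- 0; covered <- logical(nrow(R))
  for (gi in seq_len(nrow(G))) for (ri in seq_len(nrow(R))) {
    d <- sqrt(sum((G[gi, ] - R[ri, ])^2))
    if (d <= rr[ri]) { cnt <- cnt + 1; covered[ri] <- TRUE }
  }
  c(density = cnt / (k * nrow(G)), coverage = mean(covered))
}

test_that("precision/recall and density/coverage match exhaustive enumeration", {
  set.seed(26)
  expect_identical(precisionRecall(runit(10, 2) * 3, runit(10, 2) * 3 * 0 + 100, 3L),
                   c(precision = 0, recall = 0))
  R <- matrix(rnorm(14 * 2), 14, 2)
  expect_identical(unname(precisionRecall(R, R, 3L)), c(1, 1))
  expect_identical(unname(densityCoverage(R, R, 5L)["coverage"]), 1)
  for (i in 1:5) {
    R <- matrix(rnorm(12 * 2), 12, 2)
    G <- matrix(rnorm(15 * 2, sd = 1.3), 15, 2)
    expect_equal(precisionRecall(R, G, 3L), pr_oracle(R, G, 3L), tolerance = 1e-12)
    expect_equal(densityCoverage(R, G, 4L), dc_oracle(R, G, 4L), tolerance = 1e-12)
  }
  expect_error(precisionRecall(R[1:3, ], R, 3L), "smaller")
})

test_that("full-reference metrics behave at the identity and under noise", {
  set.seed(27)
  x <- matrix(runif(40 * 40, -1, 1), 40, 40)
  expect_identical(psnr(x, x), Inf)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  y <- pmin(pmax(x + rnorm(1600, sd = 0.1), -1), 1)
  expect_lt(ssim(x, y), 1)
  expect_gt(ssim(x, y), ssim(x, pmin(pmax(x + rnorm(1600, sd = 0.4), -1), 1)))
})

test_that("directory evaluation is a faithful self-comparison at identity", {
  spec <- tiny_spec()
  d <- withr::local_tempdir()
  dir.create(file.path(d, "set"))
  for (i in 1:8)
    writeFrameImage(simulateRetinaPhantom(spec, seed = 40 + i),
                    file.path(d, "set", sprintf("img_%02d.tif", i)))
  rep <- suppressWarnings(evaluateSets(file.path(d, "set"), file.path(d, "set"),
                                       out = file.path(d, "report")))
  expect_lt(rep@fid, 1e-6)
  # the unbiased MMD^2 estimator carries an O(1/n) self-pair bias at identity
  expect_lt(abs(rep@kid), 1e-2)
  expect_identical(rep@absDeltaGCF, 0)
  expect_identical(rep@absDeltaFNE, 0)
  expect_identical(c(rep@precision, rep@recall, rep@coverage), c(1, 1, 1))
  expect_true(file.exists(file.path(d, "report.json")))
  expect_true(file.exists(file.path(d, "report.csv")))
})
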