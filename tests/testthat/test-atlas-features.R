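test_that("correlation matches closed forms and an independent oracle", {
  expect_equal(fc_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  expect_equal(fc_correlation(c(1, 2, 3, 4), c(-1, -2, -3, -4)), -1.0)
  # frozen value computed with the separately coded covariance/sd formula
  expect_equal(oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(fc_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(41)
  for (i in 1:20) {
    u <- rnorm(15); v <- rnorm(15)
    expect_equal(fc_correlation(u, v), oracle_pearson(u, v), tolerance = 1e-12)
  }
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(42)
  for (i in 1:25) {
    u <- rnorm(20); v <- rnorm(20)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    c_ <- runif(1, 0.1, 5); d <- rnorm(1)
    expect_equal(fc_correlation(a * u + b, c_ * v + d),
                 fc_correlation(u, v), tolerance = 1e-10)
  }
})

test_that("zero-variance input yields 0 with a warning, never NaN", {
  expect_warning(r <- fc_correlation(rep(2, 5), rnorm(5)), "zero-variance")
  expect_identical(r, 0)
  expect_error(fc_correlation(1, 1), "at least 2")
  expect_error(fc_correlation(1:3, 1:4), "equal length")
})

test_that("feature count follows the pairwise identity", {
  expect_identical(feature_count(116), 6670L)
  expect_identical(feature_count(200), 19900L)
  expect_identical(feature_count(111), 6105L)
  expect_identical(feature_count(2), 1L)
  expect_error(feature_count(1), "invalid atlas")
  for (n in 2:300) expect_identical(feature_count(n), as.integer(choose(n, 2)))
  a <- atlas_spec("AAL", 116)
  expect_identical(a$feature_dim, 6670L)
  expect_error(atlas_spec("X", 1), "invalid atlas")
})

test_that("connectivity matrix agrees with the brute-force pairwise oracle", {
  set.seed(7)
  x <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  expect_equal(unname(connectivity_matrix(x)), matrix(1, 2, 2))
  # orthogonal mean-zero columns: zero off-diagonals
  x2 <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(unname(connectivity_matrix(x2)), diag(2))
  for (i in 1:10) {
    x3 <- matrix(rnorm(5 * 30), 30, 5)
    m <- connectivity_matrix(x3)
    bf <- diag(5)
    for (a in 1:5) for (b in 1:5) bf[a, b] <- oracle_pearson(x3[, a], x3[, b])
    expect_lt(max(abs(m - unname(bf))), 1e-10)
    expect_equal(m, t(m))
  }
})

test_that("constant ROI columns are zeroed with an informative warning", {
  x <- cbind(rnorm(10), rep(3, 10), rnorm(10))
  expect_warning(m <- connectivity_matrix(x), "column\\(s\\) 2")
  expect_true(all(m[2, ] == 0) && all(m[, 2] == 0))
  expect_equal(diag(m), c(1, 0, 1))
})

test_that("lower-triangle vectorization uses row-major pair order", {
  m2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(vectorize_lower_triangle(m2), 0.5)
  m3 <- diag(3)
  m3[2, 1] <- m3[1, 2] <- 0.1  # a = (2,1)
  m3[3, 1] <- m3[1, 3] <- 0.2  # b = (3,1)
  m3[3, 2] <- m3[2, 3] <- 0.3  # c = (3,2)
  expect_equal(vectorize_lower_triangle(m3), c(0.1, 0.2, 0.3))
  # enumeration oracle on a random symmetric 4x4
  m4 <- random_symmetric(4, seed = 3)
  want <- c()
  for (i in 2:4) for (j in 1:(i - 1)) want <- c(want, m4[i, j])
  expect_equal(vectorize_lower_triangle(m4), want)
  expect_length(want, 6L)
  expect_error(vectorize_lower_triangle(matrix(1, 2, 3)), "square")
})

test_that("vectorization round-trips through reconstruction exactly", {
  for (n in c(2, 5, 9)) {
    m <- random_symmetric(n, seed = n)
    v <- vectorize_lower_triangle(m)
    expect_length(v, feature_count(n))
    back <- unvectorize_lower_triangle(v, n)
    off <- m; diag(off) <- 1
    expect_identical(back, off)
  }
})

test_that("view feature tables have one row per subject in cohort order", {
  atlas <- atlas_spec("TOY", 5)
  set.seed(11)
  mk <- function(id) roi_timeseries(id, atlas, matrix(rnorm(100), 20, 5))
  cohort <- list(mk("s1"), mk("s2"), mk("s3"))
  x <- build_view_features(cohort, atlas)
  expect_identical(dim(x), c(3L, 10L))
  expect_identical(rownames(x), c("s1", "s2", "s3"))
  expect_equal(x["s2", ],
               setNames(vectorize_lower_triangle(connectivity_matrix(cohort[[2]])),
                        colnames(x)))
  # empty cohort keeps the feature dimension
  e <- build_view_features(list(), atlas)
  expect_identical(dim(e), c(0L, 10L))
  # identical subjects give identical rows
  twin <- list(mk("a"), mk("a"))
  twin[[2]]$data <- twin[[1]]$data
  xt <- build_view_features(twin, atlas)
  expect_identical(xt[1, ], xt[2, ])
  # mixed atlases rejected
  other <- roi_timeseries("s4", atlas_spec("OTHER", 6), matrix(rnorm(120), 20, 6))
  expect_error(build_view_features(list(mk("s1"), other), atlas), "atlas")
})

test_that("time-series container enforces its invariants", {
  atlas <- atlas_spec("TOY", 4)
  expect_error(roi_timeseries("s", atlas, matrix(1, 10, 3)), "4 ROIs")
  expect_error(roi_timeseries("s", atlas, matrix(1, 1, 4)), "2 time points")
  bad <- matrix(rnorm(40), 10, 4); bad[3, 2] <- NA
  expect_error(roi_timeseries("s", atlas, bad), "missing values")
})
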