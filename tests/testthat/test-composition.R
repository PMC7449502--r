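test_that("closure normalizes to the simplex and is idempotent", {
  expect_equal(close_composition(c(1, 1, 1, 1, 1)), rep(0.2, 5))
  v <- c(83.4, 1.1, 2.7, 2.5, 2.0)
  expect_equal(close_composition(v), v / 91.7)
  expect_equal(close_composition(rep(0.2, 5)), rep(0.2, 5))
  expect_error(close_composition(rep(0, 5)), "all-zero")
  m <- matrix(runif(20, 0.1, 5), 4, 5)
  expect_equal(rowSums(close_composition(m)), rep(1, 4))
})

test_that("multiplicative zero replacement preserves closure and non-zero ratios", {
  out <- replace_zeros(c(1, 0, 0, 0, 0), delta = 0.001)
  expect_equal(out, c(0.996, 0.001, 0.001, 0.001, 0.001))
  x <- close_composition(c(5, 3, 2, 1, 4))
  expect_identical(replace_zeros(x), x)
  expect_error(replace_zeros(c(1, 0, 0, 0, 0), delta = 0), "positive")
  expect_error(replace_zeros(close_composition(c(10, 1, 0, 5, 4)),
                             delta = 0.5), "smallest non-zero")
  y <- replace_zeros(close_composition(c(10, 1, 0, 5, 4)))
  expect_equal(sum(y), 1, tolerance = 1e-12)
  expect_true(all(y > 0))
  expect_equal(y[1] / y[2], 10, tolerance = 1e-12)  # non-zero ratios kept
})

test_that("the ilr basis is orthonormal with zero-sum rows", {
  for (D in 2:6) {
    V <- ilr_basis(D)
    expect_equal(unname(V %*% t(V)), diag(D - 1), tolerance = 1e-12)
    expect_equal(unname(rowSums(V)), rep(0, D - 1), tolerance = 1e-12)
  }
})

test_that("the two-part coordinate reduces to the scaled log-odds", {
  for (p in c(0.1, 0.35, 0.8)) {
    expect_equal(unname(ilr(c(p, 1 - p))), log(p / (1 - p)) / sqrt(2),
                 tolerance = 1e-12)
  }
})

test_that("ilr maps equal parts to the origin and round-trips the simplex", {
  expect_equal(unname(ilr(rep(0.2, 5))), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(ilr_inv(rep(0, 4))), rep(0.2, 5), tolerance = 1e-12)
  comps <- random_compositions(100, seed = 42)
  for (i in seq_len(nrow(comps))) {
    expect_equal(unname(ilr_inv(ilr(comps[i, ]))), comps[i, ],
                 tolerance = 1e-9)
  }
  set.seed(43)
  for (i in 1:100) {
    z <- rnorm(4, 0, 2)
    expect_equal(unname(ilr(ilr_inv(z))), z, tolerance = 1e-9)
  }
})

test_that("ilr rejects non-positive parts, naming the class", {
  x <- c(lymphocytes = 0.5, monocytes = 0, eosinophils = 0.2,
         heterophils = 0.2, basophils = 0.1)
  expect_error(ilr(x), "monocytes")
  expect_error(ilr_inv(c(0, NA, 0, 0)), "finite")
})

test_that("a large coordinate concentrates mass on its leading parts while staying closed", {
  x <- ilr_inv(c(50, 0, 0, 0))
  expect_equal(sum(x), 1, tolerance = 1e-12)
  expect_gt(x[[1]], 1 - 1e-9)
})

test_that("ilr is an isometry for the Aitchison metric", {
  a <- random_compositions(30, seed = 7)
  b <- random_compositions(30, seed = 8)
  for (i in seq_len(nrow(a))) {
    d_ait <- aitchison_dist(a[i, ], b[i, ])
    d_ilr <- sqrt(sum((ilr(a[i, ]) - ilr(b[i, ]))^2))
    expect_equal(d_ilr, d_ait, tolerance = 1e-10)
  }
})

test_that("consistently permuting parts and basis columns preserves coordinate norms", {
  set.seed(9)
  V <- ilr_basis(5)
  for (i in 1:20) {
    x <- as.numeric(random_compositions(1, seed = 100 + i))
    perm <- sample(5)
    z1 <- ilr(x, V)
    z2 <- ilr(x[perm], V[, perm])
    expect_equal(sum(z2^2), sum(z1^2), tolerance = 1e-10)
  }
})

test_that("the basis serializes to plain text and back", {
  V <- ilr_basis(5)
  f <- tempfile(fileext = ".csv")
  write_ilr_basis(V, f)
  expect_equal(read_ilr_basis(f), V, tolerance = 1e-15)
})
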