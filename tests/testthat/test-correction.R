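test_that("natural_abundance_matrix reproduces the binomial expansion", {
  # zero natural abundance -> identity
  m0 <- natural_abundance_matrix(2, 0)
  expect_equal(m0$entries, diag(3), ignore_attr = TRUE)

  p <- 0.0107
  m <- natural_abundance_matrix(2, p)
  expect_equal(as.numeric(m$entries[, 1]),
               c((1 - p)^2, 2 * p * (1 - p), p^2), tolerance = 1e-12)
  expect_equal(as.numeric(m$entries[, 1]),
               c(0.97871, 0.02117, 0.00011), tolerance = 1e-4)
  # lower triangular
  expect_true(all(m$entries[upper.tri(m$entries)] == 0))
  expect_error(natural_abundance_matrix(2, 0.6), "p13C")
  expect_error(natural_abundance_matrix(2, -0.01), "p13C")
})

test_that("every correction-matrix column is a probability vector", {
  # independent oracle: explicit summation of choose() terms
  oracle_colsum <- function(n, j, p) {
    s <- 0
    for (i in j:n) s <- s + choose(n - j, i - j) * p^(i - j) * (1 - p)^(n - i)
    s
  }
  for (n in c(2, 5, 6)) {
    m <- natural_abundance_matrix(n, 0.0107)
    expect_true(all(m$entries >= 0))
    for (j in 0:n) {
      expect_equal(sum(m$entries[, j + 1]), oracle_colsum(n, j, 0.0107),
                   tolerance = 1e-12)
      expect_equal(sum(m$entries[, j + 1]), 1, tolerance = 1e-9)
    }
  }
})

test_that("correct_mid inverts the forward matrix application", {
  # frozen round-trip example: x = (0.5, 0, 0.5) at n=2, p=0.0107
  cm <- natural_abundance_matrix(2, 0.0107)
  x <- mid(c(0.5, 0, 0.5), "Glc2", n_carbons = 2)
  measured <- apply_correction_matrix(x, cm)
  expect_gt(measured$fractions[["m1"]], 0)   # natural abundance adds m1
  back <- correct_mid(measured, cm)
  expect_equal(as.numeric(back$fractions), c(0.5, 0, 0.5), tolerance = 1e-9)

  # property: round-trip identity over random MIDs and sizes
  set.seed(99)
  for (n in c(2, 3, 5, 6)) {
    for (p in c(0, 0.0107)) {
      cmn <- natural_abundance_matrix(n, p)
      for (i in 1:5) {
        x <- random_mid(n)
        back <- correct_mid(apply_correction_matrix(x, cmn), cmn)
        expect_equal(as.numeric(back$fractions), as.numeric(x$fractions),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("correct_mid handles pure isotopologues and the p = 0 identity", {
  cm <- natural_abundance_matrix(3, 0.0107)
  for (j in 0:3) {
    col <- mid(as.numeric(cm$entries[, j + 1]), n_carbons = 3)
    unit <- numeric(4); unit[j + 1] <- 1
    expect_equal(as.numeric(correct_mid(col, cm)$fractions), unit,
                 tolerance = 1e-9)
  }
  id <- natural_abundance_matrix(4, 0)
  x <- mid(c(0.1, 0.2, 0.3, 0.25, 0.15), n_carbons = 4)
  expect_equal(correct_mid(x, id)$fractions, x$fractions, tolerance = 1e-12)
  expect_error(correct_mid(x, cm), "does not match")
})
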