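test_that("weight deviation: identity and a hand-computed value", {
  a <- triplet_profile("GCTGCT", TBL)
  b <- triplet_profile("GCT", TBL)
  expect_equal(weight_deviation(a, a, TBL), 0)
  # single differing term: |2 - 1| * 1.1 / 64
  expect_equal(weight_deviation(a, b, TBL), 0.0171875)
})

test_that("misaligned profiles are a structural error", {
  a <- triplet_profile("GCTGCT", TBL)
  expect_error(weight_deviation(a, a[1:10], TBL), "64")
  shuffled <- rev(a)
  expect_error(weight_deviation(a, shuffled, TBL), "canonical")
})

test_that("weight deviation satisfies the metric axioms", {
  set.seed(31)
  for (i in 1:500) {
    x <- random_profile()
    y <- random_profile()
    z <- random_profile()
    dxy <- weight_deviation(x, y, TBL)
    expect_gte(dxy, 0)
    expect_equal(dxy, weight_deviation(y, x, TBL))
    expect_equal(weight_deviation(x, x, TBL), 0)
    expect_lte(weight_deviation(x, z, TBL),
               dxy + weight_deviation(y, z, TBL) + 1e-12)
  }
})

test_that("weight deviation is translation-invariant and 1-homogeneous", {
  set.seed(32)
  x <- random_profile()
  y <- random_profile()
  d <- weight_deviation(x, y, TBL)
  # add the same c occurrences of one triplet to both profiles
  bump <- function(p, t, c) {
    q <- p
    q[t] <- q[t] + c
    q
  }
  expect_equal(weight_deviation(bump(x, "ATG", 7), bump(y, "ATG", 7), TBL),
               d)
  xs <- x
  ys <- y
  xs[] <- 5L * as.integer(x)
  ys[] <- 5L * as.integer(y)
  expect_equal(weight_deviation(xs, ys, TBL), 5 * d)
})

test_that("pairwise matrix is symmetric, zero-diagonal and input-ordered", {
  expect_equal(pairwise_matrix(c(a = "GCTGCT", b = "GCTGCT")),
               matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  set.seed(33)
  seqs <- c(s1 = unname(random_cds(40, 101)),
            s2 = unname(random_cds(50, 102)),
            s3 = unname(random_cds(30, 103)))
  m <- pairwise_matrix(seqs, TBL)
  expect_identical(rownames(m), names(seqs))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(s1 = 0, s2 = 0, s3 = 0))
  expect_true(all(m >= 0))
  # triangle inequality on the realised distances
  expect_lte(m[1, 3], m[1, 2] + m[2, 3] + 1e-12)
  expect_lte(m[1, 2], m[1, 3] + m[3, 2] + 1e-12)
  expect_lte(m[2, 3], m[2, 1] + m[1, 3] + 1e-12)
})

test_that("duplicate or missing sequence ids are rejected", {
  expect_error(pairwise_matrix(c(a = "GCT", a = "ATG")), "duplicate")
  expect_error(pairwise_matrix(c("GCT", "ATG")), "named")
  expect_error(pairwise_matrix(c(a = "GCT")), "at least 2")
})

test_that("matrix csv output round-trips at 4-decimal precision", {
  f <- withr::local_tempfile(fileext = ".csv")
  m <- pairwise_matrix(load_betaglobin()[1:4], TBL)
  write_matrix(m, f, "csv")
  back <- read_matrix(f)
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(back, m, tolerance = 1e-4)

  z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  write_matrix(z, f, "csv")
  lines <- readLines(f)
  expect_length(lines, 3)
  expect_match(lines[2], "0.0000", fixed = TRUE)
  expect_match(lines[3], "0.0000", fixed = TRUE)
})

test_that("phylip output is readable back as the same matrix", {
  f <- withr::local_tempfile(fileext = ".phy")
  m <- pairwise_matrix(load_betaglobin()[c(1, 5, 11)], TBL)
  write_matrix(m, f, "phylip")
  expect_identical(trimws(readLines(f)[1]), "3")
  back <- read_matrix(f, format = "phylip")
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(back, m, tolerance = 1e-4)
})

test_that("triangle layout prints the upper triangle with zero diagonal", {
  f <- withr::local_tempfile(fileext = ".txt")
  m <- pairwise_matrix(load_betaglobin(), TBL)
  write_matrix(m, f, "triangle")
  lines <- readLines(f)
  expect_length(lines, 12)
  human <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  expect_identical(human[1], "Human")
  expect_identical(human[2], "0")
  # last cell of the human row is the human-Gallus deviation, 4 decimals
  expect_identical(human[12], sprintf("%.4f", round(m["Human", "Gallus"], 4)))
  gallus <- strsplit(lines[12], "\t", fixed = TRUE)[[1]]
  expect_identical(gallus[12], "0")
})
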