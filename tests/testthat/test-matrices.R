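# Substitution-matrix representation, file I/O, Hadamard power, Cholesky.

test_that("matrix files round trip and row order is canonicalized", {
  ab <- toy_alphabet(3)
  m <- matrix(c(1, 0.5, 0.2,
                0.5, 2, 0.1,
                0.2, 0.1, 3), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sm <- substitution_matrix(m, ab, name = "toy")

  f <- withr::local_tempfile(fileext = ".txt")
  write_substitution_matrix(sm, f)
  back <- read_substitution_matrix(f)
  expect_equal(back$values, sm$values, tolerance = 1e-9)

  # shuffled row order reads identically
  shuffled <- c("# comment", "B C A",
                "C 0.1 3 0.2",
                "A 0.5 0.2 1",
                "B 2 0.1 0.5")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(shuffled, f2)
  expect_equal(read_substitution_matrix(f2)$values, sm$values)
})

test_that("malformed matrix files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A C", "A 1 0.5", "C 0.7 1"), f)
  expect_error(read_substitution_matrix(f), "asymmetric")

  writeLines(c("A C", "A 1 x", "C 0.5 1"), f)
  expect_error(read_substitution_matrix(f), "non-numeric")

  writeLines(c("A C", "A 1 0.5"), f)
  expect_error(read_substitution_matrix(f), "expected 2 data rows")

  writeLines(c("A C", "A 1 0.5", "A 1 0.5"), f)
  expect_error(read_substitution_matrix(f), "duplicate")
})

test_that("the bundled BL62 matrix is a valid residue kernel", {
  sm <- bl62()
  expect_identical(dim(sm), c(20L, 20L))
  expect_identical(rownames(sm$values), AA_LETTERS)
  expect_true(all(sm$values > 0))
  pd <- is_positive_definite(sm)
  expect_true(pd$pd)
  expect_gt(pd$lambda_min, 1)           # comfortably positive definite
  expect_equal(max(sm$values), sm$values["W", "W"])
})

test_that("hadamard_power is entrywise and composes multiplicatively", {
  sm <- bl62()
  expect_equal(hadamard_power(sm, 0.2)$values["A", "C"],
               sm$values["A", "C"]^0.2)
  two <- substitution_matrix(matrix(2, 2, 2,
                                    dimnames = list(c("A", "C"), c("A", "C"))))
  expect_equal(hadamard_power(two, 0.2)$values[1, 1], 2^0.2)
  # identity fixed under any power; beta = 1 is the identity operation
  id <- identity_sm()
  expect_equal(hadamard_power(id, 3.7)$values, id$values)
  expect_equal(hadamard_power(sm, 1)$values, sm$values)
  # composition: (M^b1)^b2 == M^(b1 b2)
  expect_equal(hadamard_power(hadamard_power(sm, 0.5), 0.4)$values,
               hadamard_power(sm, 0.2)$values, tolerance = 1e-12)
  expect_error(hadamard_power(sm, 0), "positive")
  neg <- substitution_matrix(matrix(c(1, -1, -1, 1), 2,
                                    dimnames = list(c("A", "C"), c("A", "C"))))
  expect_error(hadamard_power(neg, 0.5), "nonnegative")
})

test_that("positive definiteness uses a relative eigenvalue tolerance", {
  expect_true(is_positive_definite(identity_sm())$pd)
  expect_equal(is_positive_definite(identity_sm())$lambda_min, 1)
  # 2x2 toy [[1,2],[2,1]]: eigenvalues 3 and -1
  m <- substitution_matrix(matrix(c(1, 2, 2, 1), 2,
                                  dimnames = list(c("A", "C"), c("A", "C"))))
  r <- is_positive_definite(m)
  expect_false(r$pd)
  expect_equal(r$lambda_min, -1)
  expect_equal(r$lambda_max, 3)
  # any L L^T with nonzero diagonal is PD, at any scale
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    L <- matrix(0, n, n)
    L[lower.tri(L, diag = TRUE)] <- rnorm(n * (n + 1) / 2) * 10^sample(-2:2, 1)
    diag(L) <- sign(diag(L)) * pmax(abs(diag(L)), 0.1)
    expect_true(is_positive_definite(tcrossprod(L))$pd)
  }
})

test_that("Cholesky factorization and reconstruction invert each other", {
  # hand-worked 2x2: [[4,2],[2,5]] = [[2,0],[1,2]] [[2,1],[0,2]]
  m <- substitution_matrix(matrix(c(4, 2, 2, 5), 2,
                                  dimnames = list(c("A", "C"), c("A", "C"))))
  L <- cholesky_factor(m)
  expect_equal(unname(L$L), matrix(c(2, 1, 0, 2), 2), tolerance = 1e-12)
  expect_equal(reconstruct_kernel(L)$values, m$values, tolerance = 1e-12)

  expect_equal(cholesky_factor(identity_sm())$L, diag(20),
               ignore_attr = TRUE)

  set.seed(21)
  for (rep in 1:5) {
    ab <- toy_alphabet(sample(2:5, 1))
    sm <- rand_pd_sm(ab)
    expect_equal(reconstruct_kernel(cholesky_factor(sm))$values, sm$values,
                 tolerance = 1e-10)
  }
  # non-PD input names the failing pivot
  bad <- substitution_matrix(matrix(c(1, 2, 2, 1), 2,
                                    dimnames = list(c("A", "C"), c("A", "C"))))
  expect_error(cholesky_factor(bad), "not positive definite")
})

test_that("as_cholesky enforces shape and the diagonal floor", {
  L <- matrix(c(2, 1, 0, 2), 2, dimnames = list(c("A", "C"), c("A", "C")))
  expect_s3_class(as_cholesky(L), "cholesky_factor")
  Lup <- L; Lup[1, 2] <- 0.3
  expect_error(as_cholesky(Lup), "zero above the diagonal")
  Lz <- L; Lz[2, 2] <- 0
  expect_error(as_cholesky(Lz), "minimum magnitude")
  # clamping pushes a vanishing diagonal back to the floor, preserving sign
  Ln <- L; Ln[2, 2] <- -1e-12
  fixed <- as_cholesky(Ln, clamp = TRUE)
  expect_equal(fixed$L[2, 2], -1e-8)
  expect_true(is_positive_definite(reconstruct_kernel(fixed))$pd)
})

test_that("row normalization gives unit row sums and flags lost symmetry", {
  ones <- ones_sm()
  n1 <- normalize_rows(ones)
  expect_equal(unname(rowSums(n1)), rep(1, 20), tolerance = 1e-12)
  expect_true(all(n1 == 1 / 20))
  expect_true(attr(n1, "symmetric"))

  expect_equal(unname(normalize_rows(identity_sm())), diag(20),
               ignore_attr = TRUE)

  m <- substitution_matrix(matrix(c(3, 1, 1, 1), 2,
                                  dimnames = list(c("A", "C"), c("A", "C"))))
  nm <- normalize_rows(m)
  expect_equal(unname(nm[1, ]), c(0.75, 0.25))
  expect_false(attr(nm, "symmetric"))

  z <- substitution_matrix(matrix(c(0, 0, 0, 1), 2,
                                  dimnames = list(c("A", "C"), c("A", "C"))))
  expect_error(normalize_rows(z), "non-positive")
})
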