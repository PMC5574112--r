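# Learning the residue kernel: objective, analytic gradients, optimizer.

test_that("pearson objective matches hand-evaluated cases", {
  expect_equal(pearson_objective(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_objective(1:3, c(6, 4, 2)), -1)
  expect_equal(pearson_objective(1:3, c(1, 1, 2)), sqrt(3) / 2)
  expect_error(pearson_objective(1:3, c(5, 5, 5)), "constant")
  expect_error(pearson_objective(1:2, 1:2), "at least 3")
})

test_that("kmax = 1 kernel gradient is the aligned-pair count matrix", {
  p1 <- kernel_params(beta = 1, kmax = 1, scheme = "uniform")
  g <- kernel_gradient(identity_sm(), "AC", "AA", p1)
  expect_equal(g["A", "A"], 2)
  expect_equal(g["C", "A"], 2)
  expect_equal(sum(g), 4)   # nothing else contributes
})

test_that("kernel gradient matches finite differences on random instances", {
  set.seed(31)
  for (rep in 1:8) {
    ab <- toy_alphabet(3)
    K <- rand_pd_sm(ab)
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    s <- rand_seq(n, ab); t <- rand_seq(m, ab)
    params <- kernel_params(beta = 1, kmax = sample(1:3, 1),
                            scheme = sample(c("uniform", "degree", "mean"), 1))
    g <- kernel_gradient(K, s, t, params)
    # asymmetric perturbation: K1(a,b) and K1(b,a) treated independently
    si <- alphabet_index(ab, strsplit(s, "")[[1]])
    ti <- alphabet_index(ab, strsplit(t, "")[[1]])
    val <- function(M) {
      pk <- vapply(seq_len(min(params$kmax, n, m)), function(k) {
        tot <- 0
        for (i in seq_len(n - k + 1)) for (j in seq_len(m - k + 1))
          tot <- tot + prod(M[cbind(si[i:(i + k - 1)], ti[j:(j + k - 1)])])
        tot
      }, numeric(1))
      sum(kmer_weight(params$scheme, seq_along(pk), params$kmax, n, m) * pk)
    }
    h <- 1e-6
    for (a in 1:3) for (b in 1:3) {
      Mp <- K$values; Mp[a, b] <- Mp[a, b] + h
      Mm <- K$values; Mm[a, b] <- Mm[a, b] - h
      fd <- (val(Mp) - val(Mm)) / (2 * h)
      expect_equal(g[a, b], fd, tolerance = 1e-5)
    }
  }
})

test_that("gradient handles zero entries of K1 (identity start)", {
  # the division-free scheme must produce finite gradients where K1 = 0
  id <- identity_sm(toy_alphabet(3))
  params <- kernel_params(beta = 1, kmax = 3, scheme = "uniform")
  g <- kernel_gradient(id, "AAA", "CCC", params)
  expect_true(all(is.finite(g)))
  # only (A,C) positions are aligned; with identity K1 the only nonzero
  # remaining-factor products come from length-1 k-mers
  expect_equal(g["A", "C"], 9)
  expect_equal(sum(g != 0), 1)
})

test_that("objective gradient in L matches central finite differences", {
  set.seed(37)
  params <- kernel_params(beta = 1, kmax = 2, scheme = "mean")
  for (rep in 1:4) {
    ab <- toy_alphabet(3)
    seqs <- random_sequences(6, sample(5:8, 1), alphabet = ab)
    sup <- simulate_supervision(seqs, n_pairs = 6, sm = rand_pd_sm(ab),
                                params = params, noise_sigma = 0.05,
                                seed = rep)
    L <- diag(3) + 0.2
    L[upper.tri(L)] <- 0
    dimnames(L) <- list(unclass(ab), unclass(ab))
    g <- objective_gradient(sup, seqs, L, params)$grad_L
    fd <- fd_objective_grad(sup, seqs, L, params)
    expect_equal(g, fd, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("degenerate supervision (constant Y) is rejected", {
  seqs <- random_sequences(4, 6, seed = 2)
  pairs <- data.frame(id1 = names(seqs)[c(1, 1, 2)],
                      id2 = names(seqs)[c(2, 3, 3)], Y = c(5, 5, 5))
  expect_error(fit_kernel_matrix(pairs, seqs), "constant")
})

test_that("optimizer converges immediately when Y is affine in X", {
  set.seed(41)
  seqs <- random_sequences(10, 15, seed = 41)
  sup <- simulate_supervision(seqs, n_pairs = 12, noise_sigma = 0, seed = 3)
  # noise-free supervision is an exact affine decreasing map of the planted
  # kernel values
  expect_equal(pearson_objective(attr(sup, "X_star"), sup$Y), -1)
  # fitting with the planted matrix's Cholesky factor starts at P = -1
  L0 <- cholesky_factor(hadamard_power(bl62(), 0.2))
  fit <- fit_kernel_matrix(sup, seqs, L0 = L0,
                           control = fit_control(max_iter = 5))
  expect_true(fit$converged)
  expect_lt(fit$P_start, -0.999999)
})

test_that("optimization improves the objective and keeps K1 positive definite", {
  seqs <- random_sequences(20, 20, seed = 8)
  sup <- simulate_supervision(seqs, n_pairs = 25, noise_sigma = 0.05,
                              seed = 8)
  fit <- fit_kernel_matrix(sup, seqs,
                           control = fit_control(max_iter = 60))
  # substantial improvement over the identity start
  expect_lt(fit$P_final, fit$P_start - 0.2)
  # trace is non-increasing across accepted steps
  expect_true(all(diff(fit$trace$P) <= 1e-14))
  # every recorded iterate reconstructs a PD matrix (final one checked here;
  # intermediate PD holds by the Cholesky parametrization + diagonal floor)
  expect_true(is_positive_definite(fit$K1)$pd)
  expect_gte(min(abs(diag(fit$L$L))), 1e-8)
  # at the returned point the gradient norm obeys the stopping rule or the
  # objective plateaued
  last <- fit$trace[nrow(fit$trace), ]
  expect_true(fit$converged || last$iteration == 60)
})

test_that("kernel_fit methods expose the fitted model", {
  seqs <- random_sequences(10, 12, seed = 9)
  sup <- simulate_supervision(seqs, n_pairs = 10, noise_sigma = 0.1,
                              seed = 9)
  fit <- fit_kernel_matrix(sup, seqs, control = fit_control(max_iter = 15))
  expect_s3_class(fit, "kernel_fit")
  expect_output(print(fit), "objective P")
  s <- summary(fit)
  expect_s3_class(s, "summary.kernel_fit")
  expect_output(print(s), "smallest eigenvalue")
  expect_identical(dim(coef(fit)), c(20L, 20L))
  expect_true(all(coef(fit, "L")[upper.tri(coef(fit, "L"))] == 0))
  # predict applies the [0, 1] clamp of string_kernel; the optimizer's
  # fitted values are kept unclamped for smoothness
  expect_equal(predict(fit, sup, seqs), pmin(pmax(fitted(fit), 0), 1),
               tolerance = 1e-12)
  expect_length(residuals(fit), nrow(sup))
  # residuals are those of the linear calibration of Y on X
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-8)
})
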