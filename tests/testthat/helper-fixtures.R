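# Shared fixtures: tiny alphabets, random positive-definite matrices and
# random sequences for property-style tests.

toy_alphabet <- function(n = 3) aa_alphabet(LETTERS[seq_len(n)])

# random symmetric PD matrix over a small alphabet (Cholesky construction)
rand_pd_sm <- function(alphabet, scale = 1) {
  n <- length(alphabet)
  V <- matrix(stats::rnorm(n * n, sd = scale), n)
  substitution_matrix(crossprod(V) + diag(n) * 0.5, alphabet,
                      name = "randPD")
}

rand_seq <- function(len, alphabet) {
  paste(sample(unclass(alphabet), len, replace = TRUE), collapse = "")
}

# identity matrix over the full 20-letter alphabet
identity_sm <- function(alphabet = aa_alphabet()) {
  n <- length(alphabet)
  substitution_matrix(diag(n), alphabet, name = "identity")
}

ones_sm <- function(alphabet = aa_alphabet()) {
  n <- length(alphabet)
  substitution_matrix(matrix(1, n, n), alphabet, name = "ones")
}

# central finite-difference gradient of the training objective in L
fd_objective_grad <- function(pairs, sequences, L, params, h = 1e-6) {
  out <- matrix(0, nrow(L), ncol(L))
  for (pq in which(lower.tri(L, diag = TRUE))) {
    Lp <- L; Lp[pq] <- Lp[pq] + h
    Lm <- L; Lm[pq] <- Lm[pq] - h
    out[pq] <- (objective_gradient(pairs, sequences, Lp, params)$P -
                objective_gradient(pairs, sequences, Lm, params)$P) / (2 * h)
  }
  out
}
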