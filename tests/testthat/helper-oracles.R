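# Shared fixtures and independent oracles.

# Best-survival female right whale parameter set (the reference analysis).
paper_vr <- function() vital_rates()

paper_matrix <- function() build_matrix(paper_vr())

# Independent dominant-eigenvalue oracle: plain power iteration on A,
# deliberately not using eigen().
power_iteration_lambda <- function(A, tol = 1e-14, maxit = 100000) {
  x <- rep(1, nrow(A))
  lam <- 0
  for (i in seq_len(maxit)) {
    y <- A %*% x
    lam_new <- sqrt(sum(y^2))
    x_new <- as.numeric(y / lam_new)
    if (max(abs(x_new - x)) < tol) {
      return(sum(x_new * (A %*% x_new)) / sum(x_new^2))  # Rayleigh quotient
    }
    x <- x_new
    lam <- lam_new
  }
  sum(x * (A %*% x)) / sum(x^2)
}

# Random irreducible nonnegative 3x3 matrices for property sweeps.
random_positive_matrix <- function() {
  matrix(runif(9, 0.05, 2), 3, 3)
}
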