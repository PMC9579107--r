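## Internal dense matrix exponential.
##
## Strategy (documented contract): eigen-decomposition when the eigenvector
## basis is well conditioned, with a fall-back to scaling-and-squaring with a
## truncated Taylor series when the matrix is (close to) defective.  Both
## paths accept real or complex input; for real input the (numerically tiny)
## imaginary part arising from complex-conjugate eigenpairs is dropped.

expm_taylor_ss <- function(A) {
  n <- nrow(A)
  nrmA <- max(rowSums(Mod(A)))
  s <- if (nrmA > 0.5) ceiling(log2(nrmA / 0.5)) else 0L
  A <- A / 2^s
  E <- diag(n) + A
  term <- A
  for (j in 2:40) {
    term <- term %*% A / j
    E <- E + term
    if (max(Mod(term)) <= 1e-17 * max(Mod(E))) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

mat_exp <- function(A) {
  real_input <- is.numeric(A)
  n <- nrow(A)
  E <- NULL
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(ev)) {
    P <- ev$vectors
    rc <- tryCatch(rcond(P), error = function(e) 0)
    if (is.finite(rc) && rc > 1e-7) {
      E <- P %*% (exp(ev$values) * solve(P))
    }
  }
  if (is.null(E)) E <- expm_taylor_ss(A)
  if (real_input) E <- Re(E)
  E
}
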