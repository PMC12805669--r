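# Dense matrix exponential by Pade approximation with scaling and squaring
# (Higham 2005, degree-13 approximant). Used for nonreversible rate matrices
# when the eigendecomposition is ill-conditioned, and small enough to live
# here rather than pulling in a linear-algebra dependency.
expm_pade <- function(A) {
  n <- nrow(A)
  nrmA <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin) / 5.4)))
  A <- A / 2^s
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  I <- diag(n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  P <- solve(V - U, V + U)
  for (i in seq_len(s)) P <- P %*% P
  P
}

# Frechet derivative of expm at A in direction E via the block trick:
# expm([[A, E], [0, A]]) has L(A, E) in its upper-right block.
expm_frechet <- function(A, E) {
  n <- nrow(A)
  M <- rbind(cbind(A, E), cbind(matrix(0, n, n), A))
  expm_pade(M)[seq_len(n), n + seq_len(n), drop = FALSE]
}
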