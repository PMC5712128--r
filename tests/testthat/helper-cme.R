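# Exact chemical-master-equation oracle for a reduced toggle:
# frozen volume, no replication or division, one copy per gene, and
# transcription/translation switched off (k_m = k_p = 0) so that each gene's
# protein pool  p_i + 2 d_i + 2 * (gene o repressed)  is conserved.  The
# remaining channels are exactly the toggle's binding core: dimerization
# k_d p (p - 1), dissociation r_d d, repression r_g d_o a_i (consuming a free
# dimer of the other gene) and activation k_g (releasing it).  The state
# space (a1, a2, d1, d2) is finite, so the stationary distribution solves
# pi Q = 0 with no truncation error.  This oracle shares no code with the
# simulator core.

cme_reduced_states <- function(N1, N2) {
  grid <- expand.grid(a1 = 0:1, a2 = 0:1,
                      d1 = 0:(N1 %/% 2), d2 = 0:(N2 %/% 2))
  p1 <- N1 - 2 * grid$d1 - 2 * (1 - grid$a2)  # dimer of gene 1 bound at gene 2
  p2 <- N2 - 2 * grid$d2 - 2 * (1 - grid$a1)
  keep <- p1 >= 0 & p2 >= 0
  cbind(grid[keep, ], p1 = p1[keep], p2 = p2[keep])
}

# stationary distribution; rates are the effective per-second rates
cme_reduced_stationary <- function(N1, N2, k_g, r_g, k_d, r_d) {
  st <- cme_reduced_states(N1, N2)
  n <- nrow(st)
  key <- function(a1, a2, d1, d2) paste(a1, a2, d1, d2)
  idx <- structure(seq_len(n), names = key(st$a1, st$a2, st$d1, st$d2))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, a1, a2, d1, d2, rate) {
    j <- idx[[key(a1, a2, d1, d2)]]
    ii <<- c(ii, from); jj <<- c(jj, j); xx <<- c(xx, rate)
  }
  for (s in seq_len(n)) {
    a1 <- st$a1[s]; a2 <- st$a2[s]; d1 <- st$d1[s]; d2 <- st$d2[s]
    p1 <- st$p1[s]; p2 <- st$p2[s]
    if (a1 == 0) add(s, 1, a2, d1, d2 + 1, k_g)            # activate gene 1
    if (a1 == 1 && d2 > 0) add(s, 0, a2, d1, d2 - 1, r_g * d2)
    if (a2 == 0) add(s, a1, 1, d1 + 1, d2, k_g)            # activate gene 2
    if (a2 == 1 && d1 > 0) add(s, a1, 0, d1 - 1, d2, r_g * d1)
    if (p1 >= 2) add(s, a1, a2, d1 + 1, d2, k_d * p1 * (p1 - 1))
    if (d1 > 0) add(s, a1, a2, d1 - 1, d2, r_d * d1)
    if (p2 >= 2) add(s, a1, a2, d1, d2 + 1, k_d * p2 * (p2 - 1))
    if (d2 > 0) add(s, a1, a2, d1, d2 - 1, r_d * d2)
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # solve pi Q = 0, sum(pi) = 1: replace one balance equation by normalization
  A <- Matrix::t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi <- as.numeric(Matrix::solve(A, b))
  data.frame(st, prob = pi)
}
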