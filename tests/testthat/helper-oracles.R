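# Shared fixtures and independent oracles used across the suite.

# random coalescent tree (optionally heterochronous) -----------------------
random_tree <- function(n_tips, hetero = FALSE, n0 = 1) {
  sh <- if (hetero) stats::runif(n_tips, 0, 1.5) else rep(0, n_tips)
  sc <- demographic_scenario("constant", n0 = n0, sampling_heights = sh)
  simulate_coalescent(sc)
}

random_alignment <- function(taxa, n_sites) {
  seqs <- vapply(taxa, function(t) {
    paste(sample(c("A", "C", "G", "T"), n_sites, replace = TRUE), collapse = "")
  }, "")
  alignment(seqs)
}

random_gtr <- function() {
  f <- stats::runif(4, 0.5, 2); f <- f / sum(f)
  r <- stats::runif(6, 0.2, 2); r <- r / sum(r)
  substitution_model("GTR", frequencies = f, rates = r)
}

random_hky <- function(eps = NULL) {
  f <- stats::runif(4, 0.5, 2); f <- f / sum(f)
  substitution_model("HKY", frequencies = f, kappa = stats::runif(1, 1, 8),
                     random_effects = eps)
}

# exhaustive sum over internal-state assignments: independent likelihood
# oracle for small trees
enumeration_loglik <- function(tree, aln, subst, clock_rate = 1,
                               sites = constant_rates()) {
  n <- tree$n_nodes
  Ps <- vector("list", n)
  total <- 0
  for (k in seq_len(sites$K)) {
    for (i in seq_len(n)) {
      if (i != tree$root) {
        d <- tree$heights[tree$parent[i]] - tree$heights[i]
        Ps[[i]] <- transition_probs(subst, d * clock_rate * sites$rates[k])
      }
    }
    if (k == 1L) Lk <- matrix(0, sites$K, length(aln$pattern_weights))
    internal <- (tree$n_tips + 1L):n
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
    for (p in seq_along(aln$pattern_weights)) {
      states <- match(aln$patterns[, p], c("A", "C", "G", "T"))
      s <- 0
      for (g in seq_len(nrow(grid))) {
        asn <- integer(n)
        asn[seq_len(tree$n_tips)] <- states
        asn[internal] <- grid[g, ]
        pr <- subst$frequencies[asn[tree$root]]
        for (i in seq_len(n)) {
          if (i != tree$root) pr <- pr * Ps[[i]][asn[tree$parent[i]], asn[i]]
        }
        s <- s + pr
      }
      Lk[k, p] <- s
    }
  }
  site_l <- colSums(Lk * sites$weights)
  sum(aln$pattern_weights * log(site_l))
}

# central finite differences of a scalar function
fd_gradient <- function(f, z, h = 1e-5) {
  vapply(seq_along(z), function(i) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    (f(zp) - f(zm)) / (2 * h)
  }, 0)
}

# numerical log|det J| of a vector-valued map at y
fd_log_det_jacobian <- function(map, y, h = 1e-6) {
  m <- length(map(y))
  J <- matrix(0, m, length(y))
  for (i in seq_along(y)) {
    yp <- y; yp[i] <- yp[i] + h
    ym <- y; ym[i] <- ym[i] - h
    J[, i] <- (map(yp) - map(ym)) / (2 * h)
  }
  determinant(J)$modulus[1]
}

# scaling-and-squaring matrix exponential oracle (independent of the
# package's eigendecomposition path)
expm_oracle <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

# adaptive quadrature of 1/N(t), split at the grid knots where the
# integrand is non-smooth so the quadrature converges to full precision
quadrature_inv_pop <- function(grid, u, v, kind) {
  brks <- sort(unique(c(u, v,
                        grid$times[grid$times > u & grid$times < v])))
  total <- 0
  for (j in seq_len(length(brks) - 1L)) {
    total <- total +
      integrate(function(t) 1 / pop_size_at(grid, t, kind),
                brks[j], brks[j + 1], rel.tol = 1e-13,
                abs.tol = 1e-14, subdivisions = 400L)$value
  }
  total
}
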