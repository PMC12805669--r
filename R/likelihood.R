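#' Felsenstein pruning log-likelihood
#'
#' Computes `sum_p weight_p log sum_k w_k sum_s pi_s partial_s(p,k)` by the
#' pruning recursion over the fixed topology. Branch lengths in expected
#' substitutions are `(parent height - child height) * clock rate *
#' category rate`. Partials are max-renormalized at every internal node and
#' the log scalers accumulated per pattern, so alignments far larger than
#' the underflow threshold remain finite.
#'
#' @param tree a [time_tree].
#' @param aln an [alignment] covering exactly the tree's taxa.
#' @param subst a [substitution_model].
#' @param sites a `site_rate_model` (see [discrete_gamma_rates]).
#' @param clock a [strict_clock].
#' @return the log-likelihood (a single real).
#' @export
tree_log_likelihood <- function(tree, aln, subst, sites = constant_rates(),
                                clock = strict_clock(1, fixed = TRUE)) {
  pruning_core(tree, aln, subst, sites, clock, grad = FALSE)$loglik
}

#' Pruning log-likelihood with analytic gradients
#'
#' Same likelihood as [tree_log_likelihood] together with its exact
#' derivatives: per-node height gradients via an outside (pre-order) pass,
#' substitution-parameter gradients via eigendecomposition Frechet
#' derivatives of `exp(Qt)`, the site-model shape gradient via the chain
#' rule through the category rates, and the clock-rate gradient.
#'
#' @inheritParams tree_log_likelihood
#' @param wrt character vector naming substitution parameters to
#'   differentiate (subset of `names(subst_free_params(subst))`), or `NULL`
#'   for all free parameters.
#' @return list with `loglik`, `d_heights` (full node vector; tip slots
#'   meaningless), `d_clock`, `d_shape`, and `d_subst` (named list matching
#'   the free parameter layout).
#' @export
tree_log_likelihood_grad <- function(tree, aln, subst,
                                     sites = constant_rates(),
                                     clock = strict_clock(1, fixed = TRUE),
                                     wrt = NULL) {
  pruning_core(tree, aln, subst, sites, clock, grad = TRUE, wrt = wrt)
}

pruning_core <- function(tree, aln, subst, sites, clock, grad = FALSE,
                         wrt = NULL, tip_cache = NULL) {
  if (is.null(tip_cache) && !setequal(tree$labels, aln$taxa)) {
    stop("tree_log_likelihood: tree and alignment taxa differ")
  }
  n_tips <- tree$n_tips
  n_nodes <- tree$n_nodes
  P <- length(aln$pattern_weights)
  wgt <- aln$pattern_weights
  pi <- subst$frequencies
  K <- sites$K
  rates <- sites$rates
  wk <- sites$weights
  h <- tree$heights
  dur <- numeric(n_nodes)
  nonroot_nodes <- which(tree$parent != 0L)
  dur[nonroot_nodes] <- h[tree$parent[nonroot_nodes]] - h[nonroot_nodes]
  if (any(dur < -1e-9)) stop("tree_log_likelihood: negative branch duration")
  dur[dur < 0] <- 0
  eig <- subst_eigen(subst)

  tipP <- if (is.null(tip_cache)) {
    lapply(seq_len(n_tips), function(i) tip_partials(aln, tree$labels[i]))
  } else tip_cache

  logLpk <- matrix(NA_real_, K, P)
  store <- if (grad) vector("list", K) else NULL
  for (k in seq_len(K)) {
    Ins <- vector("list", n_nodes)
    sc <- matrix(0, n_nodes, P)
    Pmat <- vector("list", n_nodes)  # transition matrix on branch above node
    Amat <- vector("list", n_nodes)  # Pmat[[c]] %*% Ins[[c]]
    for (i in seq_len(n_tips)) Ins[[i]] <- tipP[[i]]
    for (n in tree$postorder) {
      prod <- NULL
      for (c in tree$children[[n]]) {
        Pc <- prob_from_eigen(eig, dur[c] * clock$rate * rates[k])
        Pmat[[c]] <- Pc
        A <- Pc %*% Ins[[c]]
        Amat[[c]] <- A
        prod <- if (is.null(prod)) A else prod * A
      }
      f <- pmax(prod[1, ], prod[2, ], prod[3, ], prod[4, ])
      if (any(f == 0)) return(list(loglik = -Inf))
      Ins[[n]] <- prod / rep(f, each = 4)
      cc <- tree$children[[n]]
      sc[n, ] <- sc[cc[1], ] + sc[cc[2], ] + log(f)
    }
    logLpk[k, ] <- log(colSums(pi * Ins[[tree$root]])) + sc[tree$root, ]
    if (grad) store[[k]] <- list(Ins = Ins, sc = sc, Pmat = Pmat, Amat = Amat)
  }
  # log-sum-exp over categories with weights
  lw <- log(wk)
  if (K == 1L) {
    logLp <- logLpk[1L, ] + lw
  } else {
    mlk <- apply(logLpk + lw, 2, max)
    logLp <- mlk + log(colSums(exp(logLpk + lw - rep(mlk, each = K))))
  }
  loglik <- sum(wgt * logLp)
  if (!grad) return(list(loglik = loglik))

  free <- subst_free_params(subst)
  if (is.null(wrt)) wrt <- names(free)
  dQs <- if (length(wrt)) subst_dQ(subst, wrt) else list()
  d_subst <- lapply(free[wrt], function(len) numeric(len))
  G <- matrix(0, n_nodes, K)      # d loglik / d branch length (subst units)
  d_pi_root <- numeric(4)

  for (k in seq_len(K)) {
    st <- store[[k]]
    Ins <- st$Ins; sc <- st$sc; Pmat <- st$Pmat; Amat <- st$Amat
    QP <- vector("list", n_nodes)
    U <- vector("list", n_nodes)
    su <- matrix(0, n_nodes, P)
    U[[tree$root]] <- matrix(pi, 4, P)
    # root frequency term
    fac_root <- exp(sc[tree$root, ] + lw[k] - logLp)
    d_pi_root <- d_pi_root + as.numeric((Ins[[tree$root]] * rep(fac_root, each = 4)) %*% wgt)
    for (n in tree$preorder) {
      cc <- tree$children[[n]]
      for (idx in 1:2) {
        c <- cc[idx]; s <- cc[3 - idx]
        W <- U[[n]] * Amat[[s]]
        swc <- su[n, ] + sc[s, ]
        fac <- wgt * exp(swc + sc[c, ] + lw[k] - logLp)
        BI <- Ins[[c]]
        # branch-length derivative: dP/ds = Q P
        v <- colSums(W * (eig$Q %*% Pmat[[c]] %*% BI))
        G[c, k] <- G[c, k] + sum(fac * v)
        # substitution-parameter derivatives
        if (length(wrt)) {
          slen <- dur[c] * clock$rate * rates[k]
          for (p in names(dQs)) {
            for (m in seq_along(dQs[[p]])) {
              dP <- dprob_from_eigen(eig, slen, dQs[[p]][[m]])
              v <- colSums(W * (dP %*% BI))
              d_subst[[p]][m] <- d_subst[[p]][m] + sum(fac * v)
            }
          }
        }
        if (c > n_tips) {
          raw <- crossprod(Pmat[[c]], W)
          f <- pmax(raw[1, ], raw[2, ], raw[3, ], raw[4, ], 1e-300)
          U[[c]] <- raw / rep(f, each = 4)
          su[c, ] <- swc + log(f)
        }
      }
    }
  }
  if ("frequencies" %in% names(d_subst)) {
    d_subst$frequencies <- d_subst$frequencies + d_pi_root
  }
  d_dur <- as.numeric(G %*% (clock$rate * rates))
  d_heights <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    if (i == tree$root) next
    d_heights[i] <- d_heights[i] - d_dur[i]
    d_heights[tree$parent[i]] <- d_heights[tree$parent[i]] + d_dur[i]
  }
  d_rate_k <- as.numeric(crossprod(G, dur * clock$rate)[, 1])
  d_shape <- if (is.null(sites$drates) || sites$K == 1L) 0 else
    sum(d_rate_k * sites$drates(sites$shape))
  d_clock <- sum(G %*% rates * dur)
  list(loglik = loglik, d_heights = d_heights, d_clock = d_clock,
       d_shape = d_shape, d_subst = d_subst)
}
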