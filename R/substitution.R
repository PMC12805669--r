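#' Nucleotide substitution models
#'
#' Constructs a continuous-time Markov substitution model over states
#' (A, C, G, T). Off-diagonal rates are `base_ij * pi_j * exp(eps_ij)` where
#' `base` is the model's exchangeability (JC69: all equal; HKY: `kappa` on
#' transitions A<->G and C<->T; GTR: six symmetric rates in the order
#' AC, AG, AT, CG, CT, GT), `pi` the stationary frequencies and `eps` an
#' optional 12-vector of nonreversible random effects on the ordered pairs
#' (A>C, A>G, A>T, C>A, C>G, C>T, G>A, G>C, G>T, T>A, T>C, T>G). The matrix
#' is always renormalized to one expected substitution per unit time,
#' `-sum_i pi_i Q_ii = 1`, so random effects change relative rather than
#' absolute rates and the clock rate stays identifiable.
#'
#' @param name one of `"JC69"`, `"HKY"`, `"GTR"`.
#' @param frequencies stationary frequencies (length 4, positive, sums to 1).
#' @param kappa transition/transversion rate ratio (HKY).
#' @param rates six GTR exchange rates (any positive scale; only their
#'   relative sizes matter after normalization).
#' @param random_effects optional 12-vector `eps` (HKY-RE style).
#' @return An object of class `substitution_model`.
#' @export
substitution_model <- function(name = c("JC69", "HKY", "GTR"),
                               frequencies = rep(0.25, 4),
                               kappa = NULL, rates = NULL,
                               random_effects = NULL) {
  name <- match.arg(name)
  if (length(frequencies) != 4L || any(frequencies <= 0)) {
    stop("substitution_model: frequencies must be 4 positive values")
  }
  if (abs(sum(frequencies) - 1) > 1e-8) {
    stop("substitution_model: frequencies must sum to 1")
  }
  frequencies <- frequencies / sum(frequencies)
  if (name == "HKY") {
    if (is.null(kappa)) kappa <- 1
    if (kappa <= 0) stop("substitution_model: kappa must be positive")
  }
  if (name == "GTR") {
    if (is.null(rates)) rates <- rep(1 / 6, 6)
    if (length(rates) != 6L || any(rates <= 0)) {
      stop("substitution_model: GTR needs 6 positive rates")
    }
  }
  if (!is.null(random_effects) && length(random_effects) != 12L) {
    stop("substitution_model: random_effects must have length 12")
  }
  structure(list(name = name, frequencies = frequencies, kappa = kappa,
                 rates = rates, random_effects = random_effects),
            class = "substitution_model")
}

NUC <- c("A", "C", "G", "T")
# row-major ordered pairs i != j, for the random-effects vector
ordered_pairs <- local({
  p <- which(matrix(TRUE, 4, 4) & !diag(4) == 1, arr.ind = TRUE)
  p <- expand.grid(j = 1:4, i = 1:4)[, 2:1]
  p <- p[p$i != p$j, ]
  as.matrix(p[order(p$i, p$j), ])
})
# GTR pair order AC, AG, AT, CG, CT, GT
gtr_pairs <- cbind(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4))

exchange_matrix <- function(model) {
  R <- matrix(1, 4, 4)
  if (model$name == "HKY") {
    R[1, 3] <- R[3, 1] <- model$kappa
    R[2, 4] <- R[4, 2] <- model$kappa
  } else if (model$name == "GTR") {
    for (m in 1:6) {
      R[gtr_pairs[m, 1], gtr_pairs[m, 2]] <- model$rates[m]
      R[gtr_pairs[m, 2], gtr_pairs[m, 1]] <- model$rates[m]
    }
  }
  diag(R) <- 0
  R
}

eps_matrix <- function(model) {
  E <- matrix(0, 4, 4)
  if (!is.null(model$random_effects)) {
    E[ordered_pairs] <- model$random_effects
  }
  E
}

rate_matrix_parts <- function(model) {
  pi <- model$frequencies
  Qraw <- exchange_matrix(model) * rep(pi, each = 4) * exp(eps_matrix(model))
  diag(Qraw) <- 0
  diag(Qraw) <- -rowSums(Qraw)
  nu <- -sum(pi * diag(Qraw))
  list(Qraw = Qraw, nu = nu, Q = Qraw / nu)
}

#' Normalized instantaneous rate matrix
#'
#' @param model a [substitution_model].
#' @return 4x4 matrix with zero row sums, normalized to expected rate 1.
#' @export
rate_matrix <- function(model) {
  rate_matrix_parts(model)$Q
}

is_reversible <- function(model) is.null(model$random_effects)

# Eigendecomposition of the normalized Q. Reversible models go through the
# symmetric similarity transform diag(sqrt(pi)) Q diag(1/sqrt(pi)) for
# stability; nonreversible ones use the general (possibly complex) solver
# with a Pade fallback when the eigenvector basis is ill-conditioned.
subst_eigen <- function(model) {
  parts <- rate_matrix_parts(model)
  Q <- parts$Q
  if (is_reversible(model)) {
    sp <- sqrt(model$frequencies)
    S <- Q * (sp %o% (1 / sp))
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    E <- e$vectors / sp
    invE <- t(e$vectors) * rep(sp, each = 4)
    list(values = e$values, E = E, invE = invE, Q = Q, ok = TRUE)
  } else {
    e <- eigen(Q)
    E <- e$vectors
    invE <- tryCatch(solve(E), error = function(err) NULL)
    if (is.null(invE) || max(Mod(E %*% invE - diag(4))) > 1e-6) {
      return(list(values = NULL, E = NULL, invE = NULL, Q = Q, ok = FALSE))
    }
    list(values = e$values, E = E, invE = invE, Q = Q, ok = TRUE)
  }
}

prob_from_eigen <- function(eig, t) {
  if (!eig$ok) return(expm_pade(eig$Q * t))
  P <- eig$E %*% (exp(eig$values * t) * eig$invE)
  P <- Re(P)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [substitution_model].
#' @param t branch length in expected substitutions per site (duration in
#'   years x clock rate x site-rate category), nonnegative.
#' @return 4x4 row-stochastic matrix.
#' @export
transition_probs <- function(model, t) {
  if (t < 0) stop("transition_probs: t must be nonnegative")
  prob_from_eigen(subst_eigen(model), t)
}

# Frechet derivative of P(t) in the direction dQ, from a precomputed
# eigendecomposition: dP = E ((invE dQ E) o F) invE with the divided
# difference matrix F_ij = (exp(l_i t) - exp(l_j t)) / (l_i - l_j).
dprob_from_eigen <- function(eig, t, dQ) {
  if (!eig$ok) return(expm_frechet(eig$Q * t, dQ * t))
  lam <- eig$values
  el <- exp(lam * t)
  d <- outer(lam, lam, `-`)
  F <- outer(el, el, `-`) / d
  same <- Mod(d) < 1e-9
  F[same] <- t * outer(el, rep(1, 4))[same]
  V <- eig$invE %*% dQ %*% eig$E
  Re(eig$E %*% ((V * F) %*% eig$invE))
}

# Free constrained parameters of a substitution model: a list of
# name -> length used by the joint posterior, in canonical order.
subst_free_params <- function(model, estimate_frequencies = TRUE) {
  out <- list()
  if (model$name == "HKY") out$kappa <- 1L
  if (model$name == "GTR") out$rates <- 6L
  if (estimate_frequencies && model$name != "JC69") out$frequencies <- 4L
  if (!is.null(model$random_effects)) out$random_effects <- 12L
  out
}

# Directional derivatives of the *normalized* Q with respect to each free
# constrained parameter component. Returns a named list; each element is a
# list of 4x4 matrices (one per component of that parameter).
subst_dQ <- function(model, params = names(subst_free_params(model))) {
  parts <- rate_matrix_parts(model)
  pi <- model$frequencies
  R <- exchange_matrix(model)
  Eps <- exp(eps_matrix(model))
  diag(Eps) <- 0
  norm_chain <- function(dQraw) {
    # d(Qraw/nu) given dQraw (off-diagonals set; diagonal recomputed here)
    diag(dQraw) <- 0
    diag(dQraw) <- -rowSums(dQraw)
    dnu <- -sum(pi * diag(dQraw))
    dQraw / parts$nu - parts$Q * (dnu / parts$nu)
  }
  out <- list()
  for (p in params) {
    if (p == "kappa") {
      dR <- matrix(0, 4, 4)
      dR[1, 3] <- dR[3, 1] <- 1
      dR[2, 4] <- dR[4, 2] <- 1
      out$kappa <- list(norm_chain(dR * rep(pi, each = 4) * Eps))
    } else if (p == "rates") {
      out$rates <- lapply(1:6, function(m) {
        dR <- matrix(0, 4, 4)
        dR[gtr_pairs[m, 1], gtr_pairs[m, 2]] <- 1
        dR[gtr_pairs[m, 2], gtr_pairs[m, 1]] <- 1
        norm_chain(dR * rep(pi, each = 4) * Eps)
      })
    } else if (p == "frequencies") {
      out$frequencies <- lapply(1:4, function(x) {
        dQraw <- matrix(0, 4, 4)
        dQraw[, x] <- R[, x] * Eps[, x]
        diag(dQraw) <- 0
        ddiag <- -rowSums(dQraw)
        dQraw <- dQraw + diag(ddiag)
        # nu = sum_i pi_i rowsum_i(Qraw): explicit pi_x term plus Qraw change
        dnu <- sum(pi * -ddiag) + (-diag(parts$Qraw)[x])
        dQraw / parts$nu - parts$Q * (dnu / parts$nu)
      })
    } else if (p == "random_effects") {
      out$random_effects <- lapply(1:12, function(m) {
        dQraw <- matrix(0, 4, 4)
        ij <- ordered_pairs[m, , drop = FALSE]
        dQraw[ij] <- parts$Qraw[ij]
        norm_chain(dQraw)
      })
    }
  }
  out
}

#' Strict molecular clock
#'
#' @param rate substitutions per site per year (positive).
#' @param fixed if `TRUE` the rate is held constant during inference.
#' @return an object of class `strict_clock`.
#' @export
strict_clock <- function(rate, fixed = FALSE) {
  if (rate <= 0) stop("strict_clock: rate must be positive")
  structure(list(rate = rate, fixed = fixed), class = "strict_clock")
}
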