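# ---- empirical constants ----------------------------------------------------

# Amino-acid alphabet in the classical rate-matrix ordering
.AA <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

# JTT (Jones, Taylor & Thornton 1992) exchangeability counts -- the lower
# triangle of the symmetric 20x20 matrix in .AA order, column-major -- and
# the published equilibrium frequencies. These are the canonical constants
# distributed with the major phylogenetics programs.
.jtt_constants <- function() {
  q <- c(
    58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
    11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
    126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
    8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
    31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
    597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
    5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
    16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
    245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
    103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
    285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16
  )
  bf <- c(
    0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
    0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
    0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005
  )
  list(lower = q, bf = bf / sum(bf))
}

# ---- model construction -----------------------------------------------------

#' Construct a substitution model
#'
#' Builds a reversible continuous-time Markov substitution model for sequence
#' simulation and likelihood computation. Supported kinds:
#'
#' * `"JTT"` -- the empirical JTT amino-acid model (exchangeabilities and
#'   equilibrium frequencies embedded);
#' * `"Poisson"` -- equal-rates amino-acid model, uniform frequencies;
#' * `"K2P"` -- Kimura 2-parameter nucleotide model (`kappa` =
#'   transition/transversion rate ratio).
#'
#' The rate matrix is scaled so one unit of branch length equals one expected
#' substitution per site. Optional among-site rate variation: a discrete
#' gamma with `gamma_k` equiprobable categories of shape `gamma_alpha`, and
#' an invariant-site proportion `p_inv`.
#'
#' @param kind One of `"JTT"`, `"Poisson"`, `"K2P"`.
#' @param kappa Transition/transversion ratio for `"K2P"` (default 2).
#' @param gamma_k,gamma_alpha Discrete-gamma categories and shape (`NULL`
#'   for no rate variation).
#' @param p_inv Proportion of invariant sites (default 0).
#' @return An object of class `substitution_model`.
#' @examples
#' m <- substitution_model("JTT")
#' range(rowSums(m$Q))   # rows sum to zero
#' @export
substitution_model <- function(kind = c("JTT", "Poisson", "K2P"), kappa = 2,
                               gamma_k = NULL, gamma_alpha = NULL, p_inv = 0) {
  kind <- match.arg(kind)
  if (kind == "JTT") {
    cst <- .jtt_constants()
    alphabet <- .AA
    bf <- cst$bf
    S <- matrix(0, 20, 20, dimnames = list(alphabet, alphabet))
    S[lower.tri(S)] <- cst$lower
    S <- S + t(S)
  } else if (kind == "Poisson") {
    alphabet <- .AA
    bf <- rep(1 / 20, 20)
    S <- matrix(1, 20, 20) - diag(20)
    dimnames(S) <- list(alphabet, alphabet)
  } else {
    alphabet <- c("A", "C", "G", "T")
    bf <- rep(0.25, 4)
    S <- matrix(1, 4, 4, dimnames = list(alphabet, alphabet))
    S["A", "G"] <- S["G", "A"] <- S["C", "T"] <- S["T", "C"] <- kappa
    diag(S) <- 0
  }
  names(bf) <- alphabet
  Q <- S %*% diag(bf)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))      # expected substitutions per site per unit time
  Q <- Q / mu
  dimnames(Q) <- list(alphabet, alphabet)

  # eigen-decomposition of the reversible generator via symmetrisation
  sq <- sqrt(bf)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)

  if (p_inv < 0 || p_inv >= 1) abort("p_inv must lie in [0, 1)")
  rates <- 1; weights <- 1
  if (!is.null(gamma_k)) {
    if (is.null(gamma_alpha)) abort("gamma_alpha required when gamma_k is set")
    rates <- .discrete_gamma_rates(gamma_alpha, gamma_k)
    weights <- rep(1 / gamma_k, gamma_k)
  }
  # with invariant sites, variable-site rates are rescaled so the overall
  # mean rate stays 1 (the usual +I convention)
  if (p_inv > 0) rates <- rates / (1 - p_inv)
  structure(
    list(kind = kind, alphabet = alphabet, freqs = bf, Q = Q,
         eig_values = eig$values, eig_vectors = eig$vectors, sqrt_freqs = sq,
         rates = rates, rate_weights = weights, p_inv = p_inv),
    class = "substitution_model"
  )
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model>", x$kind, "|", length(x$alphabet), "states |",
      length(x$rates), "rate categorie(s) | p_inv =", x$p_inv, "\n")
  invisible(x)
}

# mean rates of k equiprobable discrete-gamma categories (mean-of-quantile
# discretisation, the usual phylogenetics convention)
.discrete_gamma_rates <- function(alpha, k) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  r <- numeric(k)
  for (i in seq_len(k)) {
    lo <- stats::pgamma(q[i], shape = alpha + 1, rate = alpha)
    hi <- stats::pgamma(q[i + 1L], shape = alpha + 1, rate = alpha)
    r[i] <- (hi - lo) * k
  }
  r * (k / sum(r))  # guard rounding; category mean is 1 by construction
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site), `t >= 0`.
#' @param rate Optional rate multiplier (for gamma categories).
#' @return Stochastic matrix over the model alphabet.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  if (t < 0) abort("branch length must be >= 0")
  el <- exp(model$eig_values * t * rate)
  V <- model$eig_vectors
  B <- V %*% (el * t(V))
  P <- (1 / model$sqrt_freqs) * B %*% diag(model$sqrt_freqs)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}
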