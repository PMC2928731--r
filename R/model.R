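NUC <- c("A", "C", "G", "T")

#' Specify a nucleotide substitution model
#'
#' Builds a GTR-family model: six exchangeabilities (order AC, AG, AT, CG,
#' CT, GT; GT is the reference and conventionally 1), stationary base
#' frequencies, optional discrete-gamma rate heterogeneity with shape
#' `alpha` over `k` equal-probability categories, and an optional proportion
#' of invariant sites `p_inv`.  The generator is normalised so that the
#' expected number of substitutions per site per unit branch length is 1 at
#' stationarity (branch lengths are therefore in substitutions/site).
#'
#' @param rates six non-negative exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param pi four base frequencies (A, C, G, T); must be positive, summing
#'   to one (renormalised).
#' @param alpha gamma shape (> 0), or `NULL` for no rate heterogeneity.
#'   Small alpha (e.g. 0.1) gives a sharp L-shaped rate distribution: most
#'   sites nearly invariable, a few highly mutable.
#' @param p_inv proportion of invariant sites in `[0, 1)`, or `NULL`.
#' @param k number of discrete gamma categories (default 8).
#' @return an object of class `"subst_model"`.
#' @examples
#' m <- subst_model(alpha = 0.101, p_inv = 0.4)  # GTR+G+I style, JC rates
#' @export
subst_model <- function(rates = rep(1, 6), pi = rep(0.25, 4),
                        alpha = NULL, p_inv = NULL, k = 8L) {
  stopifnot(length(rates) == 6, all(rates >= 0), length(pi) == 4)
  if (any(pi <= 0)) stop("base frequencies must all be positive")
  pi <- pi / sum(pi)
  if (!is.null(alpha) && alpha <= 0) stop("gamma shape alpha must be > 0")
  if (!is.null(p_inv) && (p_inv < 0 || p_inv >= 1)) {
    stop("p_inv must lie in [0, 1)")
  }
  if (k < 1L) stop("k must be >= 1")
  names(pi) <- NUC
  m <- structure(list(rates = as.numeric(rates), pi = pi,
                      alpha = alpha, p_inv = p_inv, k = as.integer(k)),
                 class = "subst_model")
  m$eig <- gtr_eigen(m)
  m
}

#' @export
print.subst_model <- function(x, ...) {
  lab <- if (all(x$rates == x$rates[1]) && all(abs(x$pi - 0.25) < 1e-12)) "JC"
         else if (all(abs(x$rates[c(1, 3, 4, 6)] - x$rates[1]) < 1e-12) &&
                  abs(x$rates[2] - x$rates[5]) < 1e-12) "HKY" else "GTR"
  cat(sprintf("%s model%s%s\n", lab,
              if (!is.null(x$alpha)) sprintf(" +G(alpha=%.4g, K=%d)", x$alpha, x$k) else "",
              if (!is.null(x$p_inv)) sprintf(" +I(p_inv=%.4g)", x$p_inv) else ""))
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      sprintf("%.4g", x$rates), "\n")
  cat("  base frequencies (A C G T):", sprintf("%.4g", x$pi), "\n")
  invisible(x)
}

# Normalised GTR generator Q: q_ij = r_ij * pi_j (i != j),
# scaled so -sum_i pi_i q_ii = 1.
gtr_generator <- function(model) {
  r <- model$rates
  pi <- model$pi
  R <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  R["A", "C"] <- r[1]; R["A", "G"] <- r[2]; R["A", "T"] <- r[3]
  R["C", "G"] <- r[4]; R["C", "T"] <- r[5]; R["G", "T"] <- r[6]
  R <- R + t(R)
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix: all exchangeabilities zero")
  Q / mu
}

# Eigendecomposition of Q in pi-symmetrised form (stable for reversible
# models): S = D Q D^-1 with D = diag(sqrt(pi)) is symmetric.
gtr_eigen <- function(model) {
  Q <- gtr_generator(model)
  d <- sqrt(model$pi)
  S <- (d %o% (1 / d)) * Q
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       right = (1 / d) * e$vectors,        # rows scaled by 1/sqrt(pi)
       left = t(e$vectors * d))            # columns scaled by sqrt(pi)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q * t * rate)` for the model's normalised GTR generator,
#' computed via the cached eigendecomposition.  Rows sum to one; detailed
#' balance `pi_i P_ij = pi_j P_ji` holds by reversibility.
#'
#' @param model a [subst_model()].
#' @param t branch length in expected substitutions/site (>= 0).
#' @param rate site-rate multiplier (>= 0), e.g. a discrete-gamma category
#'   rate.
#' @return a 4x4 row-stochastic matrix over states A, C, G, T.
#' @export
transition_probs <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length t must be >= 0")
  if (rate < 0) stop("rate multiplier must be >= 0")
  e <- model$eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  # clip tiny negative round-off and renormalise rows
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(NUC, NUC)
  P
}

#' Discrete-gamma rate categories
#'
#' Approximates mean-one gamma rate heterogeneity by `k` equal-probability
#' categories whose rates are the conditional means of the gamma within each
#' quantile bin (the mean method).  The bin mean is evaluated by the exact
#' incomplete-gamma identity
#' `E[X; a < X < b] = pgamma(b, alpha+1) - pgamma(a, alpha+1)` for
#' `X ~ Gamma(alpha, rate = alpha)`.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return list with `rates` (strictly increasing, mean exactly 1) and
#'   `weights` (each `1/k`).
#' @examples
#' discrete_gamma_rates(0.101, 8)
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (k < 1L) stop("k must be >= 1")
  k <- as.integer(k)
  if (k == 1L) return(list(rates = 1, weights = 1))
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X | bin] * P(bin) = pgamma(upper, a+1) - pgamma(lower, a+1); times k
  # because each bin has probability 1/k.
  upper <- stats::pgamma(qb[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(qb[-(k + 1)], shape = alpha + 1, rate = alpha)
  rates <- k * (upper - lower)
  rates <- rates / (sum(rates) / k)  # guard mean-one to machine precision
  list(rates = rates, weights = rep(1 / k, k))
}

# Per-site rate multipliers and weights for the full +G+I mixture.
# Invariant sites are handled separately in the likelihood; this returns the
# gamma part only (rate 1 everywhere when alpha is NULL).
model_rate_categories <- function(model) {
  if (is.null(model$alpha)) list(rates = 1, weights = 1)
  else discrete_gamma_rates(model$alpha, model$k)
}
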