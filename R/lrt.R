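#' Upper-tail chi-squared quantile
#'
#' The critical value `c` with `P(X > c) = tail_prob` for `X ~ chi^2(df)`,
#' as used to reference `2 * delta-lnL` statistics from nested substitution
#' models.
#'
#' @param tail_prob upper-tail probability in `(0, 1]`.
#' @param df degrees of freedom (positive integer).
#' @return the quantile.
#' @examples
#' chi2_quantile(0.001, 1)  # 10.83
#' @export
chi2_quantile <- function(tail_prob, df) {
  if (tail_prob <= 0 || tail_prob > 1) stop("tail_prob must lie in (0, 1]")
  if (df < 1) stop("df must be a positive integer")
  stats::qchisq(tail_prob, df = df, lower.tail = FALSE)
}

#' Likelihood ratio test between nested model fits
#'
#' `stat = 2 (lnL_alt - lnL_null)` referred to a chi-squared distribution
#' with `df` equal to the difference in free-parameter counts.  For the
#' common rate-heterogeneity comparison (e.g. GTR+I vs GTR+G+I) `df = 1`,
#' the standard reference despite the boundary-condition conservatism.
#'
#' @param null,alt [phylo_ml()] fits (or lists with `lnL` and
#'   `n_free_params`), with `null` nested in `alt`.
#' @param level significance level (default 0.05).
#' @return an object of class `"lrt_result"`: list with `stat`, `df`,
#'   `p_value`, `critical_value`, `level`, `reject`.
#' @examples
#' null <- list(lnL = -1000, n_free_params = 10)
#' alt  <- list(lnL = -986.37, n_free_params = 11)
#' lrt(null, alt, level = 0.001)
#' @export
lrt <- function(null, alt, level = 0.05) {
  if (is.null(null$lnL) || is.null(alt$lnL)) {
    stop("null and alt must carry lnL and n_free_params")
  }
  df <- alt$n_free_params - null$n_free_params
  if (df < 1) stop("models are not nested: alt has no extra free parameters")
  if (alt$lnL < null$lnL - 1e-6) {
    stop(sprintf("contract violation: lnL(alt)=%.6f < lnL(null)=%.6f",
                 alt$lnL, null$lnL))
  }
  stat <- max(0, 2 * (alt$lnL - null$lnL))
  crit <- chi2_quantile(level, df)
  structure(list(stat = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 critical_value = crit, level = level,
                 reject = stat > crit),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: 2*dlnL = %.4f, df = %d, p = %.4g\n",
              x$stat, x$df, x$p_value))
  cat(sprintf("  critical value at level %.4g: %.4f -> %s\n",
              x$level, x$critical_value,
              if (x$reject) "reject the simpler model" else "do not reject"))
  invisible(x)
}

#' Rank substitution models by AIC
#'
#' Fits each candidate on the same fixed topology (the NJ tree on JC
#' distances unless `tree` is given) and ranks by `AIC = 2k - 2 lnL`,
#' breaking ties in favour of fewer parameters.  Candidates whose fit fails
#' are dropped with a warning.
#'
#' @param aln an [alignment()].
#' @param candidates character vector of model strings, e.g.
#'   `c("JC", "HKY+G", "GTR+G+I")`.
#' @param tree optional fixed `phylo` topology.
#' @param k gamma categories for +G candidates.
#' @return data frame with columns `model`, `lnL`, `n_free_params`, `AIC`,
#'   sorted ascending by AIC; attribute `fits` holds the [phylo_ml()]
#'   objects in the same order.
#' @export
select_model <- function(aln, candidates, tree = NULL, k = 8L) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  if (is.null(tree)) tree <- nj_tree(jc_distance_matrix(aln))
  fits <- list()
  for (cand in candidates) {
    f <- tryCatch(phylo_ml(aln, model = cand, k = k, tree = tree,
                           search = "fixed"),
                  error = function(e) {
                    warning(sprintf("candidate '%s' failed: %s",
                                    cand, conditionMessage(e)))
                    NULL
                  })
    if (!is.null(f)) fits[[cand]] <- f
  }
  if (length(fits) == 0L) stop("all candidate fits failed")
  tab <- data.frame(
    model = names(fits),
    lnL = vapply(fits, function(f) f$lnL, numeric(1)),
    n_free_params = vapply(fits, function(f) f$n_free_params, numeric(1)))
  tab$AIC <- 2 * tab$n_free_params - 2 * tab$lnL
  ord <- order(tab$AIC, tab$n_free_params)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
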