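# Maximum-likelihood fitting of GTR-family substitution models.
#
# The optimizer is plain coordinate ascent: a branch-length sweep (one
# bounded 1-D golden-section search per edge, against cached partial
# likelihoods so each candidate length costs a single 4x4 product), then the
# gamma shape, then p_inv, then the exchangeabilities, repeated in that fixed
# order until the log-likelihood improves by less than `tol_lnl`.

MODEL_FAMILY <- c("JC", "HKY", "GTR")

parse_model_spec <- function(spec) {
  s <- toupper(gsub("\\s", "", spec))
  s <- gsub("GAMMA", "G", s)
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  if (!base %in% MODEL_FAMILY) {
    stop(sprintf("unknown model '%s' (expected one of %s, optionally +G, +I)",
                 spec, paste(MODEL_FAMILY, collapse = "/")))
  }
  extras <- parts[-1]
  if (!all(extras %in% c("G", "I"))) {
    stop(sprintf("unknown model component in '%s'", spec))
  }
  list(base = base, gamma = "G" %in% extras, inv = "I" %in% extras,
       label = paste(c(base, intersect(c("G", "I"), extras)), collapse = "+"))
}

n_free_params_spec <- function(spec, n_tips) {
  spec <- if (is.character(spec)) parse_model_spec(spec) else spec
  nb <- if (n_tips <= 2) 1L else 2L * n_tips - 3L
  k <- switch(spec$base, JC = 0L, HKY = 1L + 3L, GTR = 5L + 3L)
  nb + k + as.integer(spec$gamma) + as.integer(spec$inv)
}

empirical_base_freqs <- function(aln) {
  m <- unclass(aln)
  counts <- vapply(NUC, function(s) sum(m == s), numeric(1))
  counts <- counts + 1  # pseudocount: frequencies must stay positive
  counts / sum(counts)
}

build_model <- function(spec, pi, pars, k_gamma) {
  rates <- switch(spec$base,
    JC = rep(1, 6),
    HKY = c(1, pars$kappa, 1, 1, pars$kappa, 1),
    GTR = c(pars$exch, 1))
  subst_model(rates = rates,
              pi = if (spec$base == "JC") rep(0.25, 4) else pi,
              alpha = if (spec$gamma) pars$alpha else NULL,
              p_inv = if (spec$inv) pars$p_inv else NULL,
              k = k_gamma)
}

# --- cached partial likelihoods for fast per-edge length optimization ------

# For each gamma category: D[[node]] = downward partials (4 x npat) and
# F[[edge]] = pi-weighted context of the rest of the tree seen across that
# edge, so that the per-pattern likelihood in category k is
# colSums(F[[e]] * P(t_e, r_k) %*% D[[child(e)]]) for ANY edge e.
edge_caches <- function(tree, patt, model) {
  rc <- model_rate_categories(model)
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  root <- ntip + 1L
  npat <- patt$npat
  out <- vector("list", length(rc$rates))
  child_edges <- split(seq_len(nedge), tree$edge[, 1])
  for (k in seq_along(rc$rates)) {
    Ptab <- lapply(tree$edge.length, function(t)
      transition_probs(model, t, rc$rates[k]))
    D <- vector("list", ntip + tree$Nnode)
    for (i in seq_len(ntip)) D[[i]] <- patt$tips[[tree$tip.label[i]]]
    Msg <- vector("list", nedge)
    for (e in seq_len(nedge)) {   # postorder
      ch <- tree$edge[e, 2]
      Msg[[e]] <- Ptab[[e]] %*% D[[ch]]
      par <- tree$edge[e, 1]
      D[[par]] <- if (is.null(D[[par]])) Msg[[e]] else D[[par]] * Msg[[e]]
    }
    Fctx <- vector("list", nedge)
    Ctx <- vector("list", ntip + tree$Nnode)
    Ctx[[root]] <- matrix(model$pi, 4, npat)
    for (e in rev(seq_len(nedge))) {  # preorder
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sibs <- setdiff(child_edges[[as.character(par)]], e)
      Fe <- Ctx[[par]]
      for (s in sibs) Fe <- Fe * Msg[[s]]
      Fctx[[e]] <- Fe
      if (ch > ntip) Ctx[[ch]] <- crossprod(Ptab[[e]], Fe)
    }
    out[[k]] <- list(D = D, F = Fctx, rate = rc$rates[k], w = rc$weights[k])
  }
  out
}

# Log-likelihood as a function of one edge length, via the caches.
lnl_edge_length <- function(t, e, tree, patt, model, caches) {
  pinv <- if (is.null(model$p_inv)) 0 else model$p_inv
  ch <- tree$edge[e, 2]
  mix <- 0
  for (ck in caches) {
    P <- transition_probs(model, t, ck$rate)
    mix <- mix + ck$w * colSums(ck$F[[e]] * (P %*% ck$D[[ch]]))
  }
  sl <- pinv * patt$inv_mass + (1 - pinv) * mix
  if (any(sl <= 0)) return(-Inf)
  sum(patt$weights * log(sl))
}

sweep_branch_lengths <- function(tree, patt, model, bl_max = 20,
                                 refresh_every = 1L) {
  nedge <- nrow(tree$edge)
  caches <- edge_caches(tree, patt, model)
  for (e in seq_len(nedge)) {
    if (e > 1L && (e - 1L) %% refresh_every == 0L) {
      caches <- edge_caches(tree, patt, model)
    }
    cur <- tree$edge.length[e]
    f <- function(t) lnl_edge_length(t, e, tree, patt, model, caches)
    opt <- stats::optimize(f, interval = c(1e-9, bl_max),
                           maximum = TRUE, tol = 1e-6)
    if (opt$objective > f(cur)) tree$edge.length[e] <- opt$maximum
  }
  tree
}

# --- coordinate ascent over model parameters -------------------------------

fit_on_tree <- function(aln, tree, spec, k_gamma = 8L, tol_lnl = 1e-4,
                        max_rounds = 25L) {
  spec <- if (is.character(spec)) parse_model_spec(spec) else spec
  tree <- prep_tree(tree, rownames(aln))
  tree$edge.length[tree$edge.length < 1e-9] <- 1e-9
  pi <- empirical_base_freqs(aln)
  pars <- list(kappa = 2, exch = rep(1, 5), alpha = 0.5, p_inv = 0.1)
  model <- build_model(spec, pi, pars, k_gamma)
  patt <- compress_patterns(aln, model$pi)
  lnl <- .loglik_patterns(tree, patt, model)
  if (!is.finite(lnl)) stop("optimization error: non-finite initial lnL")

  line_search <- function(f, lower, upper, cur, log_scale = TRUE) {
    # bounded 1-D search; returns the better of current and optimum
    g <- if (log_scale) function(x) f(exp(x)) else f
    iv <- if (log_scale) log(c(lower, upper)) else c(lower, upper)
    opt <- stats::optimize(g, interval = iv, maximum = TRUE, tol = 1e-4)
    val <- if (log_scale) exp(opt$maximum) else opt$maximum
    if (opt$objective > f(cur)) val else cur
  }

  for (round in seq_len(max_rounds)) {
    lnl_prev <- lnl
    tree <- sweep_branch_lengths(tree, patt, model)
    if (spec$gamma) {
      f <- function(a) {
        m <- model; m$alpha <- a
        .loglik_patterns(tree, patt, m)
      }
      pars$alpha <- line_search(f, 0.01, 1e4, pars$alpha)
      model$alpha <- pars$alpha
    }
    if (spec$inv) {
      f <- function(p) {
        m <- model; m$p_inv <- p
        .loglik_patterns(tree, patt, m)
      }
      pars$p_inv <- line_search(f, 0, 0.999, pars$p_inv, log_scale = FALSE)
      model$p_inv <- pars$p_inv
    }
    if (spec$base == "HKY") {
      f <- function(kap) {
        p2 <- pars; p2$kappa <- kap
        .loglik_patterns(tree, patt, build_model(spec, pi, p2, k_gamma))
      }
      pars$kappa <- line_search(f, 1e-3, 200, pars$kappa)
      model <- build_model(spec, pi, pars, k_gamma)
    } else if (spec$base == "GTR") {
      for (i in seq_len(5)) {
        f <- function(r) {
          p2 <- pars; p2$exch[i] <- r
          .loglik_patterns(tree, patt, build_model(spec, pi, p2, k_gamma))
        }
        pars$exch[i] <- line_search(f, 1e-4, 200, pars$exch[i])
      }
      model <- build_model(spec, pi, pars, k_gamma)
    }
    lnl <- .loglik_patterns(tree, patt, model)
    if (!is.finite(lnl)) {
      stop(sprintf("optimization error: non-finite lnL at round %d (alpha=%s, p_inv=%s)",
                   round, format(pars$alpha), format(pars$p_inv)))
    }
    if (lnl - lnl_prev < tol_lnl) break
  }
  list(lnl = lnl, tree = tree, model = model, spec = spec, pars = pars)
}

#' Fit a substitution model (and optionally the tree) by maximum likelihood
#'
#' The central fitting function of the package.  Given an alignment, fits a
#' member of the nested model family \{JC, HKY, GTR\} x \{plain, +I, +G,
#' +G+I\} by Felsenstein-pruning likelihood and coordinate ascent.  With
#' `search = "nni"` the topology is also optimized by hill climbing over
#' nearest-neighbour interchanges starting from a neighbor-joining tree;
#' with `search = "fixed"` only branch lengths and model parameters are
#' optimized on the supplied (or NJ) topology.
#'
#' Base frequencies are fixed at their empirical values (counted from the
#' alignment) for HKY and GTR, and at 1/4 for JC.
#'
#' @param aln an [alignment()].
#' @param model model string, e.g. `"GTR+G+I"`, `"GTR+I"`, `"JC+G"`, `"HKY"`.
#' @param k number of discrete gamma categories (used by +G models).
#' @param tree optional starting `phylo` tree; defaults to the NJ tree on
#'   JC distances.
#' @param search `"fixed"` (default) or `"nni"`.
#' @param tol_lnl convergence threshold on the log-likelihood improvement
#'   per coordinate-ascent round (and per accepted NNI move).
#' @param max_rounds cap on coordinate-ascent rounds.
#' @return an object of class `"phylo_ml"` with components `lnL`, `tree`,
#'   `model` (a [subst_model()]), `n_free_params`, `model_label`, `n_sites`,
#'   `n_tips`.
#' @examples
#' set.seed(1)
#' tr <- simulate_tree(5, seed = 1)
#' aln <- evolve_sequences(tr, subst_model(), length = 200, seed = 2)
#' fit <- phylo_ml(aln, model = "JC", tree = tr)
#' fit
#' @seealso [lrt()], [select_model()], [tree_log_likelihood()]
#' @export
phylo_ml <- function(aln, model = "GTR+G+I", k = 8L, tree = NULL,
                     search = c("fixed", "nni"), tol_lnl = 1e-4,
                     max_rounds = 25L) {
  search <- match.arg(search)
  spec <- parse_model_spec(model)
  if (is.null(tree)) {
    tree <- nj_tree(jc_distance_matrix(aln))
  }
  tree <- ape::unroot(tree)
  if (search == "nni" && nrow(aln) >= 4L) {
    res <- nni_climb(aln, tree, spec, k_gamma = k, tol_lnl = tol_lnl,
                     max_rounds = max_rounds)
  } else {
    res <- fit_on_tree(aln, tree, spec, k_gamma = k, tol_lnl = tol_lnl,
                       max_rounds = max_rounds)
  }
  structure(list(lnL = res$lnl, tree = res$tree, model = res$model,
                 n_free_params = n_free_params_spec(spec, nrow(aln)),
                 model_label = spec$label, n_sites = ncol(aln),
                 n_tips = nrow(aln), search = search),
            class = "phylo_ml")
}

# NNI hill climbing: evaluates both rearrangements of each internal edge in
# the deterministic order produced by phangorn::nni, accepting the first
# move that improves lnL by more than tol_lnl, then restarting the scan.
nni_climb <- function(aln, tree, spec, k_gamma, tol_lnl, max_rounds,
                      max_moves = 50L) {
  fit <- fit_on_tree(aln, tree, spec, k_gamma, tol_lnl, max_rounds)
  moves <- 0L
  repeat {
    improved <- FALSE
    neighbours <- phangorn::nni(fit$tree)
    for (ci in seq_along(neighbours)) {
      cand <- neighbours[[ci]]  # [[ restores tip labels on multiPhylo
      cand$edge.length <- rep(mean(fit$tree$edge.length), nrow(cand$edge))
      cf <- fit_on_tree(aln, cand, spec, k_gamma, tol_lnl,
                        max_rounds = 4L)
      if (cf$lnl > fit$lnl + tol_lnl) {
        fit <- fit_on_tree(aln, cf$tree, spec, k_gamma, tol_lnl, max_rounds)
        improved <- TRUE
        moves <- moves + 1L
        break
      }
    }
    if (!improved || moves >= max_moves) break
  }
  fit
}

# --- S3 methods -------------------------------------------------------------

#' @export
print.phylo_ml <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit: %s model, %d sequences, %d sites\n",
              x$model_label, x$n_tips, x$n_sites))
  cat(sprintf("  log-likelihood: %.4f  (free parameters: %d)\n",
              x$lnL, x$n_free_params))
  if (!is.null(x$model$alpha)) {
    cat(sprintf("  gamma shape alpha: %.4g (%d categories)\n",
                x$model$alpha, x$model$k))
  }
  if (!is.null(x$model$p_inv)) {
    cat(sprintf("  proportion of invariant sites: %.4g\n", x$model$p_inv))
  }
  invisible(x)
}

#' @export
summary.phylo_ml <- function(object, ...) {
  print(object)
  cat(sprintf("  AIC: %.4f\n", 2 * object$n_free_params - 2 * object$lnL))
  cat("  tree (Newick):", write_newick(object$tree), "\n")
  print(object$model)
  invisible(object)
}

#' @export
logLik.phylo_ml <- function(object, ...) {
  structure(object$lnL, df = object$n_free_params,
            nobs = object$n_sites, class = "logLik")
}

#' @export
coef.phylo_ml <- function(object, ...) {
  m <- object$model
  out <- c(stats::setNames(m$rates, c("AC", "AG", "AT", "CG", "CT", "GT")),
           stats::setNames(m$pi, paste0("pi_", NUC)))
  if (!is.null(m$alpha)) out <- c(out, alpha = m$alpha)
  if (!is.null(m$p_inv)) out <- c(out, p_inv = m$p_inv)
  out
}

#' @export
plot.phylo_ml <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
}

#' Simulate alignments from a fitted model
#'
#' Draws new alignments on the fitted tree under the fitted substitution
#' model (parametric bootstrap style).
#' @param object a [phylo_ml()] fit.
#' @param nsim number of alignments.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of alignments (length `nsim`).
#' @export
simulate.phylo_ml <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i) {
    evolve_sequences(object$tree, object$model, length = object$n_sites,
                     seed = seed + i - 1L)
  })
}
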