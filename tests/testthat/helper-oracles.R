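# Independent oracles and shared fixtures for the test suite.  The oracles
# deliberately use brute force (exhaustive enumeration) and closed forms,
# never the implementation's own code paths.

NUC4 <- c("A", "C", "G", "T")

random_dna <- function(n, len, seed, ids = paste0("s", seq_len(n))) {
  set.seed(seed)
  alignment(stats::setNames(
    replicate(n, paste(sample(NUC4, len, TRUE), collapse = "")), ids))
}

# Exhaustive-enumeration log-likelihood: sums over every assignment of
# internal-node states, per site, per rate category.  Usable up to ~5 taxa.
brute_force_lnl <- function(aln, tree, model) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  rc <- if (is.null(model$alpha)) list(rates = 1, weights = 1)
        else discrete_gamma_rates(model$alpha, model$k)
  pinv <- if (is.null(model$p_inv)) 0 else model$p_inv
  m <- unclass(aln)
  total <- 0
  states <- as.matrix(expand.grid(rep(list(1:4), nint)))
  for (site in seq_len(ncol(m))) {
    col <- m[, site]
    obs <- unique(col[col %in% NUC4])
    inv <- if (length(obs) == 0) 1 else if (length(obs) == 1) model$pi[obs] else 0
    mix <- 0
    for (k in seq_along(rc$rates)) {
      P <- lapply(tree$edge.length, function(t)
        transition_probs(model, t, rc$rates[k]))
      tot <- 0
      for (r in seq_len(nrow(states))) {
        st <- function(node) {
          if (node <= ntip) {
            b <- col[tree$tip.label[node]]
            if (b %in% NUC4) match(b, NUC4) else NA
          } else states[r, node - ntip]
        }
        pr <- model$pi[states[r, 1]]
        for (e in seq_len(nrow(tree$edge))) {
          ch <- st(tree$edge[e, 2])
          if (is.na(ch)) next  # missing leaf marginalises to 1
          pr <- pr * P[[e]][st(tree$edge[e, 1]), ch]
        }
        tot <- tot + pr
      }
      mix <- mix + rc$weights[k] * tot
    }
    total <- total + log(pinv * inv + (1 - pinv) * mix)
  }
  unname(total)
}

# Exhaustive minimum-change count for one column: minimises the number of
# edges whose endpoints differ, over all internal labelings (and over all
# completions of N/- leaves).
brute_force_steps <- function(tree, col) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  free_leaves <- which(!(col[tree$tip.label] %in% NUC4))
  nfree <- length(free_leaves)
  grid <- as.matrix(expand.grid(rep(list(1:4), nint + nfree)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- integer(ntip + nint)
    for (i in seq_len(ntip)) {
      b <- col[tree$tip.label[i]]
      st[i] <- if (b %in% NUC4) match(b, NUC4) else 0L
    }
    if (nfree > 0) st[free_leaves] <- grid[r, nint + seq_len(nfree)]
    st[ntip + seq_len(nint)] <- grid[r, seq_len(nint)]
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# Mosaic alignment: left half evolved on one genealogy, right half on an
# independent one (the classic recombination signal).
make_mosaic <- function(n_taxa, half_len, seed) {
  trA <- simulate_tree(n_taxa, seed = seed, mean_branch = 0.05)
  trB <- simulate_tree(n_taxa, seed = seed + 1L, mean_branch = 0.05)
  a1 <- evolve_sequences(trA, subst_model(), half_len, seed = seed + 2L)
  a2 <- evolve_sequences(trB, subst_model(), half_len, seed = seed + 3L)
  ids <- trA$tip.label
  alignment(stats::setNames(
    paste0(alignment_strings(a1)[ids], alignment_strings(a2)[ids]), ids))
}

# Haplotype pair differing at exactly n_diff positions.
make_hap_pair <- function(len, n_diff, seed) {
  set.seed(seed)
  a <- sample(NUC4, len, TRUE)
  b <- a
  idx <- sample(len, n_diff)
  for (i in idx) b[i] <- sample(setdiff(NUC4, a[i]), 1)
  list(hapA = paste(a, collapse = ""), hapB = paste(b, collapse = ""),
       diff_sites = sort(idx))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "virophase", mustWork = TRUE)
}
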