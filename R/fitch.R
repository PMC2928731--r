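# Fitch parsimony: minimum number of state changes per character on a fixed
# topology.  State sets are bitmasks, so the same pass serves nucleotide
# columns (N/- = full set) and arbitrary categorical characters (used by the
# label-association permutation test).

# chars: character matrix (rows = taxa named like tree tips, cols = sites);
# state_of: function mapping one observed value to an integer bitmask
# (0 = missing -> full set).  Returns integer vector of per-column steps.
fitch_steps_matrix <- function(tree, chars, n_states, state_of) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  full <- bitwShiftL(1L, n_states) - 1L
  nsite <- ncol(chars)
  sets <- matrix(0L, ntip + tree$Nnode, nsite)
  for (i in seq_len(ntip)) {
    v <- vapply(chars[tree$tip.label[i], ], state_of, integer(1))
    v[v == 0L] <- full
    sets[i, ] <- v
  }
  steps <- integer(nsite)
  seen <- logical(ntip + tree$Nnode)
  seen[seq_len(ntip)] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (!seen[par]) {
      sets[par, ] <- sets[ch, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(sets[par, ], sets[ch, ])
      empty <- inter == 0L
      steps <- steps + empty
      sets[par, ] <- ifelse(empty, bitwOr(sets[par, ], sets[ch, ]), inter)
    }
  }
  steps
}

nuc_state_mask <- function(b) {
  switch(b, A = 1L, C = 2L, G = 4L, T = 8L, 0L)
}

#' Minimum mutational steps per site
#'
#' Fitch parsimony on each alignment column over the given topology.
#' `N` and `-` carry the full state set (they never force a change).
#' Constant columns score zero; the score equals the true minimum number of
#' changes over all internal labelings.
#'
#' @param aln an [alignment()].
#' @param tree a `phylo` tree whose tips match the record ids.
#' @param frame reading-frame offset (0, 1 or 2) used to annotate codon
#'   index and codon position.
#' @return data frame of class `"site_steps"` with columns `site`,
#'   `min_steps`, `codon_index`, `codon_position` (NA outside complete
#'   codons).
#' @export
fitch_site_steps <- function(aln, tree, frame = 0L) {
  tree <- prep_tree(tree, rownames(aln))
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  m <- unclass(aln)
  steps <- fitch_steps_matrix(tree, m, 4L, nuc_state_mask)
  site <- seq_len(ncol(m))
  off <- site - frame  # 1-based position within the framed region
  codon_index <- ifelse(off >= 1, (off - 1) %/% 3 + 1, NA_integer_)
  codon_position <- ifelse(off >= 1, (off - 1) %% 3 + 1, NA_integer_)
  # trailing partial codon is not annotated
  n_complete <- (ncol(m) - frame) %/% 3
  codon_index[!is.na(codon_index) & codon_index > n_complete] <- NA_integer_
  codon_position[is.na(codon_index)] <- NA_integer_
  structure(data.frame(site = site, min_steps = steps,
                       codon_index = codon_index,
                       codon_position = codon_position),
            class = c("site_steps", "data.frame"))
}

#' @export
plot.site_steps <- function(x, ...) {
  graphics::plot(x$site, x$min_steps, type = "h",
                 xlab = "alignment position",
                 ylab = "minimum mutational steps", ...)
}

#' Permutation test for association between leaf labels and the tree
#'
#' Operationalises "no clustering of haplotypes by host species": the
#' statistic is the Fitch parsimony score of the categorical label character
#' on the tree (few steps = strong clustering), compared against labels
#' permuted across leaves.  `p = (1 + #\{permuted <= observed\}) /
#' (n_perm + 1)`.
#'
#' @param tree a `phylo` tree.
#' @param labels named character vector: leaf id -> category; at least two
#'   categories, each with at least two members.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `statistic` (observed steps), `p_value`, `n_perm`.
#' @export
label_association_test <- function(tree, labels, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  labels <- labels[tree$tip.label]
  if (any(is.na(labels))) stop("labels must cover every leaf")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("degenerate input: need >= 2 categories with >= 2 members each")
  }
  cats <- names(tab)
  mask_of <- function(v) bitwShiftL(1L, match(v, cats) - 1L)
  score <- function(lab) {
    chars <- matrix(lab, ncol = 1, dimnames = list(tree$tip.label, NULL))
    fitch_steps_matrix(tree, chars, length(cats), mask_of)
  }
  obs <- score(labels)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) score(sample(labels)),
                   integer(1))
    list(statistic = obs,
         p_value = (1 + sum(perm <= obs)) / (n_perm + 1),
         n_perm = n_perm)
  })
}
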