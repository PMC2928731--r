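# Simulators for validation: random genealogies, haplotype alignments under
# GTR+G+I, two-haplotype mixture peak signals, and missing-data patterns.

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards.
with_seed <- function(seed, expr) {
  force(seed)  # any RNG use in the caller's seed expression happens first
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a random unrooted genealogy
#'
#' Coalescent-style random joining: starting from the `n_taxa` tips, pairs
#' of lineages are merged uniformly at random until three remain, which are
#' joined at the (unrooted) root.  Branch lengths are i.i.d. exponential
#' with mean `mean_branch` substitutions/site.  The result is an unrooted
#' binary tree: `n_taxa` leaves, `n_taxa - 2` internal nodes and
#' `2 n_taxa - 3` edges.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @param mean_branch mean branch length (> 0).
#' @param labels optional leaf labels (default `t1, t2, ...`).
#' @return a `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, mean_branch = 0.1,
                          labels = paste0("t", seq_len(n_taxa))) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (mean_branch <= 0) stop("mean_branch must be > 0")
  with_seed(seed, {
    if (n_taxa == 2L) {
      txt <- sprintf("(%s:%f,%s:%f);", labels[1],
                     stats::rexp(1, 1 / mean_branch),
                     labels[2], stats::rexp(1, 1 / mean_branch))
      return(parse_newick(txt))
    }
    sub <- as.list(labels)
    while (length(sub) > 3L) {
      ij <- sample.int(length(sub), 2L)
      merged <- sprintf("(%s:%f,%s:%f)",
                        sub[[ij[1]]], stats::rexp(1, 1 / mean_branch),
                        sub[[ij[2]]], stats::rexp(1, 1 / mean_branch))
      sub[[ij[1]]] <- merged
      sub[[ij[2]]] <- NULL
    }
    bl <- stats::rexp(3, 1 / mean_branch)
    txt <- sprintf("(%s:%f,%s:%f,%s:%f);",
                   sub[[1]], bl[1], sub[[2]], bl[2], sub[[3]], bl[3])
    parse_newick(txt)
  })
}

#' Evolve sequences along a tree under GTR+G+I
#'
#' Each site independently draws its rate: invariant (rate 0) with
#' probability `p_inv`, otherwise a uniformly chosen discrete-gamma category
#' rate — the same discrete approximation used by the likelihood engine, so
#' simulation and inference are mutually consistent.  The root state is
#' drawn from the stationary frequencies and substituted along each edge
#' with the model's transition probabilities.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param model a [subst_model()].
#' @param length number of sites (>= 1).
#' @param seed integer seed.
#' @return an [alignment()] with one record per leaf.
#' @export
evolve_sequences <- function(tree, model, length, seed = 1L) {
  if (length < 1L) stop("length must be >= 1")
  if (length(tree$tip.label) < 2L) stop("tree needs at least 2 leaves")
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  with_seed(seed, {
    rc <- model_rate_categories(model)
    pinv <- if (is.null(model$p_inv)) 0 else model$p_inv
    rate <- ifelse(stats::runif(length) < pinv, 0,
                   sample(rc$rates, length, replace = TRUE))
    states <- matrix(0L, ntip + tree$Nnode, length)
    states[root, ] <- sample.int(4L, length, replace = TRUE, prob = model$pi)
    urates <- sort(unique(rate))
    # preorder: parents before children
    for (e in rev(seq_len(nrow(tree$edge)))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]
      for (r in urates) {
        idx <- which(rate == r)
        if (length(idx) == 0L) next
        if (r == 0 || t_e == 0) {
          states[ch, idx] <- states[par, idx]
        } else {
          P <- transition_probs(model, t_e, r)
          cum <- t(apply(P, 1, cumsum))
          u <- stats::runif(length(idx))
          ps <- states[par, idx]
          states[ch, idx] <- pmin(rowSums(cum[ps, , drop = FALSE] < u) + 1L, 4L)
        }
      }
    }
    m <- matrix(NUC[states[seq_len(ntip), , drop = FALSE]], ntip, length)
    rownames(m) <- tree$tip.label
    alignment(m)
  })
}

#' Simulate a two-haplotype mixture peak table
#'
#' Emulates the Sanger signal of a sample infected by two haplotypes at
#' relative abundances `ratio` and `1 - ratio`: at every position, on each
#' strand independently, the base of the major haplotype receives intensity
#' `ratio` and the minor base `1 - ratio` (summed where they coincide), plus
#' Gaussian noise truncated at zero.
#'
#' @param hapA,hapB equal-length gap-free sequence strings or single-row
#'   alignments; `hapA` is the major haplotype.
#' @param ratio major-haplotype abundance in `(0.5, 1]`.
#' @param noise_sd noise standard deviation (intensity units; >= 0).
#' @param seed integer seed.
#' @return a [peak_table()] covering both strands.
#' @export
simulate_mixture_peaks <- function(hapA, hapB, ratio = 0.7, noise_sd = 0.02,
                                   seed = 1L) {
  a <- toupper(if (is.character(hapA)) strsplit(hapA, "")[[1]] else as.vector(unclass(hapA)))
  b <- toupper(if (is.character(hapB)) strsplit(hapB, "")[[1]] else as.vector(unclass(hapB)))
  if (length(a) != length(b)) stop("haplotypes must have equal length")
  if (any(!(c(a, b) %in% NUC))) stop("haplotypes must be gap-free A/C/G/T")
  if (ratio <= 0.5 || ratio > 1) stop("ratio must lie in (0.5, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- length(a)
  with_seed(seed, {
    # rows ordered position-major, strands F then R; both strands noised
    # independently
    base_int <- matrix(0, n, 4, dimnames = list(NULL, NUC))
    base_int[cbind(seq_len(n), match(a, NUC))] <- ratio
    idx_b <- cbind(seq_len(n), match(b, NUC))
    base_int[idx_b] <- base_int[idx_b] + (1 - ratio)
    ints <- base_int[rep(seq_len(n), each = 2L), , drop = FALSE]
    ints <- pmax(ints + matrix(stats::rnorm(2L * n * 4L, 0, noise_sd),
                               2L * n, 4L), 0)
    peak_table(data.frame(position = rep(seq_len(n), each = 2L),
                          strand = rep(c("F", "R"), n),
                          A = ints[, "A"], C = ints[, "C"],
                          G = ints[, "G"], T = ints[, "T"]))
  })
}

#' Replace bases by N to emulate low-quality stretches
#'
#' `mode = "ends"` mimics Sanger fragments trimmed for low quality near the
#' primers: the Ns are split between the two fragment ends.  `mode =
#' "random"` scatters them uniformly.  Exactly `round(fraction * length)`
#' bases are replaced.
#'
#' @param record a sequence string (named, or supply `id`).
#' @param fraction fraction of bases to mask, in `[0, 1)`.
#' @param seed integer seed (used by both modes: `ends` draws the split).
#' @param mode `"ends"` or `"random"`.
#' @return the masked sequence string.
#' @export
inject_missing <- function(record, fraction, seed = 1L,
                           mode = c("ends", "random")) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  bases <- strsplit(record, "")[[1]]
  n <- length(bases)
  k <- round(fraction * n)
  if (k == 0L) return(record)
  with_seed(seed, {
    if (mode == "ends") {
      k_head <- sample.int(k + 1L, 1L) - 1L  # uniform split over the two ends
      k_tail <- k - k_head
      if (k_head > 0L) bases[seq_len(k_head)] <- "N"
      if (k_tail > 0L) bases[seq(n - k_tail + 1L, n)] <- "N"
    } else {
      bases[sample.int(n, k)] <- "N"
    }
    paste(bases, collapse = "")
  })
}
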