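# Pairwise homoplasy index (PHI) test for recombination.
#
# Under clonal evolution every pair of sites fits one genealogy; under
# recombination, nearby site pairs stay compatible while distant pairs
# accumulate incompatibility.  PHI is the mean refined incompatibility over
# nearby informative-site pairs; its permutation null shuffles the order of
# the informative sites, destroying spatial signal while preserving the
# columns themselves.

is_informative <- function(col) {
  col <- col[col %in% NUC]
  tab <- table(col)
  sum(tab >= 2L) >= 2L
}

# integer encoding: A..T -> 1..4, N/- -> 0
encode_col <- function(col) {
  v <- match(col, NUC)
  v[is.na(v)] <- 0L
  v
}

# refined incompatibility on integer-coded columns (hot path)
pair_score_int <- function(a, b) {
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  joint <- unique(a * 5L + b)
  sa <- unique(a); sb <- unique(b)
  nv <- length(sa) + length(sb)
  # union-find over marginal states (<= 8 vertices)
  parent <- seq_len(nv)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (js in joint) {
    ia <- match(js %/% 5L, sa)
    ib <- length(sa) + match(js %% 5L, sb)
    ra <- find(ia); rb <- find(ib)
    if (ra != rb) parent[rb] <- ra
  }
  n_comp <- length(unique(vapply(seq_len(nv), find, integer(1))))
  max(0L, length(joint) - nv + n_comp)
}

#' Refined incompatibility score of two sites
#'
#' The minimum number of extra state changes needed to explain both columns
#' on a single tree, beyond what each column needs alone.  Computed exactly
#' as the cycle rank `E - (k_i + k_j) + C` of the partition intersection
#' graph (marginal states as vertices, one edge per observed joint state,
#' `C` connected components): zero iff the graph is a forest, i.e. the two
#' sites fit one tree.  For two binary sites this reduces to the four-gamete
#' test: 1 iff all four combinations occur.  Sequences carrying N/- at
#' either site are excluded.
#'
#' @param col_i,col_j character vectors (alignment columns), both
#'   parsimony-informative.
#' @return non-negative integer score.
#' @export
site_pair_incompatibility <- function(col_i, col_j) {
  if (!is_informative(col_i) || !is_informative(col_j)) {
    stop("both columns must be parsimony-informative")
  }
  as.integer(pair_score_int(encode_col(col_i), encode_col(col_j)))
}

informative_columns <- function(aln) {
  m <- unclass(aln)
  idx <- which(vapply(seq_len(ncol(m)), function(j) is_informative(m[, j]),
                      logical(1)))
  list(cols = lapply(idx, function(j) m[, j]),
       coded = lapply(idx, function(j) encode_col(m[, j])),
       positions = idx)
}

# in-window (i, j) index pairs over the ORDERED informative sites
window_pairs <- function(positions, window) {
  n <- length(positions)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  jmax <- findInterval(positions + window, positions)
  cnt <- pmax(jmax - seq_len(n), 0L)
  i <- rep.int(seq_len(n), cnt)
  j <- unlist(lapply(seq_len(n), function(k)
    if (cnt[k] > 0L) (k + 1L):jmax[k] else integer(0)), use.names = FALSE)
  cbind(i, j)
}

# All-pairs score matrix: scores depend only on the unordered column pair,
# so permutation replicates can reuse them by index.  Pairs of two-state
# columns reduce to the four-gamete test, evaluated for every pair at once
# by cross-products of presence indicators; pairs involving a 3+-state
# column (rare in nucleotide data) take the exact graph route.
pair_score_matrix <- function(coded) {
  n <- length(coded)
  S <- matrix(0L, n, n)
  if (n < 2L) return(S)
  # a state carried by a single sequence only ever adds a leaf edge to the
  # partition graph, so masking it leaves every pair score unchanged
  coded <- lapply(coded, function(v) {
    tab <- tabulate(v, nbins = 4L)
    v[v > 0L & tab[pmax(v, 1L)] == 1L] <- 0L
    v
  })
  cm <- do.call(cbind, coded)              # taxa x columns
  nstates <- apply(cm, 2, function(v) length(unique(v[v > 0L])))
  bin <- which(nstates == 2L)
  if (length(bin) >= 2L) {
    A <- matrix(0, nrow(cm), length(bin))  # indicator of the first state
    B <- A                                 # indicator of the second state
    for (jj in seq_along(bin)) {
      v <- cm[, bin[jj]]
      s <- unique(v[v > 0L])
      A[, jj] <- v == s[1]
      B[, jj] <- v == s[2]
    }
    four <- (crossprod(A) > 0) & (crossprod(B) > 0) &
            (crossprod(A, B) > 0) & (crossprod(B, A) > 0)
    S[bin, bin] <- as.integer(four)
  }
  multi <- which(nstates > 2L)
  for (i in multi) {
    for (j in seq_len(n)) {
      if (j == i) next
      S[i, j] <- S[j, i] <- pair_score_int(coded[[i]], coded[[j]])
    }
  }
  S
}

phi_from_scores <- function(S, perm, pairs) {
  if (nrow(pairs) == 0L) return(NA_real_)
  mean(S[cbind(perm[pairs[, 1]], perm[pairs[, 2]])])
}

#' PHI statistic
#'
#' Mean refined incompatibility over informative-site pairs whose physical
#' distance is at most `window` alignment positions.
#'
#' @param aln an [alignment()] with >= 4 records.
#' @param window maximum pair distance in sites (default 100).
#' @return list of class `"phi_result"` with `phi`,
#'   `n_informative_sites`, `n_informative_pairs`, `window`, `untestable`
#'   (TRUE when fewer than two informative sites, or no pair falls within
#'   the window).
#' @export
phi_statistic <- function(aln, window = 100L) {
  if (nrow(aln) < 4L) stop("need at least 4 sequences")
  info <- informative_columns(aln)
  if (length(info$cols) < 2L) {
    return(structure(list(phi = NA_real_, n_informative_sites = length(info$cols),
                          n_informative_pairs = 0L, window = window,
                          untestable = TRUE),
                     class = "phi_result"))
  }
  pairs <- window_pairs(info$positions, window)
  S <- pair_score_matrix(info$coded)
  phi <- phi_from_scores(S, seq_along(info$coded), pairs)
  structure(list(phi = phi, n_informative_sites = length(info$cols),
                 n_informative_pairs = nrow(pairs), window = window,
                 untestable = nrow(pairs) == 0L),
            class = "phi_result")
}

#' PHI permutation test for recombination
#'
#' The null distribution permutes the order of the informative sites
#' (columns are preserved; their spatial arrangement is destroyed).
#' Recombination makes nearby pairs unusually compatible, so small observed
#' phi is evidence for recombination:
#' `p = (1 + #\{phi_perm <= phi_obs\}) / (n_perm + 1)`.
#'
#' @param aln an [alignment()] with >= 4 records.
#' @param window maximum pair distance in sites.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return a `"phi_result"` with additional fields `p_value` and `n_perm`.
#' @export
phi_permutation_test <- function(aln, window = 100L, n_perm = 999L,
                                 seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  if (nrow(aln) < 4L) stop("need at least 4 sequences")
  info <- informative_columns(aln)
  n_info <- length(info$coded)
  pairs <- if (n_info >= 2L) window_pairs(info$positions, window)
           else matrix(integer(0), 0, 2)
  if (nrow(pairs) == 0L) {
    return(structure(list(phi = NA_real_, n_informative_sites = n_info,
                          n_informative_pairs = 0L, window = window,
                          untestable = TRUE, p_value = NA_real_,
                          n_perm = n_perm),
                     class = "phi_result"))
  }
  S <- pair_score_matrix(info$coded)
  obs <- structure(list(phi = phi_from_scores(S, seq_len(n_info), pairs),
                        n_informative_sites = n_info,
                        n_informative_pairs = nrow(pairs), window = window,
                        untestable = FALSE),
                   class = "phi_result")
  with_seed(seed, {
    perm_phi <- vapply(seq_len(n_perm), function(i) {
      phi_from_scores(S, sample.int(n_info), pairs)
    }, numeric(1))
    obs$p_value <- (1 + sum(perm_phi <= obs$phi)) / (n_perm + 1)
    obs$n_perm <- n_perm
    obs
  })
}

#' @export
print.phi_result <- function(x, ...) {
  if (isTRUE(x$untestable)) {
    cat("PHI test: untestable (too few informative sites in window)\n")
    return(invisible(x))
  }
  cat(sprintf("PHI = %.4f over %d informative-site pairs (window %d)\n",
              x$phi, x$n_informative_pairs, x$window))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  }
  invisible(x)
}
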