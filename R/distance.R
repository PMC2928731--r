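#' Jukes-Cantor distance matrix
#'
#' Pairwise JC69 distances `d = -(3/4) log(1 - 4p/3)`, with `p` the mismatch
#' fraction over positions where both sequences carry an unambiguous base
#' (A/C/G/T).  Pairs at or beyond the JC saturation point (`p >= 0.75`), or
#' with no comparable sites, are flagged and given the value `cap`.
#'
#' @param aln an [alignment()] with at least two records.
#' @param cap distance assigned to saturated/incomparable pairs.
#' @return list with `labels`, symmetric matrix `d`, and logical matrix
#'   `flagged` marking saturated or incomparable entries.
#' @export
jc_distance_matrix <- function(aln, cap = 5) {
  if (nrow(aln) < 2L) stop("need at least two records")
  m <- unclass(aln)
  ok <- m %in% NUC
  dim(ok) <- dim(m)
  allN <- which(rowSums(ok) == 0L)
  if (length(allN) > 0L) {
    stop(sprintf("record '%s' has no unambiguous bases", rownames(m)[allN[1]]))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  flagged <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- cap
        flagged[i, j] <- flagged[j, i] <- TRUE
        next
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- cap
        flagged[i, j] <- flagged[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  list(labels = rownames(m), d = d, flagged = flagged)
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on a distance matrix (via \pkg{ape}); negative
#' branch lengths are clamped to zero.  Saturated entries (see
#' [jc_distance_matrix()]) are used at their capped value with a warning.
#'
#' @param dm result of [jc_distance_matrix()], or a plain symmetric matrix.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (is.list(dm) && !is.null(dm$d)) {
    if (any(dm$flagged)) {
      warning("saturated distance entries present; proceeding with capped values")
    }
    d <- dm$d
  } else {
    d <- dm
  }
  if (nrow(d) < 2L) stop("need at least two taxa")
  if (nrow(d) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
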