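# Codon-level classification of observed differences, synonymous-site
# mutation-rate bound, and distinct-haplotype counting.

translate_codon <- function(codon) {
  if (any(!(codon %in% NUC))) return(NA_character_)
  seqinr::translate(tolower(codon))
}

consensus_codon <- function(aln, codon_index, frame) {
  start <- frame + (codon_index - 1L) * 3L + 1L
  m <- unclass(aln)
  vapply(start:(start + 2L), function(j) {
    col <- m[, j]
    col <- col[col %in% NUC]
    if (length(col) == 0L) return(NA_character_)
    names(which.max(table(col)))
  }, character(1))
}

#' Flag sites whose variation changes the encoded amino acid
#'
#' A variable site (`min_steps >= 1`) is flagged when substituting any pair
#' of bases observed in its column into the column-consensus codon yields
#' different amino acids.  Sites that are both flagged and hit repeatedly
#' (`min_steps >= 2`) are marked as recurrent amino-acid replacements.
#' A stop codon in the consensus translation produces a warning, and the
#' site is still processed.
#'
#' @param profile result of [fitch_site_steps()].
#' @param aln the [alignment()] the profile was computed from.
#' @param frame reading-frame offset (0, 1, 2); must match the profile's.
#' @return data frame with columns `site`, `min_steps`, `codon_index`,
#'   `codon_position`, `aa_change` (logical), `recurrent_aa` (logical).
#' @export
classify_recurrent_aa_changes <- function(profile, aln, frame = 0L) {
  if (ncol(aln) < 3L) stop("alignment must span at least one codon")
  m <- unclass(aln)
  out <- profile
  out$aa_change <- FALSE
  for (i in seq_len(nrow(out))) {
    if (out$min_steps[i] < 1L || is.na(out$codon_index[i])) next
    bases <- unique(m[, out$site[i]])
    bases <- bases[bases %in% NUC]
    if (length(bases) < 2L) next
    codon <- consensus_codon(aln, out$codon_index[i], frame)
    if (any(is.na(codon))) next
    cp <- out$codon_position[i]
    ref_aa <- translate_codon(codon)
    if (identical(ref_aa, "*")) {
      warning(sprintf("stop codon in consensus translation at codon %d",
                      out$codon_index[i]))
    }
    aas <- vapply(bases, function(b) {
      cd <- codon; cd[cp] <- b
      translate_codon(cd)
    }, character(1))
    out$aa_change[i] <- length(unique(aas)) > 1L
  }
  out$recurrent_aa <- out$aa_change & out$min_steps >= 2L
  out
}

#' Count synonymous and non-synonymous differences between two sequences
#'
#' Differences are classified one codon at a time: for a codon containing
#' exactly one differing, unambiguously compared position, the two variants
#' are substituted into the shared codon context and the encoded amino
#' acids compared.  Codons with two or more internal differences, or with
#' missing context (N/-), are counted as `ambiguous` — never silently
#' assigned.  Positions in a trailing partial codon are excluded.
#'
#' @param a,b equal-length sequence strings.
#' @param frame reading-frame offset (0, 1, 2).
#' @return list with integer counts `syn`, `nonsyn`, `ambiguous` (their sum
#'   is the number of differing comparable sites in complete codons).
#' @export
count_synonymous_diffs <- function(a, b, frame = 0L) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb)) stop("sequences must have equal length")
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  n <- length(va)
  n_codon <- (n - frame) %/% 3
  syn <- nonsyn <- amb <- 0L
  for (ci in seq_len(n_codon)) {
    pos <- frame + (ci - 1L) * 3L + (1:3)
    ca <- va[pos]; cb <- vb[pos]
    comparable <- ca %in% NUC & cb %in% NUC
    diffs <- which(comparable & ca != cb)
    if (length(diffs) == 0L) next
    if (length(diffs) >= 2L || !all(comparable)) {
      # multi-hit codon or missing context: amino-acid attribution per
      # individual site is not well defined
      amb <- amb + length(diffs)
      next
    }
    aa_a <- translate_codon(ca)
    cb2 <- ca; cb2[diffs] <- cb[diffs]
    aa_b <- translate_codon(cb2)
    if (identical(aa_a, aa_b)) syn <- syn + 1L else nonsyn <- nonsyn + 1L
  }
  list(syn = syn, nonsyn = nonsyn, ambiguous = amb)
}

#' Upper-bound estimate of the mutation rate from synonymous variation
#'
#' `rate = s_syn / (length * years)`: the number of variable synonymous
#' sites divided by the sequence length times the divergence time.  Treating
#' all synonymous variants as substitutions accumulated since divergence
#' makes this an upper bound.
#'
#' @param s_syn count of variable synonymous sites (>= 0).
#' @param length sequence length in bp (> 0).
#' @param years divergence time in years (> 0).
#' @return list of class `"rate_estimate"`: `s_syn`, `length`, `years`,
#'   `rate` (substitutions/site/year).
#' @examples
#' mutation_rate(3, 500, 11)$rate   # 5.5e-4
#' mutation_rate(10, 500, 11)$rate  # 1.8e-3
#' @export
mutation_rate <- function(s_syn, length, years) {
  if (length <= 0) stop("length must be > 0")
  if (years <= 0) stop("years must be > 0")
  if (s_syn < 0) stop("s_syn must be >= 0")
  structure(list(s_syn = s_syn, length = length, years = years,
                 rate = s_syn / (length * years)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("mutation rate: %d synonymous sites / (%d bp x %g yr) = %.3g substitutions/site/year\n",
              x$s_syn, x$length, x$years, x$rate))
  invisible(x)
}

#' Group records into distinct haplotypes
#'
#' `policy = "strict"` groups by exact string equality (the default for
#' headline haplotype counts).  `policy = "missing-tolerant"` single-links
#' records that agree at every position where both are non-N, so partially
#' sequenced records can join the haplotype they are consistent with (note
#' single linkage can merge chains through an N-rich record).
#'
#' @param aln an [alignment()].
#' @param policy `"strict"` or `"missing-tolerant"`.
#' @return list of class `"haplotype_groups"`: `groups` (list of record-id
#'   vectors), `n_distinct`, `policy`.
#' @export
distinct_haplotypes <- function(aln, policy = c("strict", "missing-tolerant")) {
  policy <- match.arg(policy)
  m <- unclass(aln)
  ids <- rownames(m)
  n <- nrow(m)
  if (policy == "strict") {
    key <- apply(m, 1, paste, collapse = "")
    groups <- split(ids, factor(key, levels = unique(key)))
    names(groups) <- NULL
  } else {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        both <- m[i, ] %in% NUC & m[j, ] %in% NUC
        if (all(m[i, both] == m[j, both])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    groups <- unname(split(ids, factor(roots, levels = unique(roots))))
  }
  structure(list(groups = groups, n_distinct = length(groups),
                 policy = policy),
            class = "haplotype_groups")
}

#' @export
print.haplotype_groups <- function(x, ...) {
  cat(sprintf("%d distinct haplotype(s) among %d record(s) [%s identity]\n",
              x$n_distinct, length(unlist(x$groups)), x$policy))
  for (g in x$groups) cat("  -", paste(g, collapse = ", "), "\n")
  invisible(x)
}
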