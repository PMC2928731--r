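# Haplotype phasing from Sanger double peaks.

# one intensity matrix per strand, rows named by position
strand_matrices <- function(peaks) {
  df <- as.data.frame(peaks)
  out <- list()
  for (s in c("F", "R")) {
    sub <- df[df$strand == s, , drop = FALSE]
    m <- as.matrix(sub[, NUC])
    rownames(m) <- as.character(sub$position)
    out[[s]] <- m
  }
  out
}
#
# A sample infected by two viral haplotypes shows two overlapping peaks at
# every site where they differ.  A site is only trusted as heterozygous when
# the secondary peak appears on BOTH strands with the same two base
# identities; relative peak height then assigns each variant to the
# high-abundance or low-abundance haplotype.

#' Call heterozygous sites from a two-strand peak table
#'
#' A position is called heterozygous iff on both strands the second-highest
#' intensity is at least `minor_ratio_min` times the highest, and the
#' top-two base identities agree between strands (as sets).  Positions
#' lacking one strand are skipped (never called).
#'
#' @param peaks a [peak_table()].
#' @param minor_ratio_min minimum minor/major intensity ratio in `(0, 1)`.
#' @return data frame of class `"het_sites"` with columns `position`,
#'   `major_base`, `minor_base`, `major_frac_F`, `major_frac_R`, sorted by
#'   position.  Major/minor are determined from strand-averaged intensities.
#' @export
call_het_sites <- function(peaks, minor_ratio_min = 0.25) {
  if (minor_ratio_min <= 0 || minor_ratio_min >= 1) {
    stop("minor_ratio_min must lie in (0, 1)")
  }
  mats <- strand_matrices(peaks)
  both <- intersect(rownames(mats$F), rownames(mats$R))  # single-stranded: skip
  out <- list()
  for (key in both) {
    fw <- mats$F[key, ]; rv <- mats$R[key, ]
    pos <- as.integer(key)
    ord_f <- order(fw, decreasing = TRUE)
    ord_r <- order(rv, decreasing = TRUE)
    tf <- ord_f[1:2]; tr <- ord_r[1:2]
    ratio_f <- fw[tf[2]] / fw[tf[1]]
    ratio_r <- rv[tr[2]] / rv[tr[1]]
    if (!is.finite(ratio_f) || !is.finite(ratio_r)) next
    if (ratio_f < minor_ratio_min || ratio_r < minor_ratio_min) next
    # >2 overlapping bases on both strands cannot be split into two
    # haplotypes: refuse rather than guess
    if (fw[ord_f[3]] / fw[tf[1]] >= minor_ratio_min &&
        rv[ord_r[3]] / rv[tr[1]] >= minor_ratio_min) {
      stop(sprintf("unphaseable: >2 overlapping peaks on both strands at position %d", pos))
    }
    if (!setequal(tf, tr)) next
    avg <- (fw + rv) / 2
    pair <- tf[order(avg[tf], decreasing = TRUE)]
    out[[length(out) + 1L]] <- data.frame(
      position = pos,
      major_base = NUC[pair[1]], minor_base = NUC[pair[2]],
      major_frac_F = unname(fw[pair[1]] / (fw[pair[1]] + fw[pair[2]])),
      major_frac_R = unname(rv[pair[1]] / (rv[pair[1]] + rv[pair[2]])))
  }
  res <- if (length(out) == 0L) {
    data.frame(position = integer(0), major_base = character(0),
               minor_base = character(0), major_frac_F = numeric(0),
               major_frac_R = numeric(0))
  } else {
    do.call(rbind, out)
  }
  res <- res[order(res$position), ]
  rownames(res) <- NULL
  class(res) <- c("het_sites", "data.frame")
  res
}

#' Phase a mixed sample into high- and low-abundance haplotypes
#'
#' Outside the heterozygous sites both haplotypes carry the consensus base
#' (maximum intensity summed over strands).  At each heterozygous site the
#' strand-averaged major base goes to the high-abundance haplotype and the
#' minor base to the low-abundance one.
#'
#' @param peaks the [peak_table()] the het sites were called from.
#' @param het_sites result of [call_het_sites()].
#' @param id sample identifier used to name the output records (`id_H`,
#'   `id_L`).
#' @return list of class `"phased_haplotypes"`: `high` and `low` (sequence
#'   strings), `het_sites`, `n_haplotypes` (1 iff no het site).
#' @export
phase_haplotypes <- function(peaks, het_sites, id = "sample") {
  df <- as.data.frame(peaks)
  positions <- sort(unique(df$position))
  mats <- strand_matrices(peaks)
  total <- matrix(0, length(positions), 4,
                  dimnames = list(as.character(positions), NUC))
  for (s in c("F", "R")) {
    m <- mats[[s]]
    if (nrow(m) > 0L) total[rownames(m), ] <- total[rownames(m), ] + m
  }
  cons <- stats::setNames(NUC[max.col(total, ties.method = "first")],
                          rownames(total))
  high <- cons
  low <- cons
  if (nrow(het_sites) > 0L) {
    # strand-consistency of the major call: the top base must win on both
    # strands individually, otherwise relative abundance is uninterpretable
    for (i in seq_len(nrow(het_sites))) {
      h <- het_sites[i, ]
      if ((h$major_frac_F - 0.5) * (h$major_frac_R - 0.5) < 0) {
        stop(sprintf("phasing conflict at position %d: major base differs between strands",
                     h$position))
      }
      key <- as.character(h$position)
      high[key] <- h$major_base
      low[key] <- h$minor_base
    }
  }
  structure(list(high = paste(high, collapse = ""),
                 low = paste(low, collapse = ""),
                 het_sites = het_sites,
                 n_haplotypes = if (nrow(het_sites) > 0L) 2L else 1L,
                 id = id),
            class = "phased_haplotypes")
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  cat(sprintf("Sample '%s': %d haplotype(s), %d heterozygous site(s)\n",
              x$id, x$n_haplotypes, nrow(x$het_sites)))
  if (nrow(x$het_sites) > 0L) print(as.data.frame(x$het_sites))
  invisible(x)
}

#' Phased haplotypes as an alignment
#' @param x a [phase_haplotypes()] result
#' @return an [alignment()] with records `<id>_H` and `<id>_L` (or the single
#'   consensus `<id>` when only one haplotype is present)
#' @export
as_alignment <- function(x) {
  stopifnot(inherits(x, "phased_haplotypes"))
  if (x$n_haplotypes == 2L) {
    alignment(stats::setNames(c(x$high, x$low),
                              paste0(x$id, c("_H", "_L"))))
  } else {
    alignment(stats::setNames(x$high, x$id))
  }
}

#' Missing-data quality rule
#'
#' A record passes iff its fraction of `N` bases is strictly below
#' `max_fraction` (default 0.18, i.e. fewer than 18% of the sequence filled
#' with Ns).
#'
#' @param record sequence string.
#' @param max_fraction strict upper bound on the N fraction.
#' @return `TRUE` or `FALSE`.
#' @examples
#' missing_fraction_ok(strrep("A", 500))                         # TRUE
#' missing_fraction_ok(paste0(strrep("N", 90), strrep("A", 410)))  # FALSE: 18%
#' @export
missing_fraction_ok <- function(record, max_fraction = 0.18) {
  if (nchar(record) == 0L) stop("record must be non-empty")
  bases <- strsplit(toupper(record), "")[[1]]
  mean(bases == "N") < max_fraction
}
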