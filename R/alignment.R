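#' Construct a nucleotide alignment
#'
#' An alignment is a character matrix with one row per sequence record and one
#' column per aligned site, restricted to the alphabet `A C G T N -`.
#' Row names are the (unique, non-empty) record identifiers.  Per-record
#' metadata (host species, origin, lab duration, strand coverage, ...) can be
#' attached as a data frame.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix of single bases with row names.
#' @param meta optional data frame of per-record metadata, one row per record,
#'   matched to records by row order.
#' @return an object of class `"hap_alignment"`: a character matrix with
#'   attribute `meta`.
#' @examples
#' aln <- alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' dim(aln)
#' @export
alignment <- function(seqs, meta = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("every sequence record needs a non-empty id")
    }
    n <- nchar(seqs)
    if (length(unique(n)) != 1L) {
      stop(sprintf("alignment error: records have unequal lengths (%s)",
                   paste(unique(n), collapse = ", ")))
    }
    m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
    rownames(m) <- names(seqs)
  }
  m[] <- toupper(m)
  ok <- m %in% c("A", "C", "G", "T", "N", "-")
  dim(ok) <- dim(m)
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("parse error: illegal character '%s' in record '%s' at position %d",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]], bad[1, 2]))
  }
  if (anyDuplicated(rownames(m))) stop("duplicate record ids")
  if (nrow(m) < 1L) stop("alignment must contain at least one record")
  if (!is.null(meta)) {
    stopifnot(is.data.frame(meta), nrow(meta) == nrow(m))
    rownames(meta) <- rownames(m)
  }
  structure(m, meta = meta, class = c("hap_alignment", class(m)))
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences, %d sites\n", nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 6)
  for (id in show) {
    s <- paste(x[id, seq_len(min(ncol(x), 50))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (ncol(x) > 50) "..." else ""))
  }
  if (nrow(x) > 6) cat(sprintf("  ... and %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Subset keeps the class
#' @export
`[.hap_alignment` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("hap_alignment", class(out))
  out
}

#' Collapse alignment rows back to strings
#' @param aln alignment
#' @return named character vector of sequence strings
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' Records are returned in file order; bases are uppercased; `N` and `-` are
#' preserved.  All records must have equal length and use only the
#' `A C G T N -` alphabet.
#'
#' @param path path to a FASTA file.
#' @return a [alignment()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  if (length(recs) == 0L) stop(sprintf("no FASTA records in %s", path))
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln alignment
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(aln, path) {
  seqs <- alignment_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(c(paste0(">", id), seqs[[id]]), con)
  }
  invisible(path)
}

#' Read a two-strand chromatogram peak table
#'
#' The peak-table dialect is TSV with header columns
#' `position, strand, A, C, G, T`: one row per (position, strand), 1-based
#' contiguous positions, strand `F` (forward) or `R` (reverse), and four
#' non-negative peak intensities in arbitrary units.  This tabular form stands
#' in for rendered electropherograms.
#'
#' @param path path to the TSV file.
#' @return an object of class `"peak_table"`: a data frame with the columns
#'   above, plus attribute `single_stranded` (TRUE when only one strand is
#'   present).
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  peak_table(df)
}

#' Validate a peak-table data frame
#' @param df data frame with columns position, strand, A, C, G, T
#' @return classed data frame (see [read_peak_table()])
#' @export
peak_table <- function(df) {
  need <- c("position", "strand", "A", "C", "G", "T")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("format error: peak table lacks column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[, need]
  if (!all(df$strand %in% c("F", "R"))) {
    stop("format error: strand must be 'F' or 'R'")
  }
  ints <- as.matrix(df[, c("A", "C", "G", "T")])
  if (!is.numeric(ints) || any(!is.finite(ints))) {
    stop("value error: intensities must be finite numbers")
  }
  if (any(ints < 0)) {
    stop(sprintf("value error: negative intensity at position %d",
                 df$position[which(apply(ints < 0, 1, any))[1]]))
  }
  pos <- sort(unique(df$position))
  if (length(pos) > 1L && any(diff(pos) != 1)) {
    stop("format error: positions must be contiguous")
  }
  single <- length(unique(df$strand)) < 2L
  df <- df[order(df$position, df$strand), ]
  rownames(df) <- NULL
  structure(df, single_stranded = single,
            class = c("peak_table", "data.frame"))
}

#' Write a peak table to TSV
#' @param peaks peak table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a Newick string into a phylogenetic tree
#'
#' Thin wrapper around \pkg{ape}'s Newick reader with the contracts this
#' package relies on: leaf labels preserved, absent branch lengths default to
#' zero, and `write_newick(parse_newick(x))` preserves topology and lengths.
#'
#' @param text a Newick string.
#' @return an \pkg{ape} `phylo` tree.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop(sprintf("Newick parse error in: %s", text))
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

#' Serialize a tree to Newick
#' @param tree a `phylo` tree
#' @return a Newick string
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}
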