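# Alignments are plain uppercase character matrices (rows = sequences, named;
# columns = sites) over {A,C,G,T,-,N,?}. This keeps the QC code transparent;
# conversion from FASTA goes through ape.

#' Read a FASTA alignment into a character matrix
#'
#' Wraps [ape::read.FASTA()]; sequences must all have the same length.
#' Characters are uppercased; gaps are `-`, missing data `N` or `?`.
#'
#' @param path FASTA file path.
#' @return Character matrix with one named row per sequence.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  seqs <- lapply(as.character(dna), toupper)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
         "): not an alignment")
  aln <- do.call(rbind, seqs)
  rownames(aln) <- names(dna)
  as_alignment(aln)
}

#' @rdname read_fasta
#' @param aln Alignment matrix.
#' @param width Characters per FASTA line.
#' @export
write_fasta <- function(aln, path, width = 80) {
  aln <- as_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    writeLines(c(paste0(">", rownames(aln)[i]),
                 substring(s, seq(1, nchar(s), width),
                           pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))),
               con)
  }
  invisible(path)
}

as_alignment <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- toupper(as.character(as.matrix(aln)))
  if (!is.matrix(aln) || !is.character(aln))
    stop("alignment must be a character matrix")
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    stop("alignment rows must carry unique sequence names")
  aln <- toupper(aln)
  aln
}

#' Summary statistics of an alignment
#'
#' A site is parsimony-informative iff at least two distinct nucleotide
#' states each occur in at least two sequences; gaps and ambiguity codes
#' (`-`, `N`, `?`) never count as states. GC content and base frequencies
#' are computed over unambiguous nucleotides only.
#'
#' @param aln Character matrix alignment (see [read_fasta()]).
#' @return List with `prop_informative`, `gc_content`, `base_freqs`
#'   (named A/C/G/T, summing to 1), `n_sites`, `n_seqs`.
#' @examples
#' aln <- rbind(s1 = c("A", "A", "A", "A"), s2 = c("A", "A", "T", "-"),
#'              s3 = c("A", "T", "C", "A"), s4 = c("A", "T", "G", "-"))
#' alignment_summary(aln)$prop_informative  # only site 2 is informative
#' @export
alignment_summary <- function(aln) {
  aln <- as_alignment(aln)
  if (ncol(aln) == 0L) stop("alignment has 0 sites")
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(aln == b), numeric(ncol(aln)))
  if (ncol(aln) == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, bases))
  informative <- rowSums(counts >= 2L) >= 2L
  tot <- colSums(counts)  # per-base totals over the whole alignment
  if (sum(tot) == 0) stop("alignment contains no unambiguous nucleotides")
  freqs <- tot / sum(tot)
  list(prop_informative = mean(informative),
       gc_content = unname(freqs["G"] + freqs["C"]),
       base_freqs = freqs,
       n_sites = ncol(aln),
       n_seqs = nrow(aln))
}

#' Pearson chi-squared comparison of informative-site counts
#'
#' Compares the (informative, non-informative) site counts of one gene's
#' alignment at two processing stages via the 2x2 Pearson chi-squared test
#' (1 df, no continuity correction). A zero row or column margin makes the
#' table degenerate: the p-value is reported as 1 and flagged.
#'
#' @param countsA,countsB Length-2 integer vectors
#'   `(informative, non-informative)`.
#' @param alpha Significance level (default 0.05).
#' @return List with `chi2`, `pvalue`, `significant`, `degenerate`.
#' @export
informative_chi2 <- function(countsA, countsB, alpha = 0.05) {
  a <- as.numeric(countsA); b <- as.numeric(countsB)
  if (length(a) != 2L || length(b) != 2L || any(c(a, b) < 0))
    stop("countsA and countsB must be non-negative length-2 vectors")
  tab <- rbind(a, b)
  rows <- rowSums(tab); cols <- colSums(tab); n <- sum(tab)
  if (any(rows == 0) || any(cols == 0)) {
    return(list(chi2 = 0, pvalue = 1, significant = FALSE, degenerate = TRUE))
  }
  chi2 <- unname(n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
                   prod(c(rows, cols)))
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, pvalue = pval, significant = pval < alpha,
       degenerate = FALSE)
}
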