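#' Nucleotide alignment with site-pattern compression
#'
#' Light container for a taxa x sites nucleotide matrix.  Site patterns are
#' compressed once at construction: `patterns` is an integer matrix
#' (taxa x distinct patterns, A/C/G/T coded 0..3, anything else 4 =
#' fully ambiguous) and `weights` the pattern multiplicities.  Compression
#' is exact: the pattern-wise log-likelihood weighted by multiplicities
#' equals the site-wise sum.
#'
#' @param x character matrix of single characters (taxa in rows, rownames =
#'   taxon labels), or a matrix of single-character strings.
#' @return object of class `phylo_alignment` with fields `taxa`, `mat`,
#'   `n_sites`, `patterns`, `weights`.
#' @export
phylo_alignment <- function(x) {
  if (is.null(rownames(x))) stop("alignment matrix needs taxon rownames")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels")
  mat <- toupper(as.matrix(x))
  code <- match(mat, c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- 4L
  code <- matrix(code, nrow = nrow(mat))
  key <- apply(code, 2, paste, collapse = "")
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  patterns <- code[, first, drop = FALSE]
  weights <- as.numeric(tabulate(idx, nbins = length(uk)))
  structure(list(taxa = rownames(mat), mat = mat, n_sites = ncol(mat),
                 patterns = patterns, weights = weights,
                 pattern_index = idx),
            class = "phylo_alignment")
}

#' @export
print.phylo_alignment <- function(x, ...) {
  cat("phylo_alignment:", length(x$taxa), "taxa,", x$n_sites, "sites,",
      ncol(x$patterns), "distinct site patterns\n")
  invisible(x)
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`; guessed from the extension when
#'   missing (.phy/.phylip is PHYLIP, otherwise FASTA).
#' @return a [phylo_alignment].
#' @export
read_alignment <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(phy|phylip)$", path, ignore.case = TRUE))
      "phylip" else "fasta"
  }
  format <- match.arg(format, c("fasta", "phylip"))
  d <- if (format == "fasta") ape::read.FASTA(path)
       else ape::read.dna(path, format = "sequential", as.matrix = TRUE)
  m <- toupper(as.character(as.matrix(d)))
  phylo_alignment(m)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param aln a [phylo_alignment].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "phylo_alignment"))
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  if (format == "fasta") {
    out <- character(2 * length(seqs))
    out[c(TRUE, FALSE)] <- paste0(">", aln$taxa)
    out[c(FALSE, TRUE)] <- seqs
    writeLines(out, path)
  } else {
    writeLines(c(paste(length(seqs), aln$n_sites),
                 paste(format(aln$taxa, width = max(nchar(aln$taxa)) + 2),
                       seqs)), path)
  }
  invisible(path)
}

#' Empirical base frequencies of an alignment
#'
#' @param aln a [phylo_alignment].
#' @return numeric(4) observed frequencies of A, C, G, T (ambiguous sites
#'   ignored).
#' @export
base_frequencies <- function(aln) {
  tab <- table(factor(aln$mat, levels = c("A", "C", "G", "T")))
  as.numeric(tab / sum(tab))
}

# integer tip-state matrix in the tip order of `tree` (rows match tip.label)
align_states <- function(aln, tree) {
  i <- match(tree$tip.label, aln$taxa)
  if (anyNA(i))
    stop("taxa missing from alignment: ",
         paste(setdiff(tree$tip.label, aln$taxa), collapse = ", "))
  aln$patterns[i, , drop = FALSE]
}
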