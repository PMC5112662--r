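#' Edit a gapped codon-aware alignment into a clean codon alignment
#'
#' Removes every codon column in which either sequence carries a gap or a
#' non-ACGT symbol, the automated counterpart of editing alignments by hand
#' before substitution counting. Input sequences must already be aligned
#' (equal length) and in frame: the aligned length must be a multiple of 3.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length; gaps as
#'   \code{-} (or any non-ACGT character). Case-insensitive.
#' @param ids Optional character vector of length 2 with sequence labels.
#' @return A \code{codon_alignment} object: list with codon vectors
#'   \code{codons_a}, \code{codons_b}, labels \code{ids}, and
#'   \code{dropped_columns} (number of codon columns removed).
#' @examples
#' edit_alignment("ATG---AAA", "ATGCCCAAA")  # 2 codons kept, 1 dropped
#' @export
edit_alignment <- function(seq_a, seq_b, ids = c("seq_a", "seq_b")) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  if (nchar(seq_a) %% 3L != 0L)
    stop("aligned length ", nchar(seq_a),
         " is not a multiple of 3; alignment must be codon-aware")
  ca <- .split_codons(seq_a)
  cb <- .split_codons(seq_b)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  dropped <- sum(!clean)
  ca <- ca[clean]
  cb <- cb[clean]
  if (length(ca) == 0L)
    stop("no comparable codons left after gap/ambiguity editing")
  stops <- .is_stop(ca) | .is_stop(cb)
  if (any(stops))
    stop("internal stop codon(s) at codon position(s) ",
         paste(which(stops), collapse = ", "),
         "; remove terminal stops or check the frame")
  structure(list(codons_a = ca, codons_b = cb, ids = ids,
                 dropped_columns = dropped),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment: ", x$ids[1], " vs ", x$ids[2], "\n", sep = "")
  cat("  codons: ", length(x$codons_a),
      "  dropped columns: ", x$dropped_columns, "\n", sep = "")
  invisible(x)
}

# Build a codon_alignment from two already-clean in-frame sequences.
codon_alignment <- function(seq_a, seq_b, ids = c("seq_a", "seq_b")) {
  edit_alignment(seq_a, seq_b, ids = ids)
}
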