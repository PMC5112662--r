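# Gene models: plain lists with id, chrom, strand, and an exon data.frame
# (start, end, kind, phase) in 0-based half-open chromosome coordinates,
# ordered 5'->3' on the coding strand (descending start for minus-strand
# genes). Exon kinds: leader, N, IgC, TM, cytoplasmic, other.

.EXON_KINDS <- c("leader", "N", "IgC", "TM", "cytoplasmic", "other")

#' Construct a gene model
#'
#' @param id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with columns \code{start}, \code{end} (0-based
#'   half-open chromosome coordinates), \code{kind} (one of leader, N,
#'   IgC, TM, cytoplasmic, other) and optionally \code{phase} (0/1/2,
#'   default 0). Rows must be ordered 5'->3' on the coding strand and
#'   non-overlapping.
#' @param subgroup Optional subgroup label (e.g. "group1").
#' @param homeolog One of "L", "S" or "none".
#' @param anchoring Membrane anchoring annotation: "TM", "GPI" or
#'   "secreted" (supplied, not predicted).
#' @return A \code{gene_model} object.
#' @export
gene_model <- function(id, chrom, strand, exons, subgroup = NA_character_,
                       homeolog = "none", anchoring = "TM") {
  stopifnot(strand %in% c("+", "-"))
  if (is.null(exons$phase)) exons$phase <- 0L
  if (!all(exons$kind %in% .EXON_KINDS))
    stop("unknown exon kind(s): ",
         paste(setdiff(exons$kind, .EXON_KINDS), collapse = ", "))
  ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(ord, seq_len(nrow(exons))))
    stop("exons must be ordered 5'->3' on the coding strand")
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  chk <- exons[order(exons$start), ]
  if (nrow(chk) > 1 && any(chk$start[-1] < chk$end[-nrow(chk)]))
    stop("overlapping exons")
  structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                 subgroup = subgroup, homeolog = homeolog,
                 anchoring = anchoring),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model ", x$id, " (", x$chrom, x$strand, ", ",
      nrow(x$exons), " exons", ")\n", sep = "")
  invisible(x)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Coding-strand sequence of one chromosome interval of a gene.
.gene_segment <- function(chrom_seq, start, end, strand) {
  if (start < 0 || end > nchar(chrom_seq))
    stop("interval [", start, ",", end, ") outside chromosome bounds")
  s <- substr(chrom_seq, start + 1L, end)
  if (strand == "-") .revcomp(s) else s
}

#' Coding-strand exon sequences of a gene model
#'
#' @param gene A \code{gene_model}.
#' @param chrom_seq Chromosome sequence (plus strand) as a string.
#' @return Character vector of exon sequences in coding order
#'   (reverse-complemented for minus-strand genes).
#' @export
gene_exon_seqs <- function(gene, chrom_seq) {
  vapply(seq_len(nrow(gene$exons)), function(i)
    .gene_segment(chrom_seq, gene$exons$start[i], gene$exons$end[i],
                  gene$strand), character(1))
}

#' Coding-strand intron sequences of a gene model
#'
#' @inheritParams gene_exon_seqs
#' @return Character vector of intron sequences between consecutive
#'   coding-order exons.
#' @export
gene_intron_seqs <- function(gene, chrom_seq) {
  ex <- gene$exons
  n <- nrow(ex)
  if (n < 2) return(character(0))
  vapply(seq_len(n - 1L), function(i) {
    if (gene$strand == "+") {
      .gene_segment(chrom_seq, ex$end[i], ex$start[i + 1L], "+")
    } else {
      .gene_segment(chrom_seq, ex$end[i + 1L], ex$start[i], "-")
    }
  }, character(1))
}

#' Call pseudogene status from N-exon stops and splice-site integrity
#'
#' A gene is a pseudogene iff any N exon contains an in-frame stop codon,
#' or any intron flanking an N exon lacks the canonical GT donor / AG
#' acceptor dinucleotides (evaluated strand-aware on the coding strand).
#'
#' @param gene A \code{gene_model}.
#' @param chrom_seq Chromosome sequence (plus strand) as a string.
#' @param allow_gc Accept GC donors as valid (default FALSE).
#' @return list with \code{id}, \code{status} ("intact"/"pseudogene") and
#'   \code{reasons} (character vector among "internal stop",
#'   "bad splice donor", "bad splice acceptor").
#' @export
call_pseudogene <- function(gene, chrom_seq, allow_gc = FALSE) {
  ex <- gene$exons
  n_idx <- which(ex$kind == "N")
  if (length(n_idx) == 0) stop("gene has no N exon")
  reasons <- character(0)
  exseqs <- gene_exon_seqs(gene, chrom_seq)
  for (i in n_idx) {
    s <- exseqs[i]
    ph <- ex$phase[i]
    cod_start <- seq(ph + 1L, nchar(s) - 2L, by = 3L)
    codons <- substring(s, cod_start, cod_start + 2L)
    if (any(codons %in% c("TAA", "TAG", "TGA"))) {
      reasons <- c(reasons, "internal stop")
      break
    }
  }
  introns <- gene_intron_seqs(gene, chrom_seq)
  donors_ok <- c("GT", if (allow_gc) "GC")
  flank_n <- unique(c(n_idx - 1L, n_idx))  # introns 5' and 3' of N exons
  flank_n <- flank_n[flank_n >= 1L & flank_n <= length(introns)]
  for (i in flank_n) {
    intr <- introns[i]
    if (!substr(intr, 1, 2) %in% donors_ok)
      reasons <- c(reasons, "bad splice donor")
    if (substr(intr, nchar(intr) - 1L, nchar(intr)) != "AG")
      reasons <- c(reasons, "bad splice acceptor")
  }
  reasons <- unique(reasons)
  list(id = gene$id,
       status = if (length(reasons)) "pseudogene" else "intact",
       reasons = reasons)
}

#' Cluster N-exon nucleotide sequences into distinct exons
#'
#' Single-linkage clustering of N-exon sequences at a divergence
#' threshold; the number of clusters is the distinct-exon count used for
#' gene-family size estimates (sequences more than \code{threshold}
#' diverged count as distinct). Divergence is 1 - identity over aligned
#' non-gap columns of a global pairwise alignment (match +1, mismatch -1,
#' gap open -5, extend -1).
#'
#' @param seqs Named character vector of N-exon nucleotide sequences.
#' @param threshold Divergence at or below which two exons are linked
#'   (default 0.01, i.e. the "> 1 percent counts as distinct" rule).
#' @return list with \code{n_distinct} and \code{membership} (named
#'   integer vector of cluster ids; empty input gives 0 clusters).
#' @export
cluster_n_exons <- function(seqs, threshold = 0.01) {
  n <- length(seqs)
  if (n == 0) return(list(n_distinct = 0L, membership = integer(0)))
  if (n == 1) return(list(n_distinct = 1L,
                          membership = setNames(1L, names(seqs))))
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- nucleotide_divergence(seqs[[i]], seqs[[j]])
    }
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  memb <- match(roots, unique(roots))
  list(n_distinct = length(unique(memb)),
       membership = setNames(memb, names(seqs)))
}

#' Pairwise nucleotide divergence from a global alignment
#'
#' @param a,b Nucleotide sequences (unaligned).
#' @return 1 - identity over aligned non-gap columns.
#' @export
nucleotide_divergence <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- pa != "-" & sb != "-"
  1 - sum(pa[keep] == sb[keep]) / sum(keep)
}

#' Collapse an ordered locus annotation of exons into genes
#'
#' Consecutive N exons with no non-N exon in between belong to one gene;
#' a new gene starts at each leader or N exon that follows a
#' non-leader/non-N exon.
#'
#' @param exons data.frame with column \code{kind}, rows ordered by
#'   chromosomal position along the locus.
#' @return list with \code{n_genes} and \code{gene_of} (integer vector,
#'   one entry per exon; 0 marks exons of a locus without any N exon).
#'   The gene count never exceeds the number of N-exon runs.
#' @export
merge_exons_to_genes <- function(exons) {
  k <- exons$kind
  n <- length(k)
  if (n == 0) return(list(n_genes = 0L, gene_of = integer(0)))
  n_idx <- which(k == "N")
  if (length(n_idx) == 0) return(list(n_genes = 0L,
                                      gene_of = integer(n)))
  # a gene break falls between consecutive N exons separated by >= 1
  # non-N exon; each N run plus its flanking non-N exons is one gene
  gene_of_n <- cumsum(c(1L, diff(n_idx) > 1L))
  gene_of <- integer(n)
  gene_of[n_idx] <- gene_of_n
  for (i in seq_len(n)) {
    if (gene_of[i] > 0L) next
    if (k[i] == "leader") {
      nxt <- n_idx[n_idx > i]
      gene_of[i] <- if (length(nxt)) gene_of[nxt[1]]
                    else gene_of_n[length(gene_of_n)]
    } else {
      prv <- n_idx[n_idx < i]
      gene_of[i] <- if (length(prv)) gene_of[prv[length(prv)]] else 1L
    }
  }
  list(n_genes = max(gene_of_n), gene_of = gene_of)
}

#' Oppositely oriented inhibitory/activating gene pairs
#'
#' All (inhibitory, activating) gene pairs on opposite strands within the
#' same subgroup, ordered by genomic distance between gene midpoints.
#'
#' @param genes data.frame with columns \code{id}, \code{strand},
#'   \code{class} ("inhibitory"/"activating"/...), \code{subgroup},
#'   \code{start}, \code{end}.
#' @return data.frame with columns \code{inhibitory}, \code{activating},
#'   \code{subgroup}, \code{distance}.
#' @export
orientation_pairs <- function(genes) {
  inh <- genes[genes$class == "inhibitory", , drop = FALSE]
  act <- genes[genes$class == "activating", , drop = FALSE]
  out <- data.frame(inhibitory = character(0), activating = character(0),
                    subgroup = character(0), distance = numeric(0))
  for (i in seq_len(nrow(inh))) for (j in seq_len(nrow(act))) {
    if (inh$subgroup[i] != act$subgroup[j]) next
    if (inh$strand[i] == act$strand[j]) next
    mid_i <- (inh$start[i] + inh$end[i]) / 2
    mid_j <- (act$start[j] + act$end[j]) / 2
    out <- rbind(out, data.frame(
      inhibitory = inh$id[i], activating = act$id[j],
      subgroup = inh$subgroup[i], distance = abs(mid_i - mid_j)))
  }
  out[order(out$distance, out$inhibitory, out$activating), , drop = FALSE]
}
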