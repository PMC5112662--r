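# Distance-based orthology: pairwise protein distances, hand-rolled
# neighbor-joining with deterministic tie-breaking, bootstrap bipartition
# support, subgroup assignment, and reciprocal-best-hit relation calls.

#' Pairwise protein distance
#'
#' Globally aligns two amino-acid sequences (BLOSUM62), drops gap columns
#' and returns the p-distance or its Poisson correction, plus percent
#' identity.
#'
#' @param a,b Amino-acid sequences (unaligned strings).
#' @param model "p" (proportion of mismatches) or "poisson"
#'   (\eqn{-\ln(1-p)}).
#' @return list with \code{distance}, \code{p} and \code{identity}
#'   (percent).
#' @export
protein_distance <- function(a, b, model = c("poisson", "p")) {
  model <- match.arg(model)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- pa != "-" & sb != "-"
  nc <- sum(keep)
  if (nc == 0) stop("no comparable columns between sequences")
  p <- sum(pa[keep] != sb[keep]) / nc
  d <- if (model == "poisson") -log(1 - p) else p
  list(distance = d, p = p, identity = 100 * (1 - p))
}

#' Pairwise distance matrix for a set of protein sequences
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param model Distance model, see [protein_distance()].
#' @return list with \code{D} (symmetric matrix, zero diagonal) and
#'   \code{identity} (percent identity matrix).
#' @export
protein_distance_matrix <- function(seqs, model = "poisson") {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  I <- D
  diag(I) <- 100
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pd <- protein_distance(seqs[[i]], seqs[[j]], model = model)
      D[i, j] <- D[j, i] <- pd$distance
      I[i, j] <- I[j, i] <- pd$identity
    }
  }
  list(D = D, identity = I)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration with two pinned-down behaviours: negative
#' branch lengths are clamped to zero with the deficit moved to the
#' sister branch, and ties in the Q criterion are broken deterministically
#' by label order.
#'
#' @param D Symmetric distance matrix with labels (>= 3 taxa).
#' @return An [ape::phylo] unrooted tree.
#' @export
build_nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  # node representation: newick fragment + sort key for tie-breaking
  nodes <- labels
  keys <- labels
  d <- D
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest pair of sort keys
    pick <- order(keys[cand[, 1]], keys[cand[, 2]])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], vi, nodes[j], vj)
    new_key <- min(keys[i], keys[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    keys <- c(keys[keep], new_key)
    d <- d2
  }
  # final three nodes: star join with three-point branch lengths
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], v[1], nodes[2], v[2], nodes[3], v[3])
  ape::read.tree(text = nwk)
}

# Distance matrix from a multiple alignment (character matrix or named
# vector of equal-length aligned strings), pairwise deletion of gaps.
aligned_distance_matrix <- function(aln, model = "poisson") {
  msa_distances(aln, model)$D
}

#' Distances and percent identity from a multiple alignment
#'
#' Pairwise-deletion p-distances (optionally Poisson-corrected) and
#' percent identity over the comparable columns of a multiple alignment.
#'
#' @param aln Named character vector of equal-length aligned sequences,
#'   or a character matrix (rows = taxa).
#' @param model "poisson" or "p".
#' @return list with symmetric matrices \code{D} and \code{identity}.
#' @export
msa_distances <- function(aln, model = "poisson") {
  M <- .as_aln_matrix(aln)
  n <- nrow(M)
  labs <- rownames(M)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  I <- D; diag(I) <- 100
  ok <- M %in% c(LETTERS)
  dim(ok) <- dim(M)
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    keep <- ok[i, ] & ok[j, ]
    nc <- sum(keep)
    p <- if (nc == 0) NA_real_ else sum(M[i, keep] != M[j, keep]) / nc
    d <- if (is.na(p)) NA_real_
         else if (model == "poisson") -log(max(1e-12, 1 - p)) else p
    D[i, j] <- D[j, i] <- d
    I[i, j] <- I[j, i] <- 100 * (1 - p)
  }
  list(D = D, identity = I)
}

.as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  L <- unique(nchar(aln))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  M <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(M) <- names(aln)
  M
}

#' Multiple sequence alignment via mafft
#'
#' Thin wrapper around the mafft command-line aligner (deterministic
#' progressive mode); the input type (nucleotide or amino acid) is
#' auto-detected by mafft.
#'
#' @param seqs Named character vector of sequences.
#' @return Named character vector of aligned sequences (equal length).
#' @export
align_proteins <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("mafft not found on PATH; required for multiple alignment")
  fin <- tempfile(fileext = ".fa")
  write_fasta(seqs, fin)
  out <- system2("mafft", c("--retree", "2", "--maxiterate", "0",
                            "--quiet", fin), stdout = TRUE)
  unlink(fin)
  fout <- tempfile(fileext = ".fa")
  writeLines(out, fout)
  res <- read_fasta(fout)
  unlink(fout)
  res[names(seqs)]
}

#' Bootstrap support for the NJ tree of a multiple alignment
#'
#' Columns of the alignment are resampled with replacement; support for
#' each internal edge of the full-alignment NJ tree is the percentage of
#' replicate NJ trees containing the same bipartition.
#'
#' @param aln Named character vector of aligned sequences (or character
#'   matrix), e.g. from [align_proteins()].
#' @param reps Number of bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed (resampling is fully seeded).
#' @param model Distance model passed to the distance step.
#' @return list with \code{tree} (ape phylo; node labels carry support
#'   percentages) and \code{support} (numeric vector per internal node).
#' @export
bootstrap_support <- function(aln, reps = 100, seed = 1L,
                              model = "poisson") {
  M <- .as_aln_matrix(aln)
  ref <- build_nj_tree(aligned_distance_matrix(M, model))
  boots <- vector("list", reps)
  .with_seed(seed, {
    for (r in seq_len(reps)) {
      cols <- sample(ncol(M), replace = TRUE)
      boots[[r]] <- build_nj_tree(aligned_distance_matrix(M[, cols,
                                                            drop = FALSE],
                                                          model))
    }
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / reps
  ref$node.label <- round(support, 1)
  list(tree = ref, support = support)
}

#' Assign sequences to two subgroups
#'
#' Splits a set of N-domain sequences into two clusters, either by cutting
#' the NJ tree at its longest internal edge or by 2-medoid partitioning of
#' the distance matrix. When all sequences are nearly identical (maximum
#' distance below \code{min_gap}) no split is made.
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param method "tree" (cut longest internal NJ edge) or "medoid".
#' @param min_gap Maximum pairwise distance below which the set is flagged
#'   as a single cluster (default 0.1).
#' @param pdm Optional precomputed list with \code{D} and \code{identity}
#'   matrices (e.g. from [msa_distances()]); skips pairwise realignment.
#' @return list with \code{split} (logical), \code{membership} (named
#'   integer vector, 1/2; all 1 when no split), \code{identity_within}
#'   and \code{identity_between} (percent identity ranges, min/max).
#' @export
assign_subgroups <- function(seqs, method = c("tree", "medoid"),
                             min_gap = 0.1, pdm = NULL) {
  method <- match.arg(method)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(pdm)) pdm <- protein_distance_matrix(seqs)
  D <- pdm$D[names(seqs), names(seqs)]
  I <- pdm$identity[names(seqs), names(seqs)]
  if (max(D) < min_gap) {
    return(list(split = FALSE,
                membership = setNames(rep(1L, length(seqs)), names(seqs)),
                identity_within = range(I[upper.tri(D)]),
                identity_between = c(NA_real_, NA_real_)))
  }
  if (method == "tree" && length(seqs) >= 4) {
    tree <- build_nj_tree(D)
    ntip <- length(tree$tip.label)
    internal <- tree$edge[, 1] > ntip & tree$edge[, 2] > ntip
    if (any(internal)) {
      e <- which(internal)[which.max(tree$edge.length[internal])]
      child <- tree$edge[e, 2]
      parts <- ape::prop.part(tree)
      tips1 <- tree$tip.label[parts[[child - ntip]]]
      memb <- setNames(ifelse(names(seqs) %in% tips1, 1L, 2L), names(seqs))
    } else method <- "medoid"
  }
  if (method == "medoid" || length(seqs) < 4) {
    # 2-medoid partitioning (exhaustive over medoid pairs, small n)
    n <- length(seqs)
    best <- NULL; best_cost <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      assign_ <- ifelse(D[, i] <= D[, j], 1L, 2L)
      cost <- sum(pmin(D[, i], D[, j]))
      if (cost < best_cost) { best_cost <- cost; best <- assign_ }
    }
    memb <- setNames(best, names(seqs))
  }
  same <- outer(memb, memb, "==")
  ut <- upper.tri(D)
  iw <- I[ut & same]
  ib <- I[ut & !same]
  list(split = TRUE, membership = memb,
       identity_within = if (length(iw)) range(iw) else c(NA, NA),
       identity_between = if (length(ib)) range(ib) else c(NA, NA))
}

#' Call ortholog, paralog-group and homeolog relations
#'
#' Orthologs are reciprocal best cross-species hits by N-domain identity;
#' homeologs are reciprocal best hits across L/S homeolog tags within an
#' allotetraploid species; paralog groups are within-species mutual
#' nearest neighbours that are closer to each other than either is to any
#' cross-species sequence. Ties are broken by label order and flagged.
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param species Character vector (same length/order) of species labels.
#' @param tags Optional homeolog tags ("L", "S" or "none"), same order.
#' @param identity Optional precomputed percent-identity matrix (rows and
#'   columns named like \code{seqs}); avoids realigning large sets.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{species_a}, \code{species_b}, \code{relation} (ortholog /
#'   paralog-group / homeolog), \code{identity}, \code{tie}.
#' @export
call_orthologs <- function(seqs, species, tags = NULL, identity = NULL) {
  n <- length(seqs)
  if (is.null(tags)) tags <- rep("none", n)
  stopifnot(length(species) == n, length(tags) == n)
  ids <- names(seqs)
  I <- if (is.null(identity)) protein_distance_matrix(seqs)$identity
       else identity[ids, ids]
  diag(I) <- -Inf
  best_in <- function(i, pool) {
    # highest identity within pool; ties by label order, flagged
    if (!length(pool)) return(NULL)
    v <- I[i, pool]
    top <- pool[which(v == max(v))]
    list(j = top[order(ids[top])][1], tie = length(top) > 1)
  }
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    species_a = character(0), species_b = character(0),
                    relation = character(0), identity = numeric(0),
                    tie = logical(0))
  add_rbh <- function(out, pool_a, pool_b, relation) {
    for (i in pool_a) {
      ba <- best_in(i, pool_b)
      if (is.null(ba)) next
      bb <- best_in(ba$j, pool_a)
      if (!is.null(bb) && bb$j == i) {
        out <- rbind(out, data.frame(
          gene_a = ids[i], gene_b = ids[ba$j],
          species_a = species[i], species_b = species[ba$j],
          relation = relation, identity = I[i, ba$j],
          tie = ba$tie || bb$tie))
      }
    }
    out
  }
  sps <- unique(species)
  if (length(sps) > 1) {
    for (a in seq_along(sps)) for (b in seq_along(sps)) {
      if (a >= b) next
      out <- add_rbh(out, which(species == sps[a]),
                     which(species == sps[b]), "ortholog")
    }
  }
  # homeologs within species carrying L/S tags
  for (sp in sps) {
    iL <- which(species == sp & tags == "L")
    iS <- which(species == sp & tags == "S")
    if (length(iL) && length(iS))
      out <- add_rbh(out, iL, iS, "homeolog")
  }
  # paralog groups: within-species mutual nearest neighbours closer than
  # any cross-species sequence
  for (sp in sps) {
    own <- which(species == sp)
    other <- which(species != sp)
    for (i in own) {
      bi <- best_in(i, setdiff(own, i))
      if (is.null(bi)) next
      bj <- best_in(bi$j, setdiff(own, bi$j))
      if (is.null(bj) || bj$j != i || ids[i] >= ids[bi$j]) next
      cross_max <- if (length(other)) max(I[i, other], I[bi$j, other])
                   else -Inf
      if (I[i, bi$j] > cross_max) {
        out <- rbind(out, data.frame(
          gene_a = ids[i], gene_b = ids[bi$j],
          species_a = sp, species_b = sp,
          relation = "paralog-group", identity = I[i, bi$j],
          tie = bi$tie || bj$tie))
      }
    }
  }
  out
}
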