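# Paired-receptor identification, diversifying-selection ranking, and
# homeologous-locus retention/loss comparison.

#' Identify putative paired receptors
#'
#' A paired-receptor pair is an inhibitory gene (ITIM/ITSM class) and an
#' activating gene (ITAM/ITAM-like class) in the same subgroup that (i)
#' have opposing motif classes, (ii) share at least
#' \code{identity_threshold} percent N-domain amino-acid identity and
#' (iii) lie in opposite transcriptional orientation. One inhibitory gene
#' may pair with several activating genes. Genes with ambiguous motif
#' class are excluded and listed separately.
#'
#' @param genes data.frame with columns \code{id}, \code{strand},
#'   \code{class}, \code{subgroup}, \code{start}, \code{end}.
#' @param ndom_seqs Named character vector of N-domain amino-acid
#'   sequences (names matching \code{genes$id}).
#' @param identity_threshold Minimum percent identity (default 80).
#' @param identity Optional precomputed percent-identity matrix.
#' @return list with \code{pairs} (data.frame: inhibitory, activating,
#'   subgroup, identity, distance) and \code{ambiguous} (ids excluded).
#' @export
identify_paired_receptors <- function(genes, ndom_seqs,
                                      identity_threshold = 80,
                                      identity = NULL) {
  amb <- genes$id[genes$class == "ambiguous"]
  genes <- genes[genes$class %in% c("inhibitory", "activating"), ,
                 drop = FALSE]
  cand <- orientation_pairs(genes)
  pairs <- data.frame(inhibitory = character(0), activating = character(0),
                      subgroup = character(0), identity = numeric(0),
                      distance = numeric(0))
  for (i in seq_len(nrow(cand))) {
    a <- cand$inhibitory[i]; b <- cand$activating[i]
    if (!a %in% names(ndom_seqs) || !b %in% names(ndom_seqs)) next
    idy <- if (is.null(identity))
      protein_distance(ndom_seqs[[a]], ndom_seqs[[b]])$identity
    else identity[a, b]
    if (idy >= identity_threshold) {
      pairs <- rbind(pairs, data.frame(
        inhibitory = a, activating = b, subgroup = cand$subgroup[i],
        identity = idy, distance = cand$distance[i]))
    }
  }
  pairs <- pairs[order(pairs$inhibitory, pairs$activating), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, ambiguous = amb)
}

#' Rank gene pairs by dN/dS
#'
#' Orders ortholog/homeolog pairs by decreasing dN/dS; pairs with an
#' undefined ratio rank last regardless of dN; ties are broken stably by
#' pair label. The summary flags whether the top-ranked defined ratio
#' belongs to an inhibitory (ITIM) pair.
#'
#' @param dnds_results Named list of \code{dnds} objects (names are pair
#'   labels).
#' @param classes Named character vector of motif classes per pair label.
#' @return A \code{selection_ranking} object: data.frame with columns
#'   \code{pair}, \code{ratio}, \code{dN}, \code{dS}, \code{class},
#'   \code{undefined}; attribute \code{itim_top} (logical).
#' @export
rank_selection <- function(dnds_results, classes) {
  if (length(dnds_results) == 0) stop("no dN/dS results supplied")
  df <- data.frame(
    pair = names(dnds_results),
    ratio = vapply(dnds_results, function(r) r$ratio, numeric(1)),
    dN = vapply(dnds_results, function(r) r$dN, numeric(1)),
    dS = vapply(dnds_results, function(r) r$dS, numeric(1)),
    class = unname(classes[names(dnds_results)]))
  df$undefined <- is.na(df$ratio)
  if (all(df$undefined))
    warning("all dN/dS ratios undefined; ranking is by label only")
  ord <- order(df$undefined, -ifelse(is.na(df$ratio), -Inf, df$ratio),
               df$pair)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  itim_top <- nrow(df) > 0 && !df$undefined[1] &&
    identical(df$class[1], "inhibitory")
  structure(df, class = c("selection_ranking", "data.frame"),
            itim_top = itim_top)
}

#' @export
print.selection_ranking <- function(x, ...) {
  cat("selection ranking (", nrow(x), " pairs); inhibitory pair on top: ",
      attr(x, "itim_top"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare two homeologous loci
#'
#' Assigns every gene of locus A one fate relative to locus B
#' (retained-with-homeolog or lost-from-B) and reports genes present in B
#' without a homeolog in A as gained-in-B. The loss fraction is the
#' fraction of locus-A genes without a homeolog in B.
#'
#' @param genes_a,genes_b data.frames with columns \code{id},
#'   \code{subgroup}, \code{class}.
#' @param orthology data.frame from [call_orthologs()]; rows with
#'   relation "homeolog" link the two loci.
#' @param pairs_a,pairs_b Optional paired-receptor tables (as from
#'   [identify_paired_receptors()]\code{$pairs}) used to flag whether a
#'   complete pair survives at each locus.
#' @return A \code{locus_comparison} object: list with \code{fates}
#'   (data.frame id, locus, subgroup, class, fate), \code{loss_fraction},
#'   \code{retained}, \code{lost}, \code{gained}, \code{by_subgroup},
#'   \code{by_class}, \code{pair_survives_a}, \code{pair_survives_b}.
#' @export
compare_homeologous_loci <- function(genes_a, genes_b, orthology,
                                     pairs_a = NULL, pairs_b = NULL) {
  hom <- orthology[orthology$relation == "homeolog", , drop = FALSE]
  linked_a <- genes_a$id %in% c(hom$gene_a, hom$gene_b)
  linked_b <- genes_b$id %in% c(hom$gene_a, hom$gene_b)
  fates <- rbind(
    data.frame(id = genes_a$id, locus = "A", subgroup = genes_a$subgroup,
               class = genes_a$class,
               fate = ifelse(linked_a, "retained-with-homeolog",
                             "lost-from-b")),
    data.frame(id = genes_b$id, locus = "B", subgroup = genes_b$subgroup,
               class = genes_b$class,
               fate = ifelse(linked_b, "retained-with-homeolog",
                             "gained-in-b")))
  lost <- sum(!linked_a)
  loss_fraction <- if (nrow(genes_a)) lost / nrow(genes_a) else NA_real_
  survives <- function(pairs, ids) {
    !is.null(pairs) && nrow(pairs) > 0 &&
      any(pairs$inhibitory %in% ids & pairs$activating %in% ids)
  }
  structure(list(
    fates = fates,
    loss_fraction = loss_fraction,
    retained = sum(linked_a), lost = lost, gained = sum(!linked_b),
    by_subgroup = table(genes_a$subgroup, ifelse(linked_a, "retained",
                                                 "lost")),
    by_class = table(genes_a$class, ifelse(linked_a, "retained", "lost")),
    pair_survives_a = survives(pairs_a, genes_a$id),
    pair_survives_b = survives(pairs_b, genes_b$id)),
    class = "locus_comparison")
}

#' @export
print.locus_comparison <- function(x, ...) {
  cat("homeologous locus comparison\n")
  cat(sprintf("  retained: %d  lost: %d  gained: %d  loss fraction: %.3f\n",
              x$retained, x$lost, x$gained, x$loss_fraction))
  cat("  complete paired-receptor pair at locus A:", x$pair_survives_a,
      " at locus B:", x$pair_survives_b, "\n")
  invisible(x)
}
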