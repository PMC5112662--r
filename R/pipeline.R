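# End-to-end orchestration: annotate -> subgroup -> orthologs -> dN/dS ->
# conversion scan -> paired receptors -> homeologous locus comparison.

#' Codon-align two coding sequences guided by their translations
#'
#' Aligns the amino-acid translations globally and back-maps the gaps
#' onto the nucleotide sequences in 3-nt steps, then removes all gapped
#' codon columns — the automated analogue of editing a nucleotide
#' alignment guided by the protein alignment.
#'
#' @param a,b In-frame coding nucleotide sequences (lengths multiples
#'   of 3; no internal stops).
#' @param ids Labels for the two sequences.
#' @return A \code{codon_alignment}.
#' @export
align_codons_by_protein <- function(a, b, ids = c("seq_a", "seq_b")) {
  if (nchar(a) == nchar(b)) return(edit_alignment(a, b, ids = ids))
  pa <- .translate_nt(a)
  pb <- .translate_nt(b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ca <- .split_codons(a); cb <- .split_codons(b)
  na_ <- nb_ <- 0L
  outa <- outb <- character(length(ga))
  for (i in seq_along(ga)) {
    if (ga[i] == "-") outa[i] <- "---"
    else { na_ <- na_ + 1L; outa[i] <- ca[na_] }
    if (gb[i] == "-") outb[i] <- "---"
    else { nb_ <- nb_ + 1L; outb[i] <- cb[nb_] }
  }
  edit_alignment(paste(outa, collapse = ""), paste(outb, collapse = ""),
                 ids = ids)
}

.translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n)),
                                     if.fuzzy.codon = "X"))
}

#' Annotate gene models: pseudogene status, motifs, signaling class
#'
#' @param models Named list of \code{gene_model} objects.
#' @param chromosomes Named character vector of chromosome sequences.
#' @return list with \code{table} (data.frame: id, chrom, strand, start,
#'   end, species_unit, homeolog, subgroup_in, anchoring, n_exons, class,
#'   pseudogene, reasons), \code{n_peptides} and \code{cyt_peptides}
#'   (named character vectors), \code{motifs} (named list of motif
#'   data.frames).
#' @export
annotate_genes <- function(models, chromosomes) {
  rows <- list()
  n_pep <- character(0)
  cyt_pep <- character(0)
  motifs <- list()
  for (g in models) {
    chrom_seq <- chromosomes[[g$chrom]]
    if (is.null(chrom_seq)) stop("chromosome ", g$chrom, " not supplied")
    exseqs <- gene_exon_seqs(g, chrom_seq)
    kinds <- g$exons$kind
    ps <- call_pseudogene(g, chrom_seq)
    n_nt <- paste(exseqs[kinds == "N"], collapse = "")
    cy_nt <- paste(exseqs[kinds == "cytoplasmic"], collapse = "")
    npep <- .translate_nt(n_nt)
    cpep <- if (nzchar(cy_nt)) .translate_nt(cy_nt) else ""
    mo <- scan_motifs(sub("\\*.*$", "", cpep))
    cls <- classify_signaling(mo)
    n_pep[g$id] <- npep
    cyt_pep[g$id] <- cpep
    motifs[[g$id]] <- mo
    rows[[g$id]] <- data.frame(
      id = g$id, chrom = g$chrom, strand = g$strand,
      start = min(g$exons$start), end = max(g$exons$end),
      homeolog = g$homeolog, subgroup_in = g$subgroup,
      anchoring = g$anchoring, n_exons = sum(kinds == "N"),
      class = cls, pseudogene = ps$status == "pseudogene",
      reasons = paste(ps$reasons, collapse = ";"))
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       n_peptides = n_pep, cyt_peptides = cyt_pep, motifs = motifs)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on simulator output (a
#' \code{sim_family} object or a directory written by
#' [simulate_family()]): annotation, subgroup assignment, orthology,
#' ortholog/homeolog dN/dS, conversion scans on paired-receptor
#' candidates, paired-receptor identification and homeologous-locus
#' comparison. A rerun against an unchanged input directory reuses the
#' cached report (input checksums are recorded in the output manifest).
#'
#' @param input A \code{sim_family} object or a simulator output
#'   directory.
#' @param out_dir Optional output directory for stage TSVs and the cached
#'   report.
#' @param stages Named logical vector toggling stages: annotate,
#'   orthologs, dnds, conversion, pairs, loci.
#' @param thresholds list: \code{identity} (pairing threshold, percent),
#'   \code{min_len} (conversion tract codons), \code{alpha}, \code{reps}.
#' @param seed Integer seed for all permutation tests.
#' @return A \code{run_report} list with one entry per executed stage,
#'   plus \code{thresholds}, \code{seed} and \code{warnings}.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         stages = c(annotate = TRUE, orthologs = TRUE,
                                    dnds = TRUE, conversion = TRUE,
                                    pairs = TRUE, loci = TRUE),
                         thresholds = list(identity = 80, min_len = 15,
                                           alpha = 0.05, reps = 999),
                         seed = 1L) {
  need <- function(stage, dep) {
    if (isTRUE(stages[[stage]]) && !isTRUE(stages[[dep]]))
      stop("stage '", stage, "' requires disabled stage '", dep, "'")
  }
  need("orthologs", "annotate"); need("dnds", "orthologs")
  need("conversion", "annotate"); need("pairs", "annotate")
  need("loci", "orthologs")

  from_dir <- is.character(input)
  if (from_dir) {
    files <- file.path(input, c("chromosomes.fa", "genes.gff3"))
    sums <- tools::md5sum(files)
    if (!is.null(out_dir)) {
      cache <- file.path(out_dir, "run_cache.rds")
      if (file.exists(cache)) {
        prev <- readRDS(cache)
        if (identical(prev$checksums, sums) &&
            identical(prev$thresholds, thresholds) &&
            identical(prev$seed, seed)) {
          prev$report$cached <- TRUE
          return(prev$report)
        }
      }
    }
    chromosomes <- read_fasta(files[1])
    models <- gene_models_from_gff(read_gff3(files[2]))
  } else {
    stopifnot(inherits(input, "sim_family"))
    sums <- NULL
    chromosomes <- input$chromosomes
    models <- input$genes
  }

  report <- list(seed = seed, thresholds = thresholds,
                 warnings = character(0), cached = FALSE)
  ann <- NULL
  if (isTRUE(stages[["annotate"]])) {
    ann <- annotate_genes(models, chromosomes)
    tab <- ann$table
    # one multiple alignment of all N domains feeds the subgroup split,
    # the identity matrix and the orthology stage
    msa <- align_proteins(ann$n_peptides[tab$id])
    pdm <- msa_distances(msa)
    # subgroups recomputed from N-domain sequences (family-wide split)
    sg <- assign_subgroups(ann$n_peptides[tab$id], pdm = pdm)
    tab$subgroup <- paste0("cluster", sg$membership[tab$id])
    ann$table <- tab
    ann$identity <- pdm$identity
    report$annotate <- tab
    report$subgroup_split <- sg[c("split", "identity_within",
                                  "identity_between")]
  }
  orth <- NULL
  if (isTRUE(stages[["orthologs"]])) {
    tab <- ann$table
    # species unit from the id prefix the simulator writes (A_*, B_*)
    unit <- sub("_.*$", "", tab$id)
    # reciprocal-best-hit relations are called on full-CDS nucleotide
    # identity: all exons contribute signal, and an N-exon-restricted
    # gene conversion cannot displace a gene's true ortholog
    cds <- .cds_nt(models, chromosomes)[tab$id]
    cds_identity <- msa_distances(align_proteins(cds), model = "p")$identity
    orth <- call_orthologs(cds, species = unit,
                           tags = tab$homeolog, identity = cds_identity)
    report$orthologs <- orth
  }
  if (isTRUE(stages[["dnds"]])) {
    nseq <- .n_exon_nt(models, chromosomes)
    keep <- orth$relation %in% c("ortholog", "homeolog")
    dn <- list()
    pseudo <- ann$table$id[ann$table$pseudogene]
    for (i in which(keep)) {
      a <- orth$gene_a[i]; b <- orth$gene_b[i]
      if (a %in% pseudo || b %in% pseudo) {
        report$warnings <- c(report$warnings,
                             paste0("dnds skipped (pseudogene): ", a, "~", b))
        next
      }
      aln <- align_codons_by_protein(nseq[[a]], nseq[[b]], ids = c(a, b))
      dn[[paste(a, b, sep = "~")]] <- pairwise_dnds(aln)
    }
    report$dnds <- dn
    cls <- setNames(ann$table$class, ann$table$id)
    first_gene <- sub("~.*$", "", names(dn))
    pair_class <- setNames(cls[first_gene], names(dn))
    rel <- setNames(orth$relation, paste(orth$gene_a, orth$gene_b,
                                         sep = "~"))[names(dn)]
    if (any(rel == "ortholog")) {
      report$ranking <- rank_selection(dn[rel == "ortholog"],
                                       pair_class[rel == "ortholog"])
    }
  }
  if (isTRUE(stages[["pairs"]])) {
    tab <- ann$table
    pr <- identify_paired_receptors(
      tab[, c("id", "strand", "class", "subgroup", "start", "end")],
      ann$n_peptides, identity_threshold = thresholds$identity,
      identity = ann$identity)
    report$pairs <- pr
  }
  if (isTRUE(stages[["conversion"]])) {
    nseq <- .n_exon_nt(models, chromosomes)
    scans <- list()
    cand <- report$pairs$pairs
    for (i in seq_len(NROW(cand))) {
      a <- cand$inhibitory[i]; b <- cand$activating[i]
      aln <- align_codons_by_protein(nseq[[a]], nseq[[b]], ids = c(a, b))
      scans[[paste(a, b, sep = "~")]] <-
        detect_conversion_tracts(aln, min_len = thresholds$min_len,
                                 reps = thresholds$reps, seed = seed,
                                 alpha = thresholds$alpha)
    }
    # Benjamini-Hochberg across all tract p-values in the batch
    allp <- unlist(lapply(scans, function(s) s$p_value))
    if (length(allp)) {
      adj <- stats::p.adjust(allp, method = "BH")
      k <- 0L
      for (nm in names(scans)) {
        np <- nrow(scans[[nm]])
        if (np) {
          scans[[nm]]$p_adjusted <- adj[k + seq_len(np)]
          k <- k + np
        }
      }
    }
    report$conversion <- scans
  }
  if (isTRUE(stages[["loci"]])) {
    tab <- ann$table
    gl <- tab[tab$homeolog == "L", c("id", "subgroup", "class")]
    gs <- tab[tab$homeolog == "S", c("id", "subgroup", "class")]
    if (nrow(gl) && nrow(gs)) {
      report$loci <- compare_homeologous_loci(gl, gs, orth,
                                              pairs_a = report$pairs$pairs,
                                              pairs_b = report$pairs$pairs)
    }
  }
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$annotate))
      utils::write.table(report$annotate,
                         file.path(out_dir, "gene_table.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(report$orthologs))
      utils::write.table(report$orthologs,
                         file.path(out_dir, "orthologs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(report$dnds))
      write_dnds_tsv(report$dnds, file.path(out_dir, "dnds.tsv"))
    if (!is.null(report$pairs))
      utils::write.table(report$pairs$pairs,
                         file.path(out_dir, "paired_receptors.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (from_dir)
      saveRDS(list(checksums = sums, thresholds = thresholds, seed = seed,
                   report = report),
              file.path(out_dir, "run_cache.rds"))
  }
  report
}

# full coding (all-exon) nucleotide sequence per gene model
.cds_nt <- function(models, chromosomes) {
  out <- character(0)
  for (g in models) {
    ex <- gene_exon_seqs(g, chromosomes[[g$chrom]])
    out[g$id] <- paste(ex, collapse = "")
  }
  out
}

# N-exon nucleotide sequence (coding strand) per gene model
.n_exon_nt <- function(models, chromosomes) {
  out <- character(0)
  for (g in models) {
    ex <- gene_exon_seqs(g, chromosomes[[g$chrom]])
    out[g$id] <- paste(ex[g$exons$kind == "N"], collapse = "")
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline report (seed ", x$seed,
      if (isTRUE(x$cached)) ", cached" else "", ")\n", sep = "")
  for (st in c("annotate", "orthologs", "dnds", "conversion", "pairs",
               "loci")) {
    if (!is.null(x[[st]])) {
      n <- if (is.data.frame(x[[st]])) nrow(x[[st]]) else length(x[[st]])
      cat("  ", st, ": ", n, " records\n", sep = "")
    }
  }
  invisible(x)
}
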