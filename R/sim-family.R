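# Forward simulator of a tandem paired-receptor gene cluster: tandem
# duplication before speciation, speciation into two species, an
# allotetraploidization that duplicates the second species' locus into L
# and S copies, scheduled S-locus gene losses, exon-restricted gene
# conversion between paired-receptor N exons, pseudogenization, and
# ITIM/ITAM motif cassettes in cytoplasmic exons. Emits chromosome FASTA,
# GFF3 gene models, per-gene exon FASTA and a truth table.

# Peptide cassettes: tyrosine-free scaffold so signaling classes are
# exactly the programmed ones; cytoplasmic exons evolve with omega 0
# (tails conserved) so cassette peptides are stable.
.CASSETTES <- list(
  inhibitory = "SVYAQLPRTEEDTEYSEVKAR",
  activating = "YEGLNLDDCSMYEDIKAPTRG",
  none       = "SAPLRDTEEGKARNPLQDSVG"
)

.AA_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# Deterministic reverse translation (first codon of each amino acid).
.encode_peptide <- function(pep) {
  vapply(strsplit(pep, "")[[1]], function(a) .AA_CODON[[a]][1], character(1))
}

# Tyrosine- and stop-free random peptide scaffold, as codons.
.scaffold_codons <- function(n) {
  aas <- setdiff(names(.AA_CODON), c("*", "Y"))
  vapply(sample(aas, n, replace = TRUE),
         function(a) sample(.AA_CODON[[a]], 1), character(1))
}

#' Default simulation scenario configuration
#'
#' A Xenopus-like two-subgroup cluster: 20 + 18 genes founded by tandem
#' duplication deep in the past, speciation at 60 time units before
#' present, allotetraploidization of species B at 40 with loss of most
#' S-locus genes at 35, full-N-exon gene conversion from the inhibitory
#' to the activating paired-receptor genes at 2, diversifying selection
#' (omega_sel) confined to beta-strand windows of inhibitory-gene N
#' exons, and a few programmed pseudogenes.
#'
#' @param seed Integer seed.
#' @return A \code{sim_config} list; see fields in the source or the
#'   package vignette.
#' @export
xenopus_like_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    times = list(root = 120, dup_start = 118, dup_end = 90,
                 speciation = 60, allo = 40, losses = 35, conversion = 2),
    rates = list(mu = 0.006, intron_mult = 1.5, kappa = 1),
    template = list(leader = 19, N = 107, IgC = 93, TM = 24, cyt = 40,
                    introns = c(250L, 250L, 250L, 250L),
                    intergenic = 400L),
    omega = list(bg = 0.2, sel = 2.0,
                 windows = data.frame(start = c(26, 37, 47, 77, 91),
                                      end   = c(35, 44, 55, 87, 101))),
    subgroups = list(
      group1 = list(n = 20, inhibitory = "g1_01", activating = "g1_02"),
      group2 = list(n = 18, inhibitory = "g2_01",
                    activating = c("g2_02", "g2_03"))),
    extra_itim = c("g1_10", "g2_10"),
    gpi = c("g1_15", "g2_15"),
    s_retained = c("g1_05", "g2_01", "g2_07", "g2_15"),
    pseudogenes = data.frame(
      base = c("g1_12", "g2_09"),
      species = c("A", "B"),
      tag = c("none", "L"),
      mode = c("stop", "splice_donor")),
    conversion_tract = NULL  # NULL = full N exon
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation scenario from YAML
#' @param path YAML file with the fields of [xenopus_like_config()].
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$omega$windows))
    cfg$omega$windows <- as.data.frame(cfg$omega$windows)
  if (!is.null(cfg$pseudogenes))
    cfg$pseudogenes <- as.data.frame(cfg$pseudogenes)
  class(cfg) <- "sim_config"
  cfg
}

# base ids of one subgroup
.subgroup_bases <- function(name, n) {
  sprintf("%s_%02d", sub("group", "g", name), seq_len(n))
}

.gene_class_of <- function(cfg, base) {
  for (sg in cfg$subgroups) {
    if (base %in% sg$inhibitory) return("inhibitory")
    if (base %in% sg$activating) return("activating")
  }
  if (base %in% cfg$extra_itim) return("inhibitory")
  "none"
}

# codon offsets of the five exons within the coding sequence
.exon_layout <- function(tpl) {
  lens <- c(leader = tpl$leader, N = tpl$N, IgC = tpl$IgC,
            TM = tpl$TM, cytoplasmic = tpl$cyt)
  ends <- cumsum(lens)
  data.frame(kind = names(lens), cstart = c(0, ends[-5]), cend = ends,
             row.names = NULL)
}

# per-codon omega vector for one gene
.gene_omega <- function(cfg, class) {
  tpl <- cfg$template
  lay <- .exon_layout(tpl)
  om <- rep(cfg$omega$bg, lay$cend[5])
  if (class == "inhibitory") {
    noff <- lay$cstart[lay$kind == "N"]
    w <- cfg$omega$windows
    for (i in seq_len(nrow(w)))
      om[(noff + w$start[i] + 1):(noff + w$end[i])] <- cfg$omega$sel
  }
  cy <- lay[lay$kind == "cytoplasmic", ]
  om[(cy$cstart + 1):cy$cend] <- 0   # conserved tails: cassettes stable
  om
}

# install the class cassette into a gene's cytoplasmic exon codons
.install_cassette <- function(coding, cfg, class) {
  tpl <- cfg$template
  lay <- .exon_layout(tpl)
  cy <- lay[lay$kind == "cytoplasmic", ]
  scaff <- .scaffold_codons(tpl$cyt)
  cass <- .encode_peptide(.CASSETTES[[class]])
  at <- 5L  # cassette begins at codon 6 of the cytoplasmic exon
  scaff[(at + 1):(at + length(cass))] <- cass
  coding[(cy$cstart + 1):cy$cend] <- scaff
  coding
}

.random_intron <- function(len) {
  paste0("GT", paste(sample(.BASES, len - 4L, replace = TRUE),
                     collapse = ""), "AG")
}

# evolve intron middle (splice dinucleotides fixed)
.evolve_intron <- function(intr, subs) {
  n <- nchar(intr)
  mid <- evolve_neutral(substr(intr, 3, n - 2L), subs)
  paste0(substr(intr, 1, 2), mid, substr(intr, n - 1L, n))
}

#' Simulate the evolution of a paired-receptor gene cluster
#'
#' Runs the event schedule of a \code{sim_config} forward in time and
#' emits per-species chromosome sequences, gene models, exon sequences
#' and a truth table. Deterministic under the configuration seed.
#'
#' @param cfg A \code{sim_config}, e.g. [xenopus_like_config()].
#' @param out_dir Optional directory: writes chromosome FASTA, GFF3,
#'   exon FASTA, truth JSON/TSV and a manifest.
#' @return A \code{sim_family} list: \code{chromosomes} (named character
#'   vector), \code{gff} (feature data.frame, internal coordinates),
#'   \code{genes} (named list of \code{gene_model}), \code{exon_seqs}
#'   (named character vector, names \code{<gene>|<kind>}), \code{truth}
#'   (list: gene table, event log, programmed pairs, omega windows).
#' @export
simulate_family <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  res <- .with_seed(cfg$seed, .simulate_family_run(cfg))
  if (!is.null(out_dir)) .write_sim_outputs(res, cfg, out_dir)
  res
}

.simulate_family_run <- function(cfg) {
  tpl <- cfg$template
  lay <- .exon_layout(tpl)
  n_cod <- lay$cend[5]
  mu <- cfg$rates$mu
  events <- list()
  log_event <- function(time, type, detail) {
    events[[length(events) + 1L]] <<- data.frame(time = time, type = type,
                                                 detail = detail)
  }

  # founders (one per subgroup) and duplication schedule
  genes <- list()
  new_gene <- function(base, subgroup, coding, introns) {
    class <- .gene_class_of(cfg, base)
    coding <- .install_cassette(coding, cfg, class)
    list(base = base, subgroup = subgroup, species = "anc", tag = "none",
         coding = coding, introns = introns,
         omega = .gene_omega(cfg, class), class = class,
         anchoring = if (base %in% cfg$gpi) "GPI" else "TM",
         alive = TRUE, n_lineage = base)
  }
  dup_sched <- data.frame(time = numeric(0), base = character(0),
                          parent = character(0), subgroup = character(0))
  for (sgn in names(cfg$subgroups)) {
    sg <- cfg$subgroups[[sgn]]
    bases <- .subgroup_bases(sgn, sg$n)
    founder_coding <- random_codon_sequence(n_cod)
    introns <- vapply(tpl$introns, .random_intron, character(1))
    genes[[bases[1]]] <- new_gene(bases[1], sgn, founder_coding, introns)
    if (sg$n > 1) {
      times <- seq(cfg$times$dup_start, cfg$times$dup_end,
                   length.out = sg$n - 1)
      # caterpillar expansion: each new gene buds off the previous one
      dup_sched <- rbind(dup_sched, data.frame(
        time = times, base = bases[-1], parent = bases[-sg$n],
        subgroup = sgn))
    }
  }
  dup_sched <- dup_sched[order(-dup_sched$time), ]

  # timeline: merge duplication events with the fixed epochs
  timeline <- rbind(
    data.frame(time = dup_sched$time, type = "dup", base = dup_sched$base,
               parent = dup_sched$parent, subgroup = dup_sched$subgroup),
    data.frame(time = cfg$times$speciation, type = "speciation",
               base = NA, parent = NA, subgroup = NA),
    data.frame(time = cfg$times$allo, type = "allo",
               base = NA, parent = NA, subgroup = NA),
    data.frame(time = cfg$times$losses, type = "losses",
               base = NA, parent = NA, subgroup = NA),
    data.frame(time = cfg$times$conversion, type = "conversions",
               base = NA, parent = NA, subgroup = NA),
    data.frame(time = 0, type = "end", base = NA, parent = NA,
               subgroup = NA))
  timeline <- timeline[order(-timeline$time), ]
  if (is.unsorted(rev(timeline$time)))
    stop("inconsistent event schedule")

  evolve_all <- function(dt) {
    if (dt <= 0) return(invisible())
    b <- mu * dt
    for (k in seq_along(genes)) {
      g <- genes[[k]]
      if (!g$alive) next
      g$coding <- evolve_codon_sequence(g$coding, b, g$omega,
                                        kappa = cfg$rates$kappa)
      g$introns <- vapply(g$introns, .evolve_intron, character(1),
                          subs = b * cfg$rates$intron_mult)
      genes[[k]] <<- g
    }
  }

  now <- cfg$times$root
  key <- function(g) paste(g$species, g$tag, g$base, sep = "/")
  for (ev in seq_len(nrow(timeline))) {
    evolve_all(now - timeline$time[ev])
    now <- timeline$time[ev]
    tp <- timeline$type[ev]
    if (tp == "dup") {
      pk <- which(vapply(genes, function(g)
        g$base == timeline$parent[ev] & g$alive, logical(1)))[1]
      child <- genes[[pk]]
      child$base <- timeline$base[ev]
      child$class <- .gene_class_of(cfg, child$base)
      child$coding <- .install_cassette(child$coding, cfg, child$class)
      child$omega <- .gene_omega(cfg, child$class)
      child$anchoring <- if (child$base %in% cfg$gpi) "GPI" else "TM"
      child$n_lineage <- child$base
      genes[[child$base]] <- child
      log_event(now, "duplication",
                paste(timeline$parent[ev], "->", child$base))
    } else if (tp == "speciation") {
      sp <- list()
      for (g in genes) {
        ga <- g; ga$species <- "A"
        gb <- g; gb$species <- "B"
        sp[[key(ga)]] <- ga
        sp[[key(gb)]] <- gb
      }
      genes <- sp
      log_event(now, "speciation", "anc -> A + B")
    } else if (tp == "allo") {
      sp <- list()
      for (g in genes) {
        if (g$species == "B") {
          gl <- g; gl$tag <- "L"
          gs <- g; gs$tag <- "S"
          sp[[key(gl)]] <- gl
          sp[[key(gs)]] <- gs
        } else sp[[key(g)]] <- g
      }
      genes <- sp
      log_event(now, "allotetraploidization", "B locus -> L + S")
    } else if (tp == "losses") {
      for (k in seq_along(genes)) {
        g <- genes[[k]]
        if (g$species == "B" && g$tag == "S" &&
            !(g$base %in% cfg$s_retained)) {
          genes[[k]]$alive <- FALSE
          log_event(now, "loss", key(g))
        }
      }
    } else if (tp == "conversions") {
      noff <- lay$cstart[lay$kind == "N"]
      nlen <- tpl$N
      tract <- cfg$conversion_tract %||% c(0L, nlen)
      for (sgn in names(cfg$subgroups)) {
        sg <- cfg$subgroups[[sgn]]
        for (ctx in list(c("A", "none"), c("B", "L"))) {
          dk <- paste(ctx[1], ctx[2], sg$inhibitory, sep = "/")
          if (is.null(genes[[dk]]) || !genes[[dk]]$alive) next
          for (acc in sg$activating) {
            ak <- paste(ctx[1], ctx[2], acc, sep = "/")
            if (is.null(genes[[ak]]) || !genes[[ak]]$alive) next
            don_n <- genes[[dk]]$coding[(noff + 1):(noff + nlen)]
            acc_n <- genes[[ak]]$coding[(noff + 1):(noff + nlen)]
            genes[[ak]]$coding[(noff + 1):(noff + nlen)] <-
              apply_conversion(acc_n, don_n, tract[1], tract[2])
            genes[[ak]]$n_lineage <- genes[[dk]]$n_lineage
            log_event(now, "conversion",
                      paste0(dk, " -> ", ak, " codons [", tract[1], ",",
                             tract[2], ")"))
          }
        }
      }
    }
  }

  .emit_family(cfg, genes, do.call(rbind, events), lay)
}

# strand of a gene: activating genes face the rest of their subcluster
.gene_strand <- function(cfg, base) {
  if (.gene_class_of(cfg, base) == "activating") "-" else "+"
}

.emit_family <- function(cfg, genes, event_log, lay) {
  tpl <- cfg$template
  live <- Filter(function(g) g$alive, genes)
  # deterministic chromosome order: subgroup, then base index
  ord <- order(vapply(live, `[[`, character(1), "subgroup"),
               vapply(live, `[[`, character(1), "base"))
  live <- live[ord]
  chrom_of <- function(g) {
    if (g$species == "A") "chrA7"
    else if (g$tag == "L") "chrB7L" else "chrB7S"
  }
  gid <- function(g) {
    if (g$species == "A") paste0("A_", g$base)
    else paste0("B_", g$base, ".", g$tag)
  }

  # pseudogenization (emission-time lesions), logged
  ps <- cfg$pseudogenes
  pseudo_ids <- character(0)
  for (i in seq_len(NROW(ps))) {
    k <- paste(ps$species[i], ps$tag[i], ps$base[i], sep = "/")
    pos <- which(vapply(live, function(g)
      identical(paste(g$species, g$tag, g$base, sep = "/"), k), logical(1)))
    if (!length(pos)) next
    g <- live[[pos]]
    noff <- lay$cstart[lay$kind == "N"]
    if (ps$mode[i] == "stop") {
      g$coding[noff + 40L] <- "TAA"
    } else if (ps$mode[i] == "splice_donor") {
      # corrupt the donor of the intron following the N exon
      g$introns[2] <- paste0("CC", substr(g$introns[2], 3,
                                          nchar(g$introns[2])))
    } else {
      g$introns[1] <- paste0(substr(g$introns[1], 1,
                                    nchar(g$introns[1]) - 2L), "CC")
    }
    live[[pos]] <- g
    pseudo_ids <- c(pseudo_ids, gid(g))
  }

  chroms <- list(chrA7 = character(0), chrB7L = character(0),
                 chrB7S = character(0))
  cursor <- c(chrA7 = 0L, chrB7L = 0L, chrB7S = 0L)
  gff <- list()
  models <- list()
  exon_seqs <- character(0)
  truth_rows <- list()

  for (g in live) {
    chrom <- chrom_of(g)
    strand <- .gene_strand(cfg, g$base)
    spacer <- paste(sample(.BASES, tpl$intergenic, replace = TRUE),
                    collapse = "")
    # gene unit on the coding strand: exon1 intron1 ... exon5
    ex_nt <- vapply(seq_len(5), function(i)
      paste(g$coding[(lay$cstart[i] + 1):lay$cend[i]], collapse = ""),
      character(1))
    parts <- character(0)
    offs <- matrix(0L, 5, 2)
    at <- 0L
    for (i in seq_len(5)) {
      offs[i, ] <- c(at, at + nchar(ex_nt[i]))
      parts <- c(parts, ex_nt[i])
      at <- at + nchar(ex_nt[i])
      if (i < 5) {
        parts <- c(parts, g$introns[i])
        at <- at + nchar(g$introns[i])
      }
    }
    unit <- paste(parts, collapse = "")
    ulen <- nchar(unit)
    gstart <- cursor[[chrom]] + tpl$intergenic
    if (strand == "-") {
      unit_out <- .revcomp(unit)
      ex_iv <- cbind(gstart + ulen - offs[, 2], gstart + ulen - offs[, 1])
    } else {
      unit_out <- unit
      ex_iv <- cbind(gstart + offs[, 1], gstart + offs[, 2])
    }
    chroms[[chrom]] <- c(chroms[[chrom]], spacer, unit_out)
    cursor[[chrom]] <- gstart + ulen

    id <- gid(g)
    exdf <- data.frame(start = ex_iv[, 1], end = ex_iv[, 2],
                       kind = lay$kind, phase = 0L)
    if (strand == "-") exdf <- exdf  # rows already in coding order
    models[[id]] <- gene_model(id, chrom, strand, exdf,
                               subgroup = g$subgroup, homeolog = g$tag,
                               anchoring = g$anchoring)
    gff[[length(gff) + 1L]] <- data.frame(
      seqid = chrom, source = "sim", type = "gene",
      start = gstart, end = gstart + ulen, score = ".", strand = strand,
      phase = ".",
      attributes = sprintf("ID=%s;subgroup=%s;homeolog=%s;anchoring=%s",
                           id, g$subgroup, g$tag, g$anchoring))
    gff[[length(gff) + 1L]] <- data.frame(
      seqid = chrom, source = "sim", type = "exon",
      start = exdf$start, end = exdf$end, score = ".", strand = strand,
      phase = "0",
      attributes = sprintf("Parent=%s;exon_kind=%s", id, exdf$kind))
    names(ex_nt) <- paste0(id, "|", lay$kind)
    exon_seqs <- c(exon_seqs, ex_nt)
    truth_rows[[id]] <- data.frame(
      id = id, base = g$base, species = g$species, tag = g$tag,
      subgroup = g$subgroup, class = g$class, anchoring = g$anchoring,
      strand = strand, pseudogene = id %in% pseudo_ids,
      n_lineage = g$n_lineage)
  }

  pairs <- do.call(rbind, lapply(names(cfg$subgroups), function(sgn) {
    sg <- cfg$subgroups[[sgn]]
    expand.grid(inhibitory = sg$inhibitory, activating = sg$activating,
                subgroup = sgn, stringsAsFactors = FALSE)
  }))

  structure(list(
    chromosomes = vapply(chroms, paste, character(1), collapse = ""),
    gff = do.call(rbind, gff),
    genes = models,
    exon_seqs = exon_seqs,
    truth = list(genes = do.call(rbind, c(truth_rows,
                                          make.row.names = FALSE)),
                 events = event_log,
                 pairs = pairs,
                 omega_windows = cfg$omega$windows,
                 s_retained = cfg$s_retained)),
    class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat("simulated gene family:", nrow(x$truth$genes), "genes on",
      length(x$chromosomes), "chromosomes\n")
  print(table(x$truth$genes$species, x$truth$genes$tag))
  invisible(x)
}

.write_sim_outputs <- function(res, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(res$chromosomes, p("chromosomes.fa"))
  write_gff3(res$gff, p("genes.gff3"))
  write_fasta(res$exon_seqs, p("exons.fa"))
  utils::write.table(res$truth$genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$truth$events, p("truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = cfg$seed,
                            pairs = res$truth$pairs,
                            s_retained = res$truth$s_retained,
                            files = c("chromosomes.fa", "genes.gff3",
                                      "exons.fa", "truth_genes.tsv",
                                      "truth_events.tsv")),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
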