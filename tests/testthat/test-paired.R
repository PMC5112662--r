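# helpers: peptide pairs at controlled identity
.pep_pair <- function(n = 100, diff = 10) {
  a <- paste(rep("ACDEFGHIKLMNPQRSTVWA", n / 20), collapse = "")
  x <- strsplit(a, "")[[1]]
  swap <- c(A = "G", C = "W", D = "E", E = "D", F = "Y", G = "A", H = "N",
            I = "L", K = "R", L = "I", M = "V", N = "H", P = "S", Q = "K",
            R = "Q", S = "P", T = "M", V = "T", W = "C", Y = "F")
  if (diff > 0) {
    at <- seq(1, n, length.out = diff)
    x[at] <- swap[x[at]]
  }
  c(a = a, b = paste(x, collapse = ""))
}

test_that("paired-receptor identification applies all three conditions", {
  hi <- .pep_pair(100, 15)   # 85 % identity
  lo <- .pep_pair(100, 40)   # 60 % identity
  genes <- data.frame(
    id = c("inh", "act_hi", "act_lo", "act_same_strand", "amb"),
    strand = c("+", "-", "-", "+", "-"),
    class = c("inhibitory", "activating", "activating", "activating",
              "ambiguous"),
    subgroup = "g1",
    start = c(0, 1000, 2000, 3000, 4000),
    end = c(500, 1500, 2500, 3500, 4500))
  seqs <- c(inh = unname(hi["a"]), act_hi = unname(hi["b"]),
            act_lo = unname(lo["b"]), act_same_strand = unname(hi["b"]),
            amb = unname(hi["b"]))
  out <- identify_paired_receptors(genes, seqs, identity_threshold = 80)
  expect_equal(out$pairs$inhibitory, "inh")
  expect_equal(out$pairs$activating, "act_hi")
  expect_gte(out$pairs$identity, 80)
  expect_equal(out$ambiguous, "amb")
  # one inhibitory gene may pair with several activating genes
  genes2 <- genes[genes$id != "amb", ]
  seqs2 <- seqs
  seqs2[["act_lo"]] <- unname(hi["b"])
  out2 <- identify_paired_receptors(genes2, seqs2, identity_threshold = 80)
  expect_equal(nrow(out2$pairs), 2)
  expect_equal(unique(out2$pairs$inhibitory), "inh")
})

test_that("selection ranking orders by ratio with undefined ratios last", {
  mk <- function(ratio, dN = 0.2, dS = 0.2) {
    structure(list(ratio = ratio, dN = dN, dS = dS), class = "dnds")
  }
  dn <- list(A = mk(1.3), B = mk(0.4), C = mk(0.2))
  cls <- c(A = "inhibitory", B = "activating", C = "none")
  rk <- rank_selection(dn, cls)
  expect_equal(rk$pair, c("A", "B", "C"))
  expect_true(attr(rk, "itim_top"))
  # ties broken stably by label
  rk2 <- rank_selection(list(B = mk(0.5), A = mk(0.5)),
                        c(A = "none", B = "none"))
  expect_equal(rk2$pair, c("A", "B"))
  # undefined ranked last regardless of dN
  rk3 <- rank_selection(list(A = mk(NA_real_, dN = 9), B = mk(0.1)),
                        c(A = "inhibitory", B = "none"))
  expect_equal(rk3$pair, c("B", "A"))
  expect_false(attr(rk3, "itim_top"))
  expect_warning(rank_selection(list(A = mk(NA_real_)),
                                c(A = "none")), "undefined")
})

test_that("homeologous locus comparison computes fates and loss fraction", {
  ga <- data.frame(id = paste0("L", 1:10), subgroup = rep(c("g1", "g2"), 5),
                   class = rep(c("inhibitory", "none"), 5))
  gb <- data.frame(id = c("S1", "S2"), subgroup = c("g1", "g2"),
                   class = c("inhibitory", "none"))
  orth <- data.frame(gene_a = c("L1", "L2"), gene_b = c("S1", "S2"),
                     species_a = "B", species_b = "B",
                     relation = "homeolog", identity = 90, tie = FALSE)
  cmp <- compare_homeologous_loci(ga, gb, orth)
  expect_equal(cmp$loss_fraction, 0.8)
  expect_equal(cmp$retained, 2)
  expect_equal(cmp$gained, 0)
  expect_equal(sum(cmp$fates$fate == "lost-from-b"), 8)
  # retention + loss fractions sum to one
  expect_equal(cmp$retained / nrow(ga) + cmp$loss_fraction, 1)
  # identical loci: no loss
  orth2 <- data.frame(gene_a = ga$id, gene_b = paste0("S", 1:10),
                      species_a = "B", species_b = "B",
                      relation = "homeolog", identity = 95, tie = FALSE)
  gb2 <- data.frame(id = paste0("S", 1:10), subgroup = ga$subgroup,
                    class = ga$class)
  expect_equal(compare_homeologous_loci(ga, gb2, orth2)$loss_fraction, 0)
})

test_that("inhibitory orthologs top the ranking when selection targets them", {
  # generator places omega > 1 only on inhibitory-gene N exons; the top
  # of the ortholog dN/dS ranking should be an inhibitory pair in nearly
  # all replicates. Conversions are disabled (zero-length tract): a
  # converted decoy N exon is a copy of the inhibitory donor's and would
  # carry the same selected sites.
  top_inh <- 0
  reps <- 8
  for (i in seq_len(reps)) {
    cfg <- small_sim_config(seed = 400 + i)
    cfg$conversion_tract <- c(0L, 0L)
    fam <- simulate_family(cfg)
    tr <- fam$truth$genes
    nseq <- .n_exon_nt(fam$genes, fam$chromosomes)
    a_side <- tr[tr$species == "A" & !tr$pseudogene, ]
    dn <- list()
    cls <- character(0)
    for (k in seq_len(nrow(a_side))) {
      b_id <- paste0("B_", a_side$base[k], ".L")
      if (!b_id %in% tr$id[!tr$pseudogene]) next
      key <- paste(a_side$id[k], b_id, sep = "~")
      dn[[key]] <- pairwise_dnds(edit_alignment(nseq[[a_side$id[k]]],
                                                nseq[[b_id]]))
      cls[key] <- a_side$class[k]
    }
    rk <- rank_selection(dn, cls)
    if (isTRUE(attr(rk, "itim_top"))) top_inh <- top_inh + 1
  }
  expect_gte(top_inh / reps, 0.9)
})
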