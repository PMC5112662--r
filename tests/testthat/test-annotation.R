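test_that("motif scanning finds the canonical consensi with precedence", {
  m1 <- scan_motifs("AASVYAQLAA")
  expect_equal(nrow(m1), 1)
  expect_equal(m1$kind, "ITIM")
  expect_equal(m1$offset, 2)
  expect_equal(m1$match, "SVYAQL")

  m2 <- scan_motifs("YEGLAAAAAAAYSEI")
  expect_equal(m2$kind, "ITAM")   # single modules suppressed by the ITAM
  expect_equal(m2$offset, 0)

  # ITIM and ITSM reported independently when both consensi match
  # (module spacing 8 falls outside the ITAM and ITAM-like windows)
  m3 <- scan_motifs("AASVYAQLAAAAAATAYAAV")
  expect_setequal(m3$kind, c("ITIM", "ITSM"))

  expect_equal(nrow(scan_motifs("")), 0)
  expect_equal(nrow(scan_motifs("AAAAAA")), 0)

  # a lone Yxx[ILV] module is ITAM-like only in an ITIM-free tail
  m4 <- scan_motifs("AAYAAVAA")
  expect_equal(m4$kind, "ITAM-like")
  m5 <- scan_motifs("AAYAAVAAAASVYAQLAA")  # ITIM present: no lone module
  expect_false("ITAM-like" %in% m5$kind)

  # position stability: prepending k residues shifts offsets by k
  base <- "AASVYAQLAA"
  for (k in c(1, 5, 12)) {
    shifted <- scan_motifs(paste0(strrep("G", k), base))
    expect_equal(shifted$offset, scan_motifs(base)$offset + k)
  }
})

test_that("signaling classification follows the motif-class rules", {
  expect_equal(classify_signaling(scan_motifs("AASVYAQLAA")), "inhibitory")
  expect_equal(classify_signaling(scan_motifs("YEGLAAAAAAAYSEI")),
               "activating")
  expect_equal(classify_signaling(scan_motifs(
    "AASVYAQLAAGGYEGLAAAAAAAYSEI")), "ambiguous")
  expect_equal(classify_signaling(scan_motifs("AAAAAA")), "none")
})

# A two-exon gene (N exon + other) with one intron, built on both strands.
make_test_gene <- function(strand = "+", n_exon = "ATGGTTCCTGAC",
                           intron = "GTAAGTTTTTAG", other = "GGATCC") {
  if (strand == "+") {
    chrom <- paste0("AAAA", n_exon, intron, other, "TTTT")
    exons <- data.frame(start = c(4, 4 + nchar(n_exon) + nchar(intron)),
                        end = c(4 + nchar(n_exon),
                                4 + nchar(n_exon) + nchar(intron) +
                                  nchar(other)),
                        kind = c("N", "IgC"), phase = 0L)
  } else {
    unit <- paste0(n_exon, intron, other)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(unit)))
    chrom <- paste0("AAAA", rc, "TTTT")
    u <- nchar(unit)
    exons <- data.frame(
      start = c(4 + u - nchar(n_exon), 4),
      end = c(4 + u, 4 + nchar(other)),
      kind = c("N", "IgC"), phase = 0L)
  }
  list(gene = gene_model("g", "chr", strand, exons), chrom = chrom)
}

test_that("pseudogene calling is strand-aware and reason-specific", {
  ok <- make_test_gene("+")
  expect_equal(call_pseudogene(ok$gene, ok$chrom)$status, "intact")

  stopg <- make_test_gene("+", n_exon = "ATGTAACCTGAC")
  ps <- call_pseudogene(stopg$gene, stopg$chrom)
  expect_equal(ps$status, "pseudogene")
  expect_true("internal stop" %in% ps$reasons)

  badd <- make_test_gene("+", intron = "CCAAGTTTTTAG")
  expect_true("bad splice donor" %in%
                call_pseudogene(badd$gene, badd$chrom)$reasons)
  bada <- make_test_gene("+", intron = "GTAAGTTTTTCC")
  expect_true("bad splice acceptor" %in%
                call_pseudogene(bada$gene, bada$chrom)$reasons)

  # the same gene on the minus strand is intact only with strand awareness
  minus <- make_test_gene("-")
  expect_equal(call_pseudogene(minus$gene, minus$chrom)$status, "intact")
  naive <- gene_model("g", "chr", "+",
                      minus$gene$exons[order(minus$gene$exons$start), ])
  expect_equal(call_pseudogene(naive, minus$chrom)$status, "pseudogene")

  out <- make_test_gene("+")
  bad_gene <- gene_model("g", "chr", "+",
                         data.frame(start = 4, end = 10000, kind = "N",
                                    phase = 0L))
  expect_error(call_pseudogene(bad_gene, out$chrom), "outside")
})

test_that("N-exon clustering applies the 1 percent divergence rule", {
  base <- paste(oracle_random_codons(100), collapse = "")
  mutate_at <- function(s, pos) {
    x <- strsplit(s, "")[[1]]
    for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    paste(x, collapse = "")
  }
  set.seed(2)
  near <- mutate_at(base, 7)               # 1/300 = 0.33 %
  far <- mutate_at(base, seq(10, 100, 10)) # 10/300 = 3.3 %
  expect_equal(cluster_n_exons(c(a = base, b = near))$n_distinct, 1)
  expect_equal(cluster_n_exons(c(a = base, b = far))$n_distinct, 2)
  expect_equal(cluster_n_exons(c(a = base, b = base))$n_distinct, 1)
  expect_equal(cluster_n_exons(character(0))$n_distinct, 0)
  # order invariance
  s3 <- c(a = base, b = near, c = far)
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    cl <- cluster_n_exons(s3[perm])
    expect_equal(cl$n_distinct, 2)
  }
})

test_that("exon runs collapse into genes by the N-run rule", {
  expect_equal(merge_exons_to_genes(
    data.frame(kind = c("N", "N", "IgC", "TM")))$n_genes, 1)
  expect_equal(merge_exons_to_genes(
    data.frame(kind = c("N", "IgC", "N", "TM")))$n_genes, 2)
  expect_equal(merge_exons_to_genes(data.frame(kind = character(0)))$n_genes,
               0)
  # never more genes than N-exon runs
  set.seed(3)
  for (i in 1:20) {
    kinds <- sample(c("leader", "N", "IgC", "TM"), 12, replace = TRUE)
    runs <- sum(rle(kinds == "N")$values)
    expect_lte(merge_exons_to_genes(data.frame(kind = kinds))$n_genes, runs)
  }
})

test_that("orientation pairing requires opposing classes on opposite strands", {
  genes <- data.frame(
    id = c("inh1", "act1", "act2", "inh2"),
    strand = c("+", "-", "+", "-"),
    class = c("inhibitory", "activating", "activating", "inhibitory"),
    subgroup = c("g1", "g1", "g1", "g1"),
    start = c(0, 1000, 2000, 3000), end = c(500, 1500, 2500, 3500))
  p <- orientation_pairs(genes)
  expect_true(all(p$inhibitory %in% c("inh1", "inh2")))
  # inh1(+) pairs act1(-); inh2(-) pairs act2(+); no same-strand pairs
  expect_setequal(paste(p$inhibitory, p$activating),
                  c("inh1 act1", "inh2 act2"))
  # same strand only -> nothing
  genes2 <- genes; genes2$strand <- "+"
  expect_equal(nrow(orientation_pairs(genes2)), 0)
  # ITIM/ITIM opposite strands -> nothing
  genes3 <- genes; genes3$class <- "inhibitory"
  expect_equal(nrow(orientation_pairs(genes3)), 0)
})

test_that("gff3 round-trips and gene models rebuild from it", {
  fam <- simulate_family(small_sim_config(seed = 4))
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(fam$gff, tmp)
  back <- read_gff3(tmp)
  expect_equal(back$start, fam$gff$start)
  expect_equal(back$end, fam$gff$end)
  expect_equal(back$attributes, fam$gff$attributes)
  models <- gene_models_from_gff(back)
  expect_setequal(names(models), names(fam$genes))
  g <- models[[1]]; g0 <- fam$genes[[g$id]]
  expect_equal(g$exons$start, g0$exons$start)
  expect_equal(g$exons$kind, g0$exons$kind)
  unlink(tmp)
  # malformed record errors with the line number
  bad <- tempfile()
  writeLines(c("##gff-version 3", "chr1\tx\tgene\t1"), bad)
  expect_error(read_gff3(bad), "line 2")
  unlink(bad)
})
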