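test_that("protein distances follow the closed forms", {
  a <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  expect_equal(protein_distance(a, a)$distance, 0)
  expect_equal(protein_distance(a, a)$identity, 100)
  b <- paste(rep("ACDEFGHIKM", 10), collapse = "")  # 10 mismatches / 100
  pd <- protein_distance(a, b, model = "p")
  expect_equal(pd$p, 0.1)
  expect_equal(pd$identity, 90)
  expect_equal(protein_distance(a, b, model = "poisson")$distance,
               -log(0.9), tolerance = 1e-9)
})

test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  # v_a = (5 + 9 - 10)/2 = 2, v_b = 3, v_c = 7
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0), 2, 2)))
  Dn <- D; Dn[1, 2] <- 99
  expect_error(build_nj_tree(Dn), "symmetric")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(31)
  for (i in 1:25) {
    tr <- ape::rtree(6, rooted = FALSE)
    D <- ape::cophenetic.phylo(tr)
    lab <- sort(rownames(D))
    mine <- build_nj_tree(D[lab, lab])
    expect_true(ape::dist.topo(ape::unroot(mine), ape::unroot(tr)) == 0)
    # agrees with the reference NJ implementation
    ref <- ape::nj(D[lab, lab])
    expect_true(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)) == 0)
  }
})

test_that("bootstrap supports are deterministic and saturate on clean clades", {
  # two clades with many diagnostic columns
  block1 <- paste(rep("AAAAAAAAAA", 4), collapse = "")
  block2 <- paste(rep("CCCCCCCCCC", 4), collapse = "")
  jitter <- function(s, at, to) { substr(s, at, at) <- to; s }
  aln <- c(t1 = block1, t2 = jitter(block1, 3, "D"),
           t3 = block2, t4 = jitter(block2, 5, "E"),
           t5 = jitter(block2, 9, "F"))
  bs <- bootstrap_support(aln, reps = 100, seed = 5)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  internal <- bs$support[!is.na(bs$support)]
  expect_true(any(internal == 100))   # the deep split is always recovered
  bs2 <- bootstrap_support(aln, reps = 100, seed = 5)
  expect_equal(bs$support, bs2$support)
})

test_that("subgroup assignment splits deep clades and flags uniform sets", {
  set.seed(17)
  anc1 <- random_codon_sequence(80)
  anc2 <- random_codon_sequence(80)
  mk <- function(anc, k) {
    vapply(seq_len(k), function(i)
      .translate_nt(paste(evolve_codon_sequence(anc, 0.15, 0.5),
                          collapse = "")), character(1))
  }
  seqs <- c(setNames(mk(anc1, 4), paste0("x", 1:4)),
            setNames(mk(anc2, 4), paste0("y", 1:4)))
  sg <- assign_subgroups(seqs)
  expect_true(sg$split)
  expect_equal(length(unique(sg$membership[paste0("x", 1:4)])), 1)
  expect_equal(length(unique(sg$membership[paste0("y", 1:4)])), 1)
  expect_true(sg$membership[["x1"]] != sg$membership[["y1"]])
  # within-group identity exceeds between-group identity
  expect_gt(min(sg$identity_within), max(sg$identity_between))
  # input order invariance
  sg2 <- assign_subgroups(seqs[sample(names(seqs))])
  same <- outer(sg$membership[names(seqs)], sg$membership[names(seqs)], "==")
  same2 <- outer(sg2$membership[names(seqs)], sg2$membership[names(seqs)],
                 "==")
  expect_equal(same, same2)
  # near-identical sequences: flagged, no split
  flat <- setNames(rep(paste(rep("ACDEFGHIKL", 8), collapse = ""), 4),
                   paste0("z", 1:4))
  expect_false(assign_subgroups(flat)$split)
})

test_that("ortholog, paralog and homeolog calls follow RBH rules", {
  set.seed(23)
  # two species; genes a,b duplicated before speciation; c1/c2 is a
  # recent within-species duplication (paralog pair)
  anc_a <- random_codon_sequence(90)
  anc_b <- evolve_codon_sequence(anc_a, 1.2, 0.5)
  pep <- function(cod, b = 0.2)
    .translate_nt(paste(evolve_codon_sequence(cod, b, 0.5), collapse = ""))
  seqs <- c(sp1_a = pep(anc_a), sp2_a = pep(anc_a),
            sp1_b = pep(anc_b), sp2_b = pep(anc_b))
  c_anc <- evolve_codon_sequence(anc_a, 1.0, 0.5)
  seqs <- c(seqs, sp1_c1 = pep(c_anc, 0.02), sp1_c2 = pep(c_anc, 0.02))
  species <- c("sp1", "sp2", "sp1", "sp2", "sp1", "sp1")
  calls <- call_orthologs(seqs, species)
  orth <- calls[calls$relation == "ortholog", ]
  expect_true(all(c("sp1_a sp2_a", "sp1_b sp2_b") %in%
                    paste(orth$gene_a, orth$gene_b)))
  par <- calls[calls$relation == "paralog-group", ]
  expect_true("sp1_c1 sp1_c2" %in% paste(par$gene_a, par$gene_b))
  # single species: paralog groups only
  solo <- call_orthologs(seqs[c(1, 5, 6)], rep("sp1", 3))
  expect_false("ortholog" %in% solo$relation)
  # homeologs across L/S tags within one species
  tags <- c("L", "none", "S", "none", "none", "none")
  hom <- call_orthologs(seqs, c("sp1", "sp2", "sp1", "sp2", "sp1", "sp1"),
                        tags = tags)
  hrows <- hom[hom$relation == "homeolog", ]
  expect_equal(paste(hrows$gene_a, hrows$gene_b), "sp1_a sp1_b")
})
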