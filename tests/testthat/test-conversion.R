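test_that("percent identity windows tile correctly and match a recount", {
  s <- paste(rep("ACGT", 250), collapse = "")
  w <- percent_identity_windows(s, s, window = 100, step = 25)
  expect_true(all(w$identity == 100))
  expect_equal(w$start[1], 0)
  expect_equal(w$end[1], 100)
  expect_equal(unique(diff(w$start)), 25)
  # alternating match/mismatch -> 50 %
  a <- paste(rep("AC", 100), collapse = "")
  b <- paste(rep("AG", 100), collapse = "")
  w2 <- percent_identity_windows(a, b, window = 20, step = 20)
  expect_true(all(w2$identity == 50))
  # random gapped pair: windows equal a direct recount
  set.seed(11)
  x <- sample(c("A", "C", "G", "T", "-"), 400, replace = TRUE)
  y <- sample(c("A", "C", "G", "T", "-"), 400, replace = TRUE)
  w3 <- percent_identity_windows(paste(x, collapse = ""),
                                 paste(y, collapse = ""),
                                 window = 50, step = 10)
  for (k in seq_len(nrow(w3))) {
    idx <- (w3$start[k] + 1):(w3$end[k])
    comp <- x[idx] %in% c("A", "C", "G", "T") &
            y[idx] %in% c("A", "C", "G", "T")
    want <- if (sum(comp) > 0) 100 * sum(x[idx][comp] == y[idx][comp]) /
      sum(comp) else NA_real_
    expect_equal(w3$identity[k], want)
    expect_equal(w3$low_coverage[k], sum(comp) < 25)
  }
  # window longer than the alignment collapses to one window
  w4 <- percent_identity_windows("ACGTACGT", "ACGTACGT", window = 100,
                                 step = 25)
  expect_equal(nrow(w4), 1)
  expect_error(percent_identity_windows("AC", "AC", window = 1, step = 2))
})

test_that("conversion tract detection recovers a programmed tract", {
  p <- simulate_diverged_pair(150, 0.4, omega = 0.5, seed = 21)
  conv <- apply_conversion(p$a, p$b, 50, 90)   # 40-codon tract copied
  aln <- edit_alignment(paste(conv, collapse = ""),
                        paste(p$b, collapse = ""))
  scan <- detect_conversion_tracts(aln, min_len = 15, reps = 499, seed = 9)
  expect_identical(attr(scan, "status"), "ok")
  hit <- scan$start < 90 & scan$end > 50 & scan$significant
  expect_true(any(hit))
  # seeded determinism
  scan2 <- detect_conversion_tracts(aln, min_len = 15, reps = 499, seed = 9)
  expect_equal(scan$p_value, scan2$p_value)
  # invariant to swapping the sequences
  swap <- detect_conversion_tracts(
    edit_alignment(paste(p$b, collapse = ""), paste(conv, collapse = "")),
    min_len = 15, reps = 499, seed = 9)
  expect_equal(scan$start, swap$start)
  expect_equal(scan$p_value, swap$p_value)
  # add-one p-values live in (0, 1]
  expect_true(all(scan$p_value > 0 & scan$p_value <= 1))
})

test_that("identical or difference-free alignments are not assessable", {
  s <- paste(rep("CTTGGA", 40), collapse = "")
  scan <- detect_conversion_tracts(edit_alignment(s, s), reps = 199)
  expect_identical(attr(scan, "status"), "not_assessable")
  expect_equal(nrow(scan), 0)
  expect_warning(detect_conversion_tracts(edit_alignment(s, s), reps = 50),
                 "100 permutations")
})

test_that("exon restriction check follows the splice-extended limits", {
  # tract exactly spanning the exon (with splice dinucleotides)
  expect_true(check_exon_restriction(c(98, 421), c(100, 419),
                                     slack = 10)$restricted)
  # tract covering half the exon
  expect_false(check_exon_restriction(c(100, 260), c(100, 419),
                                      slack = 10)$restricted)
  # tract running 200 nt into the intron
  expect_false(check_exon_restriction(c(100, 619), c(100, 419),
                                      slack = 10)$restricted)
  # tract entirely outside the exon
  r <- check_exon_restriction(c(500, 600), c(100, 419), slack = 10)
  expect_false(r$restricted)
  expect_match(r$note, "outside")
  expect_error(check_exon_restriction(c(0, 10), c(0, 10), slack = -1))
})

test_that("region contrast flags enrichment and behaves at the extremes", {
  regions <- data.frame(name = "win", start = 50, end = 75)
  # omega_sel inside the window, omega_bg outside
  om <- rep(0.2, 150); om[51:75] <- 2
  p <- simulate_diverged_pair(150, 0.4, omega = om, seed = 5)
  aln <- edit_alignment(paste(p$a, collapse = ""), paste(p$b, collapse = ""))
  rc <- region_contrast(aln, regions, reps = 499, seed = 3)
  expect_gt(rc$ratio, 1)
  expect_lt(rc$p_value, 0.05)
  # all differences inside the region -> minimal p
  ca <- rep("CTT", 60); cb <- ca; cb[21:30] <- "ATT"
  aln2 <- edit_alignment(paste(ca, collapse = ""), paste(cb, collapse = ""))
  rc2 <- region_contrast(aln2, data.frame(name = "r", start = 20, end = 30),
                         reps = 199, seed = 1)
  expect_equal(rc2$nonsyn_out, 0)
  expect_equal(rc2$p_value, 1 / 200)
  # no nonsynonymous differences anywhere -> undefined ratio
  cb3 <- ca; cb3[5] <- "CTA"
  rc3 <- region_contrast(edit_alignment(paste(ca, collapse = ""),
                                        paste(cb3, collapse = "")),
                         data.frame(name = "r", start = 20, end = 30),
                         reps = 99, seed = 1)
  expect_true(is.na(rc3$ratio))
  expect_error(region_contrast(aln2, data.frame(name = "r", start = 0,
                                                end = 59)),
               ">= 3 codons")
})
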