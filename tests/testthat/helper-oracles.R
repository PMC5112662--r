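# Independent brute-force oracles for substitution counting, written
# directly against the standard genetic code without reusing any of the
# package's lookup-table machinery.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

oracle_sense_codons <- function() {
  cods <- apply(expand.grid(ORACLE_BASES, ORACLE_BASES, ORACLE_BASES,
                            stringsAsFactors = FALSE),
                1, paste, collapse = "")
  cods[oracle_translate(cods) != "*"]
}

# Enumerate all 9 single-base mutants of a codon; per position the
# synonymous fraction among non-stop mutants is the site contribution.
oracle_site_counts <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(ORACLE_BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      maa <- oracle_translate(mut)
      if (maa == "*") next
      valid <- valid + 1
      if (maa == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(S = s, N = 3 - s)
}

# all permutations of a small vector (n <= 3)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# Pathway enumeration for (Sd, Nd): average over stop-free orderings of
# the differing positions; if all orderings hit a stop, include them with
# stop steps counted as nonsynonymous.
oracle_diff_counts <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0))
  paths <- oracle_perms(pos)
  stats <- lapply(paths, function(order) {
    cur <- a; sd <- 0; nd <- 0; stopped <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      a1 <- oracle_translate(cur); a2 <- oracle_translate(nxt)
      if (a1 == "*" || a2 == "*") { stopped <- TRUE; nd <- nd + 1 }
      else if (a1 == a2) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, stopped = stopped)
  })
  ok <- !vapply(stats, `[[`, logical(1), "stopped")
  use <- if (any(ok)) stats[ok] else stats
  c(Sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# Full brute-force pairwise dN/dS from the oracles plus the closed-form
# Jukes-Cantor correction.
oracle_dnds <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, function(c) oracle_site_counts(c)[["S"]],
                   numeric(1))) +
        sum(vapply(codons_b, function(c) oracle_site_counts(c)[["S"]],
                   numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  d <- mapply(function(x, y) oracle_diff_counts(x, y), codons_a, codons_b)
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, dS = jc(Sd / S), dN = jc(Nd / N))
}

oracle_random_codons <- function(n) {
  sample(oracle_sense_codons(), n, replace = TRUE)
}

# A shrunk simulation scenario for fast end-to-end tests.
small_sim_config <- function(seed = 1L) {
  cfg <- xenopus_like_config(seed)
  cfg$subgroups$group1 <- list(n = 5, inhibitory = "g1_01",
                               activating = "g1_02")
  cfg$subgroups$group2 <- list(n = 4, inhibitory = "g2_01",
                               activating = "g2_02")
  cfg$extra_itim <- character(0)
  cfg$gpi <- "g2_04"
  cfg$s_retained <- c("g1_04", "g2_04")
  cfg$pseudogenes <- data.frame(base = "g1_03", species = "A",
                                tag = "none", mode = "stop")
  cfg
}
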