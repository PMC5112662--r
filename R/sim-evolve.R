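# Codon and neutral sequence evolution used by the cluster simulator.
#
# Coding sequences evolve by a proposal/acceptance single-nucleotide
# process: proposals are uniform over all 9L single-base changes (an
# optional transition weight kappa is exposed, default 1), synonymous
# changes are accepted at relative rate 1, nonsynonymous changes at the
# omega of their codon, and proposals creating (or leaving) stop codons
# are rejected. Branch lengths are expressed as expected synonymous
# substitutions per synonymous site; the proposal count is calibrated
# from the sequence's current synonymous-change fraction.

#' Generate a random in-frame codon sequence without stops
#'
#' @param n_codons Number of codons.
#' @return Character vector of sense codons.
#' @export
random_codon_sequence <- function(n_codons) {
  sense <- sense_codons()
  sample(sense, n_codons, replace = TRUE)
}

#' Evolve a codon sequence along a branch
#'
#' @param codons Character vector of sense codons.
#' @param branch_length Expected synonymous substitutions per synonymous
#'   site along the branch.
#' @param omega Per-codon dN/dS (scalar or vector of length
#'   \code{length(codons)}); nonsynonymous proposals at codon i are
#'   accepted with relative rate \code{omega[i]}.
#' @param kappa Transition/transversion proposal weight (default 1:
#'   uniform base-change kernel).
#' @return Evolved codon vector.
#' @export
evolve_codon_sequence <- function(codons, branch_length, omega = 1,
                                  kappa = 1) {
  if (branch_length < 0) stop("branch_length must be >= 0")
  if (branch_length == 0) return(codons)
  L <- length(codons)
  omega <- rep_len(omega, L)
  if (any(omega < 0)) stop("omega must be >= 0")
  tb <- .codon_tables()
  type <- tb$type
  M <- max(1, omega)
  # synonymous-change count of the starting sequence (calibration)
  n_syn <- sum(type[codons, , ] == 0L, na.rm = TRUE)
  if (n_syn == 0) stop("sequence admits no synonymous change")
  S_tot <- sum(tb$S[codons])
  exp_syn <- branch_length * S_tot
  p_syn_per_prop <- n_syn / (9 * L) / M
  n_prop <- stats::rpois(1, exp_syn / p_syn_per_prop)
  if (n_prop == 0) return(codons)
  # transition partner of each base
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  idx <- sample.int(L, n_prop, replace = TRUE)
  pos <- sample.int(3, n_prop, replace = TRUE)
  u_acc <- stats::runif(n_prop)
  u_base <- stats::runif(n_prop)
  for (k in seq_len(n_prop)) {
    i <- idx[k]
    cod <- codons[i]
    cur <- substr(cod, pos[k], pos[k])
    alt <- setdiff(.BASES, cur)
    if (kappa == 1) {
      b <- alt[ceiling(u_base[k] * 3)]
    } else {
      w <- ifelse(alt == ts[[cur]], kappa, 1)
      b <- alt[findInterval(u_base[k] * sum(w), cumsum(w)) + 1L]
    }
    tp <- type[cod, pos[k], b]
    if (is.na(tp) || tp == 2L) next
    acc <- if (tp == 0L) 1 / M else omega[i] / M
    if (u_acc[k] <= acc) {
      substr(cod, pos[k], pos[k]) <- b
      codons[i] <- cod
    }
  }
  codons
}

#' Evolve a neutral (non-coding) sequence
#'
#' Jukes-Cantor substitution with \code{subs_per_site} expected
#' substitution events per site: each site's final base is drawn from the
#' JC transition distribution, so multiple hits are modelled exactly.
#'
#' @param seq Nucleotide string.
#' @param subs_per_site Expected substitutions per site.
#' @return Evolved string.
#' @export
evolve_neutral <- function(seq, subs_per_site) {
  if (subs_per_site <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  p_diff <- 0.75 * (1 - exp(-4 * subs_per_site / 3))
  change <- stats::runif(length(x)) < p_diff
  if (any(change)) {
    x[change] <- vapply(x[change], function(b)
      sample(setdiff(.BASES, b), 1), character(1))
  }
  paste(x, collapse = "")
}

#' Copy a gene-conversion tract from donor to acceptor
#'
#' Replaces the acceptor's codons in \[start, end) (0-based half-open)
#' with the donor's, verbatim.
#'
#' @param acceptor,donor Codon vectors of equal length.
#' @param start,end Codon interval, 0-based half-open; \code{end <= length}.
#' @return Converted acceptor codon vector.
#' @export
apply_conversion <- function(acceptor, donor, start, end) {
  L <- length(acceptor)
  if (length(donor) != L) stop("donor and acceptor lengths differ")
  if (start < 0 || end > L || end < start)
    stop("tract [", start, ",", end, ") outside exon of ", L, " codons")
  if (end > start) acceptor[(start + 1L):end] <- donor[(start + 1L):end]
  acceptor
}

#' Simulate a diverged pair of coding sequences
#'
#' Draws a random ancestor of \code{n_codons} sense codons and evolves two
#' independent lineages for \code{branch_length / 2} each, so the total
#' expected synonymous divergence of the pair is \code{branch_length}
#' synonymous substitutions per synonymous site.
#'
#' @param n_codons Number of codons.
#' @param branch_length Total expected pairwise synonymous divergence.
#' @param omega Per-codon dN/dS (scalar or vector).
#' @param seed Optional integer seed (local RNG scope).
#' @return list with codon vectors \code{a}, \code{b} and the
#'   \code{ancestor}.
#' @export
simulate_diverged_pair <- function(n_codons, branch_length, omega = 1,
                                   seed = NULL) {
  run <- function() {
    anc <- random_codon_sequence(n_codons)
    list(a = evolve_codon_sequence(anc, branch_length / 2, omega),
         b = evolve_codon_sequence(anc, branch_length / 2, omega),
         ancestor = anc)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}
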