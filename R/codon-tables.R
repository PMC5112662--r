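# Internal lookup tables for codon-level substitution counting.
#
# All counting follows the Nei & Gojobori (1986) pathway-averaging
# convention under the standard genetic code: synonymous site fractions
# exclude changes to stop codons from the per-position denominator, and
# multi-step differences are averaged over all mutational pathways that do
# not pass through a stop codon.

.pkg_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

.all_codons <- function() {
  g <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

.codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.is_stop <- function(codon) {
  .codon_aa(codon) == "*"
}

sense_codons <- function() {
  cods <- .all_codons()
  cods[!.is_stop(cods)]
}

# Synonymous site count of one sense codon (NG86): at each position, the
# fraction of non-stop single-base changes that are synonymous.
.site_count_one <- function(codon) {
  aa <- .codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    alt <- setdiff(.BASES, substr(codon, pos, pos))
    muts <- vapply(alt, function(b) {
      m <- codon
      substr(m, pos, pos) <- b
      m
    }, character(1))
    aas <- .codon_aa(muts)
    valid <- aas != "*"
    if (any(valid)) s <- s + sum(aas[valid] == aa) / sum(valid)
  }
  s
}

# Pathway-averaged (Sd, Nd) for a pair of sense codons. Pathways through
# stop codons are excluded; if every pathway passes through a stop, fall
# back to including them with stop-creating or stop-leaving steps counted
# as nonsynonymous.
.diff_count_pair <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  orders <- switch(as.character(k),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                 function(o) pos[o]))
  walk <- function(order) {
    cur <- a
    sd <- 0; nd <- 0; hits_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      aa1 <- .codon_aa(cur); aa2 <- .codon_aa(nxt)
      if (aa1 == "*" || aa2 == "*") {
        hits_stop <- TRUE
        nd <- nd + 1          # fallback classification only
      } else if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, stop = hits_stop)
  }
  paths <- lapply(orders, walk)
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  use <- if (any(ok)) paths[ok] else paths
  c(Sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# Build (once) the fast lookup tables keyed by codon string.
.codon_tables <- function() {
  if (!is.null(.pkg_cache$tables)) return(.pkg_cache$tables)
  cods <- .all_codons()
  sense <- sense_codons()
  S <- setNames(rep(NA_real_, 64), cods)
  S[sense] <- vapply(sense, .site_count_one, numeric(1))
  n <- length(sense)
  Sd <- matrix(NA_real_, n, n, dimnames = list(sense, sense))
  Nd <- Sd
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- .diff_count_pair(sense[i], sense[j])
      Sd[i, j] <- Sd[j, i] <- d[["Sd"]]
      Nd[i, j] <- Nd[j, i] <- d[["Nd"]]
    }
  }
  # substitution-type table for the simulator: for codon index, position,
  # new base -> 0 syn, 1 nonsyn, 2 stop-or-from-stop
  type <- array(NA_integer_, dim = c(64, 3, 4),
                dimnames = list(cods, NULL, .BASES))
  for (c0 in cods) {
    for (pos in 1:3) {
      for (b in .BASES) {
        if (substr(c0, pos, pos) == b) next
        c1 <- c0
        substr(c1, pos, pos) <- b
        a0 <- .codon_aa(c0); a1 <- .codon_aa(c1)
        type[c0, pos, b] <-
          if (a0 == "*" || a1 == "*") 2L else if (a0 == a1) 0L else 1L
      }
    }
  }
  .pkg_cache$tables <- list(S = S, Sd = Sd, Nd = Nd, type = type,
                            sense = sense)
  .pkg_cache$tables
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts synonymous (S) and nonsynonymous (N) sites of a single sense
#' codon under the Nei-Gojobori convention: for each codon position the
#' synonymous fraction among the non-stop single-base changes is that
#' position's synonymous site contribution, and N = 3 - S.
#'
#' @param codon A length-3 uppercase A/C/G/T string encoding a sense codon.
#' @return A named numeric vector with elements \code{S} and \code{N}
#'   (always summing to 3).
#' @examples
#' count_sites("TTT")  # S = 1/3
#' count_sites("CTT")  # S = 1 (fourfold-degenerate third position)
#' @export
count_sites <- function(codon) {
  .check_codon(codon)
  tb <- .codon_tables()
  s <- tb$S[[codon]]
  c(S = s, N = 3 - s)
}

#' Pathway-averaged substitution differences between two codons
#'
#' Counts synonymous (Sd) and nonsynonymous (Nd) differences between two
#' sense codons, averaging over all mutational pathways (orders of the
#' differing positions) that do not pass through a stop codon. Sd + Nd
#' always equals the nucleotide Hamming distance of the pair.
#'
#' @param codon_a,codon_b Length-3 uppercase A/C/G/T sense codons.
#' @return A named numeric vector with elements \code{Sd} and \code{Nd}.
#' @examples
#' count_differences("GTT", "GTA")  # one synonymous step
#' count_differences("TTT", "GTA")  # averaged over two pathways
#' @export
count_differences <- function(codon_a, codon_b) {
  .check_codon(codon_a)
  .check_codon(codon_b)
  tb <- .codon_tables()
  c(Sd = tb$Sd[codon_a, codon_b], Nd = tb$Nd[codon_a, codon_b])
}

.check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    stop("codon must be a single uppercase A/C/G/T triplet, got: ",
         deparse(codon))
  if (.is_stop(codon))
    stop("stop codon not allowed here: ", codon)
  invisible(codon)
}

# Split a nucleotide string into its codon triplets.
.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3: ", n)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
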