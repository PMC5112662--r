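#' Sliding-window percent identity over a pairwise genomic alignment
#'
#' Percent-identity-plot style track: the alignment is tiled with windows
#' of \code{window} aligned columns every \code{step} columns, and identity
#' is computed as matches over comparable (both non-gap) columns. Windows
#' in which fewer than half the columns are comparable are flagged.
#'
#' @param seq_a,seq_b Aligned sequences (equal length, gaps allowed).
#' @param window,step Window size and step in alignment columns;
#'   \code{window >= step >= 1}. A window longer than the alignment yields
#'   one whole-alignment window.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open), \code{identity} (percent, NA if no comparable columns),
#'   \code{comparable}, \code{low_coverage} (logical flag).
#' @export
percent_identity_windows <- function(seq_a, seq_b, window = 100, step = 25) {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned sequences differ in length")
  if (step < 1 || window < step) stop("need window >= step >= 1")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  L <- length(a)
  if (window > L) window <- L
  comparable <- a %in% .BASES & b %in% .BASES
  match_ <- comparable & a == b
  starts <- seq(0L, max(0L, L - window), by = step)
  out <- lapply(starts, function(s) {
    idx <- (s + 1L):(s + window)
    nc <- sum(comparable[idx])
    data.frame(start = s, end = s + window,
               identity = if (nc > 0) 100 * sum(match_[idx]) / nc else NA_real_,
               comparable = nc,
               low_coverage = nc < window / 2)
  })
  do.call(rbind, out)
}

# Per-codon synonymous/nonsynonymous difference vectors of an alignment.
.per_codon_diffs <- function(aln) {
  tb <- .codon_tables()
  idx <- cbind(match(aln$codons_a, tb$sense), match(aln$codons_b, tb$sense))
  list(Sd = tb$Sd[idx], Nd = tb$Nd[idx],
       nt = mapply(function(x, y) {
         sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
       }, aln$codons_a, aln$codons_b, USE.NAMES = FALSE))
}

# Maximal runs of zeros in a numeric vector; returns matrix [start, end)
# 0-based half-open.
.zero_runs <- function(x) {
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

.longest_zero_run <- function(x) {
  r <- rle(x == 0)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Detect candidate gene-conversion tracts in a codon alignment
#'
#' Formalises the visual criterion of a flat synonymous-substitution curve:
#' a candidate tract is a maximal run of codons with zero synonymous
#' differences of at least \code{min_len} codons. Significance of each run
#' is the fraction of seeded codon-column permutations whose longest
#' zero-synonymous run is at least as long as the observed run (add-one
#' rule, so p is in (0, 1\]).
#'
#' @param aln A \code{codon_alignment} or 2-element character vector.
#' @param min_len Minimum tract length in codons (default 15).
#' @param reps Number of permutations (default 999; fewer than 100 warns).
#' @param seed Integer seed for the permutation null.
#' @param alpha Significance level used for the \code{significant} flag.
#' @return A \code{conversion_scan} object: data.frame of candidate tracts
#'   with columns \code{start}, \code{end} (codons, 0-based half-open),
#'   \code{length}, \code{nt_diffs}, \code{syn_diffs}, \code{nonsyn_diffs},
#'   \code{p_value}, \code{significant}; attribute \code{status} is one of
#'   "ok" or "not_assessable" (no synonymous differences in the whole
#'   alignment, in which case no tracts are reported).
#' @export
detect_conversion_tracts <- function(aln, min_len = 15, reps = 999,
                                     seed = 1L, alpha = 0.05) {
  aln <- .as_codon_alignment(aln)
  if (reps < 100) warning("fewer than 100 permutations; p-values are coarse")
  d <- .per_codon_diffs(aln)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), nt_diffs = numeric(0),
                      syn_diffs = numeric(0), nonsyn_diffs = numeric(0),
                      p_value = numeric(0), significant = logical(0))
  if (sum(d$Sd) == 0) {
    return(structure(empty, class = c("conversion_scan", "data.frame"),
                     status = "not_assessable", ids = aln$ids))
  }
  runs <- .zero_runs(d$Sd)
  keep <- runs[, "end"] - runs[, "start"] >= min_len
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) {
    return(structure(empty, class = c("conversion_scan", "data.frame"),
                     status = "ok", ids = aln$ids))
  }
  # permutation null: longest zero-synonymous run of shuffled codon columns
  null_max <- integer(reps)
  .with_seed(seed, {
    for (r in seq_len(reps))
      null_max[r] <- .longest_zero_run(sample(d$Sd))
  })
  tracts <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs[i, "start"]; e <- runs[i, "end"]
    len <- e - s
    idx <- (s + 1L):e
    p <- (sum(null_max >= len) + 1) / (reps + 1)
    data.frame(start = s, end = e, length = len,
               nt_diffs = sum(d$nt[idx]),
               syn_diffs = sum(d$Sd[idx]),
               nonsyn_diffs = sum(d$Nd[idx]),
               p_value = p, significant = p <= alpha)
  })
  structure(do.call(rbind, tracts),
            class = c("conversion_scan", "data.frame"),
            status = "ok", ids = aln$ids)
}

#' @export
print.conversion_scan <- function(x, ...) {
  cat("conversion tract scan: ", attr(x, "ids")[1], " vs ",
      attr(x, "ids")[2], "\n", sep = "")
  st <- attr(x, "status")
  if (st == "not_assessable") {
    cat("  not assessable: no synonymous differences in alignment\n")
  } else if (nrow(x) == 0) {
    cat("  no candidate tracts\n")
  } else {
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Check whether a conversion tract is restricted to an exon
#'
#' Tests the hallmark of exon-limited gene conversion: both tract limits
#' fall within \code{slack} nucleotides of the exon limits, where the exon
#' interval is extended by the 2-nt splice dinucleotides on each side.
#' Tract and exon must be on a common nucleotide coordinate system
#' (0-based half-open).
#'
#' @param tract_nt Numeric length-2 vector \code{c(start, end)} of the
#'   tract in nucleotides. Codon tracts from [detect_conversion_tracts()]
#'   convert as \code{3 * c(start, end)} plus the exon's coding offset.
#' @param exon_nt Numeric length-2 vector \code{c(start, end)} of the exon.
#' @param slack Allowed deviation in nt at each limit (default 10).
#' @return list with \code{restricted} (logical) and \code{note}.
#' @export
check_exon_restriction <- function(tract_nt, exon_nt, slack = 10) {
  if (slack < 0) stop("slack must be >= 0")
  ext <- c(exon_nt[1] - 2, exon_nt[2] + 2)   # splice dinucleotides
  if (tract_nt[2] <= exon_nt[1] || tract_nt[1] >= exon_nt[2]) {
    return(list(restricted = FALSE, note = "tract outside exon"))
  }
  ok <- abs(tract_nt[1] - ext[1]) <= slack &&
        abs(tract_nt[2] - ext[2]) <= slack
  list(restricted = ok,
       note = if (ok) "tract spans exon within slack" else
         "tract limits deviate from exon limits")
}

#' Nonsynonymous enrichment contrast between codon regions
#'
#' Compares the per-codon density of nonsynonymous differences inside a
#' named set of codon intervals (e.g. the CC'C''FG beta-strand face)
#' against the remainder of the alignment, with a one-sided permutation
#' test shuffling codon labels.
#'
#' @param aln A \code{codon_alignment} or 2-element character vector.
#' @param regions data.frame with columns \code{name}, \code{start},
#'   \code{end} (codon intervals, 0-based half-open, non-overlapping).
#' @param reps Number of permutations (default 999).
#' @param seed Integer seed.
#' @return list with \code{nonsyn_in}, \code{nonsyn_out},
#'   \code{codons_in}, \code{codons_out}, \code{rate_in}, \code{rate_out},
#'   \code{ratio} (NA if no nonsynonymous differences anywhere), and
#'   \code{p_value} (one-sided, enrichment inside).
#' @export
region_contrast <- function(aln, regions, reps = 999, seed = 1L) {
  aln <- .as_codon_alignment(aln)
  d <- .per_codon_diffs(aln)
  L <- length(d$Nd)
  inside <- rep(FALSE, L)
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 0 || e > L || e <= s) stop("region out of alignment bounds")
    inside[(s + 1L):e] <- TRUE
  }
  n_in <- sum(inside); n_out <- L - n_in
  if (n_in < 3 || n_out < 3)
    stop("need >= 3 codons inside and outside the region set")
  obs_in <- sum(d$Nd[inside])
  obs_out <- sum(d$Nd[!inside])
  if (obs_in + obs_out == 0) {
    return(list(nonsyn_in = 0, nonsyn_out = 0, codons_in = n_in,
                codons_out = n_out, rate_in = 0, rate_out = 0,
                ratio = NA_real_, p_value = NA_real_))
  }
  rate_in <- obs_in / n_in
  rate_out <- obs_out / n_out
  ratio <- if (rate_out == 0) Inf else rate_in / rate_out
  obs_stat <- rate_in
  hits <- 0L
  .with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- sample(d$Nd)
      if (sum(perm[inside]) / n_in >= obs_stat) hits <- hits + 1L
    }
  })
  list(nonsyn_in = obs_in, nonsyn_out = obs_out,
       codons_in = n_in, codons_out = n_out,
       rate_in = rate_in, rate_out = rate_out, ratio = ratio,
       p_value = (hits + 1) / (reps + 1))
}

# Evaluate expr with a local RNG state seeded by seed.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
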