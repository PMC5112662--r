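#' Jukes-Cantor correction of a proportion of differences
#'
#' Corrects an observed proportion of differences per site for multiple
#' hits: \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}. At or beyond the
#' saturation point \eqn{p \ge 3/4} the distance is undefined and
#' \code{NA} is returned (with attribute \code{saturated = TRUE}) rather
#' than an error, so batch pipelines can carry the flag.
#'
#' @param p Proportion of differences per site, in \[0, 1\].
#' @return Corrected distance, or \code{NA_real_} when saturated.
#' @export
jukes_cantor <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
    stop("p must be a single non-negative number")
  if (p >= 0.75) {
    out <- NA_real_
    attr(out, "saturated") <- TRUE
    return(out)
  }
  if (p == 0) return(0)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS by pathway-averaged counting
#'
#' Computes synonymous and nonsynonymous substitution rates for a pairwise
#' codon alignment: site totals S and N are averaged over the two
#' sequences, observed differences Sd and Nd are summed over codons with
#' pathway averaging, proportions ps = Sd/S and pn = Nd/N are
#' Jukes-Cantor-corrected into dS and dN, and the ratio dN/dS is reported.
#' The ratio is undefined (NA, flagged) when dS = 0 or either rate is
#' saturated.
#'
#' @param aln A \code{codon_alignment} (see [edit_alignment()]), or a
#'   2-element character vector of equal-length in-frame sequences.
#' @return A \code{dnds} object: list with fields \code{Sd}, \code{Nd},
#'   \code{S}, \code{N}, \code{ps}, \code{pn}, \code{dS}, \code{dN},
#'   \code{ratio}, \code{codons}, \code{flags} (character vector, possibly
#'   empty: "dS_zero", "dS_saturated", "dN_saturated"), and \code{ids}.
#' @seealso [cumulative_profile()] for the per-codon running sums.
#' @export
pairwise_dnds <- function(aln) {
  aln <- .as_codon_alignment(aln)
  tb <- .codon_tables()
  ca <- aln$codons_a
  cb <- aln$codons_b
  S <- (sum(tb$S[ca]) + sum(tb$S[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, tb$sense), match(cb, tb$sense))
  sd_i <- tb$Sd[idx]
  nd_i <- tb$Nd[idx]
  Sd <- sum(sd_i)
  Nd <- sum(nd_i)
  ps <- Sd / S
  pn <- Nd / N
  dS <- jukes_cantor(ps)
  dN <- jukes_cantor(pn)
  flags <- character(0)
  if (isTRUE(attr(dS, "saturated"))) flags <- c(flags, "dS_saturated")
  if (isTRUE(attr(dN, "saturated"))) flags <- c(flags, "dN_saturated")
  ratio <- NA_real_
  if (!is.na(dS) && !is.na(dN)) {
    if (dS == 0) flags <- c(flags, "dS_zero") else ratio <- dN / dS
  }
  structure(list(Sd = Sd, Nd = Nd, S = S, N = N, ps = ps, pn = pn,
                 dS = as.numeric(dS), dN = as.numeric(dN), ratio = ratio,
                 codons = length(ca), flags = flags, ids = aln$ids,
                 per_codon = list(Sd = sd_i, Nd = nd_i)),
            class = "dnds")
}

#' @export
print.dnds <- function(x, digits = 4, ...) {
  cat("pairwise dN/dS: ", x$ids[1], " vs ", x$ids[2],
      " (", x$codons, " codons)\n", sep = "")
  cat(sprintf("  Sd = %.*f  Nd = %.*f  S = %.*f  N = %.*f\n",
              digits, x$Sd, digits, x$Nd, digits, x$S, digits, x$N))
  cat(sprintf("  dS = %s  dN = %s  dN/dS = %s\n",
              .fmt_or_na(x$dS, digits), .fmt_or_na(x$dN, digits),
              if (is.na(x$ratio)) "undefined" else
                formatC(x$ratio, digits = digits, format = "f")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.fmt_or_na <- function(v, digits) {
  if (is.na(v)) "NA" else formatC(v, digits = digits, format = "f")
}

#' Cumulative substitution profile along a codon alignment
#'
#' Running per-codon sums of synonymous and nonsynonymous differences from
#' codon 1 to each codon, the curves used to visualise gene-conversion
#' tracts (flat synonymous segments) and diversification hotspots (steep
#' nonsynonymous segments).
#'
#' @param aln A \code{codon_alignment} or 2-element character vector.
#' @return A \code{codon_profile} object: data.frame with columns
#'   \code{codon_index}, \code{cum_Sd}, \code{cum_Nd}; attributes carry the
#'   matching [pairwise_dnds()] totals.
#' @export
cumulative_profile <- function(aln) {
  aln <- .as_codon_alignment(aln)
  res <- pairwise_dnds(aln)
  df <- data.frame(codon_index = seq_len(res$codons),
                   cum_Sd = cumsum(res$per_codon$Sd),
                   cum_Nd = cumsum(res$per_codon$Nd))
  structure(df, class = c("codon_profile", "data.frame"),
            dnds = res, ids = aln$ids)
}

#' @export
plot.codon_profile <- function(x, main = NULL, ...) {
  ids <- attr(x, "ids")
  if (is.null(main)) main <- paste(ids[1], "vs", ids[2])
  ylim <- c(0, max(x$cum_Sd, x$cum_Nd, 1))
  graphics::plot(x$codon_index, x$cum_Nd, type = "s", col = "darkgreen",
                 xlab = "codon", ylab = "cumulative substitutions",
                 ylim = ylim, main = main, ...)
  graphics::lines(x$codon_index, x$cum_Sd, type = "s", col = "red")
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = c("darkgreen", "red"),
                   legend = c("nonsynonymous", "synonymous"))
  invisible(x)
}

.as_codon_alignment <- function(aln) {
  if (inherits(aln, "codon_alignment")) return(aln)
  if (is.character(aln) && length(aln) == 2L)
    return(edit_alignment(aln[1], aln[2],
                          ids = names(aln) %||% c("seq_a", "seq_b")))
  stop("expected a codon_alignment or a 2-element character vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table of pairwise dN/dS results to TSV
#'
#' @param results A list of \code{dnds} objects.
#' @param path Output file path.
#' @return The data.frame written, invisibly. Numeric columns are reported
#'   at 4 decimals; undefined ratios appear as NA with a flag.
#' @export
write_dnds_tsv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(id_a = r$ids[1], id_b = r$ids[2], codons = r$codons,
               Sd = round(r$Sd, 4), Nd = round(r$Nd, 4),
               S = round(r$S, 4), N = round(r$N, 4),
               ps = round(r$ps, 4), pn = round(r$pn, 4),
               dS = round(r$dS, 4), dN = round(r$dN, 4),
               dNdS = round(r$ratio, 4),
               flags = paste(r$flags, collapse = ";"))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
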