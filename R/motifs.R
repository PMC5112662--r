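# Signaling-motif consensus patterns (configurable via scan_motifs args).
# ITIM  [ILVS]xYxx[ILV]   inhibitory
# ITSM  TxYxx[VI]         switch
# ITAM  Yxx[LI]x{6,12}Yxx[LI]  activating (two modules, canonical spacing)
# ITAM-like: two Yxx[ILV] modules with spacing 3-5 or 13-20, or a single
# Yxx[ILV] module when no ITIM matches the peptide.
.MOTIF_PATTERNS <- list(
  ITIM      = "[ILVS].Y..[ILV]",
  ITSM      = "T.Y..[VI]",
  ITAM      = "Y..[LI].{6,12}Y..[LI]",
  ITAM_like = "Y..[ILV](.{3,5}|.{13,20})Y..[ILV]",
  module    = "Y..[ILV]"
)

# All (possibly overlapping) matches of a regex; returns data.frame
# start (0-based), length.
.regex_overlapping <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=(", pattern, "))"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), length = integer(0)))
  lens <- attr(m, "capture.length")[, 1]
  data.frame(start = as.integer(m) - 1L, length = as.integer(lens))
}

#' Scan a cytoplasmic peptide for immunoreceptor signaling motifs
#'
#' Reports all matches of the ITIM, ITSM, ITAM and ITAM-like consensus
#' patterns in a cytoplasmic-tail peptide. Precedence per overlapping
#' site: ITAM beats ITAM-like beats ITIM/ITSM (an ITAM match suppresses
#' its constituent single modules); ITIM and ITSM are reported
#' independently where both consensi match. A lone Yxx[ILV] module is
#' reported as ITAM-like only when no ITIM matches the peptide.
#'
#' @param peptide Amino-acid sequence (standard one-letter codes).
#' @param patterns Named list of regex patterns overriding the defaults
#'   (names ITIM, ITSM, ITAM, ITAM_like, module).
#' @return data.frame with columns \code{kind} (ITIM, ITSM, ITAM,
#'   ITAM-like), \code{offset} (0-based), \code{match} (peptide matched).
#'   Empty for an empty sequence.
#' @examples
#' scan_motifs("AASVYAQLAA")        # one ITIM at offset 2
#' scan_motifs("YEGLAAAAAAAYSEI")   # one ITAM
#' @export
scan_motifs <- function(peptide, patterns = .MOTIF_PATTERNS) {
  out <- data.frame(kind = character(0), offset = integer(0),
                    match = character(0))
  if (is.na(peptide) || nchar(peptide) == 0) return(out)
  peptide <- toupper(peptide)
  covered <- function(hits) {
    iv <- logical(nchar(peptide))
    for (i in seq_len(nrow(hits)))
      iv[(hits$start[i] + 1L):(hits$start[i] + hits$length[i])] <- TRUE
    iv
  }
  overlaps <- function(hit_start, hit_len, mask) {
    any(mask[(hit_start + 1L):(hit_start + hit_len)])
  }
  add <- function(df, kind, hits) {
    if (nrow(hits) == 0) return(df)
    rbind(df, data.frame(
      kind = kind, offset = hits$start,
      match = substring(peptide, hits$start + 1L, hits$start + hits$length)))
  }

  itam <- .regex_overlapping(peptide, patterns$ITAM)
  itam_mask <- if (nrow(itam)) covered(itam) else logical(nchar(peptide))

  itaml <- .regex_overlapping(peptide, patterns$ITAM_like)
  if (nrow(itaml)) {
    keep <- !vapply(seq_len(nrow(itaml)), function(i)
      overlaps(itaml$start[i], itaml$length[i], itam_mask), logical(1))
    itaml <- itaml[keep, , drop = FALSE]
  }
  act_mask <- itam_mask
  if (nrow(itaml)) act_mask <- act_mask | covered(itaml)

  itim <- .regex_overlapping(peptide, patterns$ITIM)
  itsm <- .regex_overlapping(peptide, patterns$ITSM)
  drop_in_act <- function(hits) {
    if (nrow(hits) == 0) return(hits)
    keep <- !vapply(seq_len(nrow(hits)), function(i)
      overlaps(hits$start[i], hits$length[i], act_mask), logical(1))
    hits[keep, , drop = FALSE]
  }
  itim <- drop_in_act(itim)
  itsm <- drop_in_act(itsm)

  # lone Yxx[ILV] module counts as ITAM-like only in an ITIM-free tail
  if (nrow(itim) == 0 && nrow(itam) == 0 && nrow(itaml) == 0) {
    mods <- .regex_overlapping(peptide, patterns$module)
    itaml <- mods
  }

  out <- add(out, "ITAM", itam)
  out <- add(out, "ITAM-like", itaml)
  out <- add(out, "ITIM", itim)
  out <- add(out, "ITSM", itsm)
  out[order(out$offset, out$kind), , drop = FALSE]
}

#' Classify a gene's signaling character from its motif scan
#'
#' Inhibitory: ITIM present (with or without ITSM) and no activating
#' motif. Activating: ITAM or ITAM-like present and no ITIM. Both ITIM
#' and an activating motif: "ambiguous" (excluded from receptor pairing).
#' No motif: "none".
#'
#' @param motifs data.frame from [scan_motifs()].
#' @return One of "inhibitory", "activating", "ambiguous", "none".
#' @export
classify_signaling <- function(motifs) {
  kinds <- unique(motifs$kind)
  has_inh <- "ITIM" %in% kinds
  has_act <- any(c("ITAM", "ITAM-like") %in% kinds)
  if (has_inh && has_act) return("ambiguous")
  if (has_act) return("activating")
  if (has_inh) return("inhibitory")
  "none"
}
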