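# File-format helpers. FASTA goes through Biostrings; GFF3 is read and
# written as a plain 9-column table with the 1-based inclusive disk
# convention converted to 0-based half-open internally.

#' Read FASTA into a named character vector
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Read GFF3 into an internal-coordinate data.frame
#'
#' @param path GFF3 file (1-based inclusive on disk).
#' @return data.frame with columns seqid, source, type, start, end
#'   (0-based half-open), score, strand, phase, attributes. Malformed
#'   records raise an error naming the line.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0)
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), score = character(0),
                      strand = character(0), phase = character(0),
                      attributes = character(0)))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop("malformed GFF3 record at line ", body[bad[1]], " of ", path)
  m <- do.call(rbind, parts)
  df <- data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
                   start = as.integer(m[, 4]) - 1L,  # to 0-based half-open
                   end = as.integer(m[, 5]),
                   score = m[, 6], strand = m[, 7], phase = m[, 8],
                   attributes = m[, 9])
  if (any(is.na(df$start) | is.na(df$end)))
    stop("non-numeric coordinates in ", path)
  df
}

#' Write an internal-coordinate feature table as GFF3
#' @param df data.frame as returned by [read_gff3()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df)) {
    writeLines(paste(df$seqid, df$source, df$type,
                     df$start + 1L,  # back to 1-based inclusive
                     df$end, df$score, df$strand, df$phase, df$attributes,
                     sep = "\t"), con)
  }
  invisible(path)
}

# Extract one attribute value (key=value;...) from GFF3 attribute strings.
gff_attr <- function(attributes, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(attributes, regexec(pat, attributes))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Build gene models from a GFF3 feature table
#'
#' Expects gene features with \code{ID} attributes and exon features with
#' \code{Parent} plus an \code{exon_kind} attribute (leader, N, IgC, TM,
#' cytoplasmic, other). Optional gene attributes: \code{subgroup},
#' \code{homeolog}, \code{anchoring}.
#'
#' @param gff data.frame from [read_gff3()].
#' @return Named list of \code{gene_model} objects.
#' @export
gene_models_from_gff <- function(gff) {
  genes <- gff[gff$type == "gene", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  ids <- gff_attr(genes$attributes, "ID")
  out <- vector("list", length(ids))
  names(out) <- ids
  parent <- gff_attr(exons$attributes, "Parent")
  for (i in seq_along(ids)) {
    ex <- exons[parent == ids[i], , drop = FALSE]
    strand <- genes$strand[i]
    ord <- if (strand == "+") order(ex$start) else order(-ex$start)
    ex <- ex[ord, , drop = FALSE]
    ph <- suppressWarnings(as.integer(ex$phase))
    ph[is.na(ph)] <- 0L
    exdf <- data.frame(start = ex$start, end = ex$end,
                       kind = gff_attr(ex$attributes, "exon_kind"),
                       phase = ph)
    sg <- gff_attr(genes$attributes[i], "subgroup")
    hm <- gff_attr(genes$attributes[i], "homeolog")
    an <- gff_attr(genes$attributes[i], "anchoring")
    out[[i]] <- gene_model(ids[i], genes$seqid[i], strand, exdf,
                           subgroup = sg,
                           homeolog = if (is.na(hm)) "none" else hm,
                           anchoring = if (is.na(an)) "TM" else an)
  }
  out
}
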