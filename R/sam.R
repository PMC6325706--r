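# Internal SAM-text handling.
#
# SAM text is parsed directly (it is a TSV) so that malformed lines can be
# reported with their line number; CIGAR arithmetic is delegated to
# GenomicAlignments. BAM input is accepted by converting through
# Rsamtools::asSam when that package is installed.

# Read SAM input into header lines and an alignment data.frame.
# `sam` may be a file path or a character vector of SAM lines.
read_sam <- function(sam) {
  lines <- if (length(sam) == 1L && file.exists(sam)) {
    if (grepl("\\.bam$", sam, ignore.case = TRUE)) {
      if (!requireNamespace("Rsamtools", quietly = TRUE)) {
        stopf("reading BAM requires the Rsamtools package")
      }
      tmp <- tempfile(fileext = "")
      on.exit(unlink(paste0(tmp, ".sam")))
      readLines(paste0(Rsamtools::asSam(sam, tmp), ""))
    } else {
      readLines(sam)
    }
  } else {
    as.character(sam)
  }
  is_hdr <- startsWith(lines, "@")
  body <- lines[!is_hdr]
  lineno <- which(!is_hdr)
  body <- body[nzchar(body)]
  lineno <- lineno[nzchar(lines[!is_hdr])]
  if (length(body) == 0) {
    return(list(header = lines[is_hdr],
                aln = data.frame(qname = character(0), flag = integer(0),
                                 rname = character(0), pos = integer(0),
                                 mapq = integer(0), cigar = character(0),
                                 line = integer(0))))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stopf("malformed SAM line %d: %d fields (11 required)",
          lineno[bad], nf[bad])
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- suppressWarnings(as.integer(get(2)))
  pos <- suppressWarnings(as.integer(get(4)))
  mapq <- suppressWarnings(as.integer(get(5)))
  if (anyNA(flag) || anyNA(pos) || anyNA(mapq)) {
    bad <- which(is.na(flag) | is.na(pos) | is.na(mapq))[1]
    stopf("malformed SAM line %d: non-numeric FLAG/POS/MAPQ", lineno[bad])
  }
  list(header = lines[is_hdr],
       aln = data.frame(qname = get(1), flag = flag, rname = get(3),
                        pos = pos, mapq = mapq, cigar = get(6),
                        line = lineno, stringsAsFactors = FALSE))
}

# Contig lengths from @SQ header lines, as a named integer vector.
sam_seq_lengths <- function(header) {
  sq <- header[startsWith(header, "@SQ")]
  if (length(sq) == 0) return(setNames(integer(0), character(0)))
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  setNames(ln, sn)
}

is_unmapped <- function(aln) bitwAnd(aln$flag, 4L) != 0L | aln$rname == "*"
is_secondary <- function(aln) bitwAnd(aln$flag, 256L) != 0L
is_supplementary <- function(aln) bitwAnd(aln$flag, 2048L) != 0L
is_duplicate <- function(aln) bitwAnd(aln$flag, 1024L) != 0L

# Reference span [pos, pos + width - 1] of each mapped record; width from
# CIGAR operations that consume the reference (M/D/N/=/X).
cigar_ref_width <- function(cigar, lineno = NULL) {
  w <- tryCatch(
    GenomicAlignments::cigarWidthAlongReferenceSpace(cigar),
    error = function(e) {
      if (is.null(lineno)) stop(e)
      stopf("malformed CIGAR (SAM line(s) %s): %s",
            paste(head(lineno, 3), collapse = ","), conditionMessage(e))
    })
  w
}
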