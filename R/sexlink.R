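#' Read a per-site depth TSV (CHROM/POS/DEPTH)
#'
#' Reads the three-column per-site depth table emitted by standard depth
#' utilities (and by [simulate_depth_tracks()] + [write_depth_tsv()]).
#' Files may be sparse: when `lengths` is supplied, absent positions are
#' filled in with depth 0.
#'
#' @param path TSV path; columns CHROM, POS (1-based), DEPTH, header
#'   optional.
#' @param lengths Optional named vector of contig lengths for densifying
#'   sparse files.
#' @param sample_label Optional `"male"`/`"female"` label attached to the
#'   returned track.
#' @return A depth track `data.frame` (`contig`, `pos`, `depth`).
#' @export
read_depth_tsv <- function(path, lengths = NULL, sample_label = NA_character_) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    is.na(suppressWarnings(as.integer(strsplit(first, "\t")[[1]][2])))
  d <- read.table(path, sep = "\t", header = has_header,
                  col.names = c("contig", "pos", "depth"),
                  colClasses = c("character", "integer", "integer"))
  names(d) <- c("contig", "pos", "depth")
  if (!is.null(lengths)) {
    dense <- lapply(names(lengths), function(ctg) {
      out <- data.frame(contig = ctg, pos = seq_len(lengths[[ctg]]),
                        depth = 0L, stringsAsFactors = FALSE)
      sub <- d[d$contig == ctg, , drop = FALSE]
      out$depth[sub$pos] <- sub$depth
      out
    })
    d <- do.call(rbind, dense)
  }
  attr(d, "sample_label") <- sample_label
  d
}

#' Write a depth track as a dense CHROM/POS/DEPTH TSV
#' @param track Depth track `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  write.table(track[, c("contig", "pos", "depth")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-site depth of uniquely mapped reads from alignments
#'
#' Counts, at every reference site, the primary, non-duplicate alignments
#' with MAPQ at or above `min_mapq` whose aligned reference span covers the
#' site. The MAPQ >= 10 default follows the usual uniquely-mapped-read
#' convention of depth utilities. Deletions in the read (CIGAR `D`) count as
#' covered; reference skips (`N`) and clips do not.
#'
#' @param alignments SAM text: path or character vector of lines. Contig
#'   lengths are taken from the `@SQ` header.
#' @param min_mapq Minimum MAPQ (default 10).
#' @return A dense depth track `data.frame` (`contig`, `pos`, `depth`).
#' @export
depth_from_alignments <- function(alignments, min_mapq = 10L) {
  parsed <- read_sam(alignments)
  lens <- sam_seq_lengths(parsed$header)
  aln <- parsed$aln
  keep <- !is_secondary(aln) & !is_supplementary(aln) & !is_duplicate(aln) &
    !is_unmapped(aln) & aln$mapq >= min_mapq
  aln <- aln[keep, , drop = FALSE]
  if (length(lens) == 0) {
    # no @SQ header: infer per-contig extent from the alignments themselves
    if (nrow(aln) == 0) stopf("no @SQ header and no usable alignments")
    w <- cigar_ref_width(aln$cigar, aln$line)
    lens <- tapply(aln$pos + w - 1L, aln$rname, max)
    lens <- setNames(as.integer(lens), names(lens))
  }
  covered <- NULL
  if (nrow(aln) > 0) {
    rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      aln$cigar, pos = aln$pos, ops = c("M", "D", "=", "X"),
      reduce.ranges = TRUE)
    covered <- unlist(rl)
    covered_ctg <- rep(aln$rname, lengths(rl))
  }
  out <- lapply(names(lens), function(ctg) {
    L <- lens[[ctg]]
    depth <- integer(L)
    if (!is.null(covered)) {
      r <- covered[covered_ctg == ctg]
      if (length(r) > 0) {
        depth <- as.integer(IRanges::coverage(r, width = L))
      }
    }
    data.frame(contig = ctg, pos = seq_len(L), depth = depth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Female-to-male per-site depth ratio with eligibility mask
#'
#' A site is eligible when the combined number of qualifying reads across
#' the two samples is at least `min_site_reads` (default 2, i.e. sites with
#' one or fewer reads are excluded). At eligible sites the ratio is
#' female depth / male depth, with `+Inf` when the male depth is 0 and the
#' female depth is positive; a site with zero depth in both samples is
#' ineligible by the threshold.
#'
#' @param female,male Depth tracks over the same contig set.
#' @param min_site_reads Combined-read eligibility threshold (default 2).
#' @return A `data.frame` (`contig`, `pos`, `female`, `male`, `eligible`,
#'   `ratio`); `ratio` is `NA` at ineligible sites.
#' @export
compute_ratio_profile <- function(female, male, min_site_reads = 2L) {
  if (!setequal(unique(female$contig), unique(male$contig))) {
    stopf("female and male tracks cover different contigs")
  }
  if (identical(female$contig, male$contig) &&
      identical(female$pos, male$pos)) {
    f <- female$depth
    m <- male$depth
    prof <- data.frame(contig = female$contig, pos = female$pos,
                       stringsAsFactors = FALSE)
  } else {
    merged <- merge(female[, c("contig", "pos", "depth")],
                    male[, c("contig", "pos", "depth")],
                    by = c("contig", "pos"), all = TRUE,
                    suffixes = c("_f", "_m"))
    merged <- merged[order(merged$contig, merged$pos), , drop = FALSE]
    f <- ifelse(is.na(merged$depth_f), 0L, merged$depth_f)
    m <- ifelse(is.na(merged$depth_m), 0L, merged$depth_m)
    prof <- data.frame(contig = merged$contig, pos = merged$pos,
                       stringsAsFactors = FALSE)
  }
  eligible <- (f + m) >= min_site_reads
  ratio <- rep(NA_real_, length(f))
  ratio[eligible] <- ifelse(m[eligible] > 0, f[eligible] / m[eligible],
                            ifelse(f[eligible] > 0, Inf, NA_real_))
  prof$female <- f
  prof$male <- m
  prof$eligible <- eligible
  prof$ratio <- ratio
  prof
}

#' Tile contigs into fixed-size windows
#'
#' Non-overlapping 0-based half-open windows `[k*w, min((k+1)*w, L))`; the
#' final partial window is emitted, so window lengths always sum to the
#' contig length.
#'
#' @param contig_lengths Named vector of contig lengths.
#' @param window Window size in bp (default 10 kb).
#' @return A `data.frame` (`contig`, `start`, `end`, `unit_id`).
#' @export
tile_windows <- function(contig_lengths, window = 10000L) {
  if (window <= 0) stopf("window must be > 0")
  out <- lapply(names(contig_lengths), function(ctg) {
    L <- contig_lengths[[ctg]]
    starts <- seq(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    data.frame(contig = ctg, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$unit_id <- sprintf("%s:%d-%d", out$contig, out$start, out$end)
  out
}

# Median taking the lower of the two central values for even counts, so a
# unit with exactly half zero-ratios is still called Y (conservative toward
# the median-equals-zero rule). Infinities are legal values.
median_lower <- function(x) {
  k <- length(x)
  if (k == 0) return(NA_real_)
  sort(x, method = "quick")[ceiling(k / 2)]
}

#' Assign contig windows to Y, X, or autosomes from the ratio profile
#'
#' Per unit (window or whole contig), the median female-to-male ratio over
#' eligible sites decides the label: a median of exactly 0 means the unit is
#' male-specific (Y); a median at or above `x_threshold` (default 1.5, the
#' midpoint of the X:autosome expectations 2 and 1) means X; anything in
#' between is autosomal. Units with `min_eligible_bp` or fewer eligible
#' sites (default: more than 1 kb of mappable sites required) are AMBIGUOUS.
#'
#' @param profile A ratio profile from [compute_ratio_profile()].
#' @param units Intervals `data.frame` (`contig`, `start`, `end`, 0-based
#'   half-open; optional `unit_id`), e.g. from [tile_windows()].
#' @param min_eligible_bp Units need strictly more eligible sites than this
#'   (default 1000).
#' @param x_threshold Median ratio at or above which a unit is X.
#' @return A `data.frame` (`unit_id`, `contig`, `start`, `end`, `label`,
#'   `median_ratio`, `n_eligible`).
#' @export
assign_units <- function(profile, units, min_eligible_bp = 1000L,
                         x_threshold = 1.5) {
  if (!is.data.frame(units) || nrow(units) == 0) stopf("empty unit list")
  if (is.null(units$unit_id)) {
    units$unit_id <- sprintf("%s:%d-%d", units$contig, units$start, units$end)
  }
  elig <- profile[profile$eligible, c("contig", "pos", "ratio"), drop = FALSE]
  res <- lapply(unique(units$contig), function(ctg) {
    u <- units[units$contig == ctg, , drop = FALSE]
    pr <- elig[elig$contig == ctg, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pr$pos, width = 1L),
      IRanges::IRanges(start = u$start + 1L, end = u$end))
    ratios <- split(pr$ratio[S4Vectors::queryHits(hits)],
                    factor(S4Vectors::subjectHits(hits),
                           levels = seq_len(nrow(u))))
    med <- vapply(ratios, median_lower, numeric(1))
    n_el <- lengths(ratios)
    label <- ifelse(n_el <= min_eligible_bp, "AMBIGUOUS",
                    ifelse(med == 0, "Y",
                           ifelse(med >= x_threshold, "X", "AUTOSOME")))
    med[label == "AMBIGUOUS"] <- NA_real_
    data.frame(unit_id = u$unit_id, contig = u$contig, start = u$start,
               end = u$end, label = label, median_ratio = med,
               n_eligible = as.integer(n_el), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Chromosome quotient of a reference unit
#'
#' The chromosome quotient (CQ) is the female-to-male ratio of the total
#' number of alignments (here, summed per-site depth) over a reference
#' sequence; a CQ below `y_threshold` indicates Y-linkage. Provided as the
#' comparator for the median-ratio rule.
#'
#' @param female,male Depth tracks over the unit.
#' @param y_threshold CQ below which the unit is called Y (default 0.05).
#' @return A list with `cq` (`NA` when the male sum is 0) and `label`
#'   (`"Y"`, `"NOT_Y"`, or `"AMBIGUOUS"`).
#' @export
chromosome_quotient <- function(female, male, y_threshold = 0.05) {
  fs <- sum(as.numeric(female$depth))
  ms <- sum(as.numeric(male$depth))
  if (ms == 0) {
    return(list(cq = NA_real_, label = "AMBIGUOUS"))
  }
  cq <- fs / ms
  list(cq = cq, label = if (cq < y_threshold) "Y" else "NOT_Y")
}

#' Evaluate assignments against ground truth (Y as the positive class)
#'
#' Sensitivity is the fraction of truly Y-linked units labeled Y; the false
#' assignment rate is the fraction of Y-labeled units that are not truly
#' Y-linked; specificity is the fraction of non-Y units not labeled Y.
#' AMBIGUOUS units are excluded throughout.
#'
#' @param records Assignment `data.frame` from [assign_units()] (columns
#'   `unit_id`, `label`).
#' @param truth Named character vector mapping every non-AMBIGUOUS
#'   `unit_id` to its true class (`"Y"`, `"X"`, `"AUTOSOME"`).
#' @return A list with `confusion` (`tp`, `fn`, `fp`, `tn`), `sensitivity`,
#'   `specificity`, `false_assignment_rate` (proportions in `[0, 1]`).
#' @export
evaluate_assignments <- function(records, truth) {
  rec <- records[records$label != "AMBIGUOUS", , drop = FALSE]
  missing_ids <- setdiff(rec$unit_id, names(truth))
  if (length(missing_ids)) {
    stopf("unit(s) missing from truth: %s",
          paste(head(missing_ids, 3), collapse = ", "))
  }
  tr <- truth[rec$unit_id]
  called_y <- rec$label == "Y"
  truly_y <- tr == "Y"
  tp <- sum(called_y & truly_y)
  fn <- sum(!called_y & truly_y)
  fp <- sum(called_y & !truly_y)
  tn <- sum(!called_y & !truly_y)
  list(confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       false_assignment_rate = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
}
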