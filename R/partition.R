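#' Define a heterochromatin-enrichment partition rule
#'
#' The enrichment rule keeps every read that could carry heterochromatic
#' sequence: reads that are unmapped, or whose primary alignment falls
#' outside a declared euchromatic reference set (e.g. the major chromosome
#' arms and the mitochondrion). Optionally, euchromatic BED spans restrict
#' the exclusion *within* those references, so that reads hitting
#' pericentric heterochromatin of a major arm are still retained.
#'
#' @param euchromatic_refs Character vector of reference names whose
#'   (spanned) regions are euchromatic.
#' @param euchromatic_spans Optional `data.frame` with columns `contig`,
#'   `start`, `end` (0-based half-open, BED convention) restricting the
#'   euchromatic exclusion within `euchromatic_refs`. A read whose primary
#'   alignment has at least 1 bp outside the spans is retained.
#' @param min_mapq_for_confident Primary alignments with MAPQ below this are
#'   treated as unmapped (retained). Default 0: any primary mapping counts.
#' @return A list of class `"ylink_partition_rule"`.
#' @export
partition_rule <- function(euchromatic_refs, euchromatic_spans = NULL,
                           min_mapq_for_confident = 0L) {
  if (length(euchromatic_refs) == 0 || any(!nzchar(euchromatic_refs))) {
    stopf("euchromatic_refs must be non-empty names")
  }
  if (!is.null(euchromatic_spans)) {
    stopifnot(is.data.frame(euchromatic_spans),
              all(c("contig", "start", "end") %in% names(euchromatic_spans)))
    if (any(euchromatic_spans$end <= euchromatic_spans$start)) {
      stopf("euchromatic spans must have end > start (0-based half-open)")
    }
    off <- setdiff(unique(euchromatic_spans$contig), euchromatic_refs)
    if (length(off)) stopf("spans on undeclared references: %s",
                           paste(off, collapse = ", "))
  }
  structure(list(euchromatic_refs = unique(euchromatic_refs),
                 euchromatic_spans = euchromatic_spans,
                 min_mapq_for_confident = as.integer(min_mapq_for_confident)),
            class = "ylink_partition_rule")
}

#' Partition read alignments into retained and discarded sets
#'
#' Applies the heterochromatin-enrichment rule: a read is RETAINED iff its
#' primary alignment is unmapped, or maps to a reference outside the
#' euchromatic set, or (when euchromatic spans are provided) has at least
#' 1 bp of its aligned interval outside the euchromatic spans of its
#' reference. Secondary and supplementary records are ignored for the
#' decision.
#'
#' @param alignments SAM text: a file path (`.sam` or `.bam`) or a character
#'   vector of SAM lines.
#' @param rule A [partition_rule()].
#' @return A list of class `"ylink_partition"` with `retained_ids`,
#'   `discarded_ids`, `n_reads`, `retained_fraction`.
#' @examples
#' plan <- build_genome_plan(1, 0, 1, c(2000, 2000), seed = 3)
#' sim <- simulate_read_alignments(plan, euchromatic_names = "A_contig1",
#'                                 n_reads = 50, frac_unmapped = 0.2, seed = 3)
#' partition_alignments(sim$sam, partition_rule("A_contig1"))
#' @export
partition_alignments <- function(alignments, rule) {
  stopifnot(inherits(rule, "ylink_partition_rule"))
  parsed <- read_sam(alignments)
  aln <- parsed$aln
  aln <- aln[!is_secondary(aln) & !is_supplementary(aln), , drop = FALSE]
  if (nrow(aln) == 0) {
    return(structure(list(retained_ids = character(0),
                          discarded_ids = character(0), n_reads = 0L,
                          retained_fraction = NaN),
                     class = "ylink_partition"))
  }
  dup <- aln$qname[duplicated(aln$qname)]
  if (length(dup)) stopf("read %s has more than one primary record", dup[1])
  unmapped <- is_unmapped(aln) |
    (!is_unmapped(aln) & aln$mapq < rule$min_mapq_for_confident)
  outside_refs <- !unmapped & !(aln$rname %in% rule$euchromatic_refs)
  retained <- unmapped | outside_refs
  if (!is.null(rule$euchromatic_spans)) {
    # reads on a euchromatic reference escape discard if any aligned base
    # lies outside the euchromatic spans of that reference
    cand <- which(!retained)
    if (length(cand)) {
      w <- cigar_ref_width(aln$cigar[cand], aln$line[cand])
      rd <- IRanges::IRanges(start = aln$pos[cand],
                             width = w)
      sp <- rule$euchromatic_spans
      esc <- vapply(seq_along(cand), function(k) {
        ref <- aln$rname[cand[k]]
        s <- sp[sp$contig == ref, , drop = FALSE]
        if (nrow(s) == 0) return(TRUE)  # no euchromatic span on this ref
        covered <- IRanges::reduce(IRanges::IRanges(start = s$start + 1L,
                                                    end = s$end))
        inside <- IRanges::restrict(covered, start = IRanges::start(rd[k]),
                                    end = IRanges::end(rd[k]))
        sum(IRanges::width(inside)) < IRanges::width(rd[k])
      }, logical(1))
      retained[cand[esc]] <- TRUE
    }
  }
  structure(list(retained_ids = aln$qname[retained],
                 discarded_ids = aln$qname[!retained],
                 n_reads = nrow(aln),
                 retained_fraction = mean(retained)),
            class = "ylink_partition")
}

#' Summarize a partition result
#'
#' Reports the number of retained reads, the total retained sequence (bp),
#' and the fraction of all reads retained -- the quantities one would quote
#' for an enrichment step.
#'
#' @param result A `"ylink_partition"` from [partition_alignments()].
#' @param read_lengths Named vector of read lengths (bp), covering at least
#'   every retained read id.
#' @return One-row `data.frame` with `n_retained`, `retained_bp`,
#'   `retained_fraction`.
#' @export
summarize_partition <- function(result, read_lengths) {
  stopifnot(inherits(result, "ylink_partition"))
  missing_ids <- setdiff(result$retained_ids, names(read_lengths))
  if (length(missing_ids)) {
    stopf("no length for retained read(s): %s",
          paste(head(missing_ids, 3), collapse = ", "))
  }
  bp <- if (length(result$retained_ids))
    sum(as.numeric(read_lengths[result$retained_ids])) else 0
  data.frame(n_retained = length(result$retained_ids),
             retained_bp = bp,
             retained_fraction = if (result$n_reads > 0)
               length(result$retained_ids) / result$n_reads else 0)
}
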