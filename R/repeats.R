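# RepeatMasker/TRF parsing and repeat-landscape summaries.

#' Default Repbase class-string grouping
#'
#' Maps the leading component of a Repbase `class/family` string onto the
#' major repeat groups used for landscape summaries: LTR and LINE
#' retrotransposons, DNA transposons, satellites/tandem repeats (including
#' simple and low-complexity annotations), rRNA plus its intergenic spacers,
#' and Other. Editable: pass your own named vector to
#' [composition_by_group()].
#'
#' @return Named character vector mapping class prefixes to group names.
#' @export
default_class_map <- function() {
  c(LTR = "LTR", LINE = "LINE", DNA = "DNA",
    Satellite = "Satellite/Tandem", Simple_repeat = "Satellite/Tandem",
    Low_complexity = "Satellite/Tandem",
    rRNA = "rRNA+IGS", IGS = "rRNA+IGS")
}

#' Parse a RepeatMasker .out file
#'
#' Reads the standard `.out` dialect: three header lines followed by
#' whitespace-separated columns, with an optional trailing `*`
#' higher-scoring-overlap flag. The Repbase class string is split into
#' `class_group`/`family` at the first `/`.
#'
#' @param path Path to the `.out` file.
#' @return A `data.frame` with `contig`, `begin`, `end` (1-based inclusive),
#'   `score`, `divergence`, `family` (repeat name), `repeat_class` (full
#'   Repbase string), `class_group`.
#' @export
parse_repeatmasker <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(.empty_rm())
  first_field <- sub("^\\s*(\\S*).*$", "\\1", lines)
  is_data <- grepl("^[0-9]+$", first_field)
  # everything before the first data row is header (3 lines in the
  # standard dialect); blank lines are skipped anywhere
  body_idx <- which(is_data & nzchar(trimws(lines)))
  if (length(body_idx) == 0) return(.empty_rm())
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14L) {
      stopf("malformed RepeatMasker row at line %d: %d fields", i, length(f))
    }
    b <- suppressWarnings(as.integer(f[6]))
    e <- suppressWarnings(as.integer(f[7]))
    if (is.na(b) || is.na(e)) {
      stopf("malformed RepeatMasker row at line %d: non-numeric coordinates", i)
    }
    data.frame(contig = f[5], begin = b, end = e,
               score = as.numeric(f[1]), divergence = as.numeric(f[2]),
               family = f[10], repeat_class = f[11],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class_group <- sub("/.*$", "", out$repeat_class)
  out$family <- ifelse(grepl("/", out$repeat_class),
                       sub("^[^/]*/", "", out$repeat_class), out$family)
  out
}

.empty_rm <- function() {
  data.frame(contig = character(0), begin = integer(0), end = integer(0),
             score = numeric(0), divergence = numeric(0),
             family = character(0), repeat_class = character(0),
             class_group = character(0), stringsAsFactors = FALSE)
}

#' Parse a Tandem Repeats Finder -ngs .dat file
#'
#' Reads the `-ngs` dialect: sequence header lines starting with `@`, each
#' followed by space-separated array records whose contig is taken from the
#' preceding header.
#'
#' @param path Path to the `.dat` file.
#' @return A `data.frame` with `contig`, `begin`, `end` (1-based inclusive),
#'   `period`, `copy_number`, `consensus`.
#' @export
parse_trf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ctg <- NA_character_
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "@")) {
      ctg <- trimws(sub("^@", "", ln))
      next
    }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 14L) {
      stopf("TRF record at line %d has %d fields (>= 14 required)",
            i, length(f))
    }
    if (is.na(ctg)) stopf("TRF record at line %d precedes any @header", i)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = ctg, begin = as.integer(f[1]), end = as.integer(f[2]),
      period = as.integer(f[3]), copy_number = as.numeric(f[4]),
      consensus = f[14], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), begin = integer(0),
                      end = integer(0), period = integer(0),
                      copy_number = numeric(0), consensus = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Resolve overlapping annotations on one contig: records claim bases in
# priority order (higher RepeatMasker score first, ties by original order);
# returns per-record IRanges of newly claimed bases.
.claim_bases <- function(starts, ends, priority_order) {
  claimed <- IRanges::IRanges()
  claims <- vector("list", length(starts))
  for (k in priority_order) {
    r <- IRanges::IRanges(start = starts[k], end = ends[k])
    new <- IRanges::setdiff(r, claimed)
    claims[[k]] <- new
    claimed <- IRanges::reduce(c(claimed, new))
  }
  claims
}

#' Repeat-class composition per chromosome group
#'
#' Aggregates masked base pairs by chromosome group (Y / X / AUTOSOME /
#' UNKNOWN, from the contig assignments) and repeat class group. Overlaps
#' are resolved base-by-base with the higher RepeatMasker score winning
#' (ties to the earlier record); tandem arrays claim only bases not already
#' masked by an interspersed-repeat interval. Bases claimed by no annotation
#' are `Nonrepetitive`, so per group the class totals always sum exactly to
#' the group's assembled length.
#'
#' @param intervals RepeatMasker intervals from [parse_repeatmasker()].
#' @param arrays Tandem arrays from [parse_trf()] (may be empty).
#' @param assignments Named character vector: contig -> group label.
#' @param lengths Named vector of contig lengths (bp).
#' @param class_map Named vector mapping `class_group` strings to summary
#'   groups; unmapped classes fall into `"Other"`. Default
#'   [default_class_map()].
#' @return A list of class `"ylink_composition"`: `composition`
#'   (`data.frame` with `group`, `class_group`, `bp`, `fraction`) and
#'   `group_total_bp` (named vector).
#' @export
composition_by_group <- function(intervals, arrays, assignments, lengths,
                                 class_map = default_class_map()) {
  annotated <- unique(c(intervals$contig, arrays$contig))
  no_len <- setdiff(annotated, names(lengths))
  if (length(no_len)) stopf("annotated contig(s) without length: %s",
                            paste(no_len, collapse = ", "))
  group_of <- function(ctg) {
    g <- assignments[ctg]
    ifelse(is.na(g), "UNKNOWN", g)
  }
  groups <- vapply(names(lengths), group_of, character(1))
  group_total <- tapply(as.numeric(lengths), groups, sum)
  acc <- list()
  add_bp <- function(group, cls, bp) {
    key <- paste(group, cls, sep = "\r")
    acc[[key]] <<- (acc[[key]] %||% 0) + bp
  }
  for (ctg in names(lengths)) {
    grp <- groups[[ctg]]
    L <- lengths[[ctg]]
    iv <- intervals[intervals$contig == ctg, , drop = FALSE]
    claimed <- IRanges::IRanges()
    if (nrow(iv) > 0) {
      if (any(iv$begin < 1 | iv$end > L | iv$end < iv$begin)) {
        stopf("interval out of bounds on %s", ctg)
      }
      ord <- order(-iv$score, seq_len(nrow(iv)))
      claims <- .claim_bases(iv$begin, iv$end, ord)
      for (k in seq_len(nrow(iv))) {
        bp <- sum(IRanges::width(claims[[k]]))
        if (bp > 0) {
          cls <- class_map[iv$class_group[k]]
          add_bp(grp, if (is.na(cls)) "Other" else cls, bp)
        }
        claimed <- IRanges::reduce(c(claimed, claims[[k]]))
      }
    }
    ar <- arrays[arrays$contig == ctg, , drop = FALSE]
    if (nrow(ar) > 0) {
      tand <- IRanges::reduce(IRanges::IRanges(start = ar$begin,
                                               end = pmin(ar$end, L)))
      new <- IRanges::setdiff(tand, claimed)
      bp <- sum(IRanges::width(new))
      if (bp > 0) add_bp(grp, "Satellite/Tandem", bp)
      claimed <- IRanges::reduce(c(claimed, new))
    }
    add_bp(grp, "Nonrepetitive", L - sum(IRanges::width(claimed)))
  }
  keys <- strsplit(names(acc), "\r", fixed = TRUE)
  comp <- data.frame(group = vapply(keys, `[[`, character(1), 1),
                     class_group = vapply(keys, `[[`, character(1), 2),
                     bp = as.numeric(unlist(acc)), stringsAsFactors = FALSE)
  comp$fraction <- comp$bp / as.numeric(group_total[comp$group])
  comp <- comp[order(comp$group, comp$class_group), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(composition = comp,
                 group_total_bp = group_total),
            class = "ylink_composition")
}

#' Extrapolate assembled repeat composition to the whole chromosome
#'
#' Assumes the unassembled remainder of the chromosome consists of simple
#' tandem repeats (the standing assumption for repeat-dense Y chromosomes):
#' the whole-chromosome tandem fraction is
#' `(assumed_total - assembled + assembled_tandem_bp) / assumed_total`, and
#' every other class fraction is its assembled bp over `assumed_total`.
#' When `assembled_bp == assumed_total_bp` the map is the identity.
#'
#' @param class_bp Named numeric vector of assembled bp per class group
#'   (must contain `"Satellite/Tandem"`, possibly 0).
#' @param assembled_bp Total assembled bp of the chromosome group.
#' @param assumed_total_bp Assumed true chromosome size (>= `assembled_bp`).
#' @return Named vector of whole-chromosome fractions per class.
#' @examples
#' extrapolate_chromosome(c("Satellite/Tandem" = 742964),
#'                        assembled_bp = 14578684,
#'                        assumed_total_bp = 40e6)[["Satellite/Tandem"]]
#' @export
extrapolate_chromosome <- function(class_bp, assembled_bp, assumed_total_bp) {
  if (assumed_total_bp < assembled_bp) {
    stopf("assumed_total_bp must be >= assembled_bp")
  }
  tand <- if ("Satellite/Tandem" %in% names(class_bp)) {
    class_bp[["Satellite/Tandem"]]
  } else 0
  out <- class_bp / assumed_total_bp
  out[["Satellite/Tandem"]] <-
    (assumed_total_bp - assembled_bp + tand) / assumed_total_bp
  out
}

#' Per-class enrichment between two chromosome groups
#'
#' @param summary A `"ylink_composition"` from [composition_by_group()].
#' @param group_a,group_b Group labels (fold = fraction in `group_a` over
#'   fraction in `group_b`).
#' @param classes Class groups to compare.
#' @return A `data.frame` (`class_group`, `fraction_a`, `fraction_b`,
#'   `fold`); `fold` is `NA` where `fraction_b` is 0.
#' @export
enrichment <- function(summary, group_a, group_b, classes) {
  stopifnot(inherits(summary, "ylink_composition"))
  comp <- summary$composition
  get_frac <- function(grp, cls) {
    hit <- comp$fraction[comp$group == grp & comp$class_group == cls]
    if (length(hit) == 0) 0 else hit
  }
  known <- unique(comp$class_group)
  bad <- setdiff(classes, known)
  if (length(bad)) stopf("unknown class group(s): %s",
                         paste(bad, collapse = ", "))
  fa <- vapply(classes, get_frac, numeric(1), grp = group_a)
  fb <- vapply(classes, get_frac, numeric(1), grp = group_b)
  data.frame(class_group = classes, fraction_a = fa, fraction_b = fb,
             fold = ifelse(fb > 0, fa / fb, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided Fisher exact test for positional clustering
#'
#' Tests whether duplications concentrate in a chromosomal region (e.g. the
#' pericentromere) relative to the region's share of cytological bands.
#' The 2x2 table is `[[n_in, n_total - n_in], [bands_in,
#' bands_total - bands_in]]` and the two-sided p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param n_in,n_total Duplications inside the region, and in total.
#' @param bands_in,bands_total Cytological bands inside the region, and in
#'   total.
#' @return Two-sided exact p-value in `(0, 1]`.
#' @examples
#' clustering_fisher_test(12, 13, 11, 25)  # ~0.005
#' @export
clustering_fisher_test <- function(n_in, n_total, bands_in, bands_total) {
  if (n_in > n_total || bands_in > bands_total) {
    stopf("counts inside a region cannot exceed the totals")
  }
  a <- n_in
  b <- n_total - n_in
  c_ <- bands_in
  d <- bands_total - bands_in
  if (min(a, b, c_, d) < 0) stopf("negative cell in 2x2 table")
  # margins: m = first-column total, k = first-row total, N = grand total
  m <- a + c_
  n2 <- b + d
  k <- a + b
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n2, k)
  p_obs <- probs[support == a]
  # relative tolerance as in the classical implementation, to absorb
  # floating-point ties
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
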