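#' Build a genome plan of contigs with known chromosomal truth
#'
#' A genome plan is the ground-truth scaffold for every synthetic fixture:
#' a set of named contigs, each with a length, a true chromosomal class
#' (autosome, X, or Y), and a mappable fraction. Downstream simulators draw
#' depth, reads, and repeat annotations against this plan so that assignment
#' methods can be validated against a known answer, mirroring validation
#' against assembly regions of known location.
#'
#' Each contig also receives a private `mask_seed` so that the positions of
#' unmappable sites are a property of the contig, not of the sample being
#' simulated: male and female depth tracks over the same plan share the same
#' mask, as they would for a real mappability track.
#'
#' @param n_auto,n_x,n_y Number of autosomal, X-linked, and Y-linked contigs.
#' @param length_range Length-2 integer vector; contig lengths are drawn
#'   uniformly from this range (bp).
#' @param seed Integer seed; identical seeds give byte-identical plans.
#' @param mappable_range Range from which each contig's mappable fraction is
#'   drawn (default 0.5--1.0).
#' @return A `data.frame` with columns `name`, `length`, `truth_class`
#'   (one of `"AUTOSOME"`, `"X"`, `"Y"`), `mappable_fraction`, `mask_seed`.
#' @examples
#' build_genome_plan(2, 1, 1, c(5000, 10000), seed = 1)
#' @export
build_genome_plan <- function(n_auto, n_x, n_y, length_range = c(5000, 10000),
                              seed, mappable_range = c(0.5, 1.0)) {
  counts <- c(n_auto, n_x, n_y)
  if (any(counts < 0)) stopf("contig counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stopf("at least one contig must be requested")
  if (length(length_range) != 2L || any(length_range < 1)) {
    stopf("length_range must be two lengths >= 1")
  }
  classes <- rep(c("AUTOSOME", "X", "Y"), times = counts)
  prefix <- rep(c("A", "X", "Y"), times = counts)
  idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  len_vals <- seq(length_range[1], length_range[2])
  with_seed(seed, {
    lens <- len_vals[sample.int(length(len_vals), n, replace = TRUE)]
    mf <- runif(n, mappable_range[1], mappable_range[2])
    mask_seed <- sample.int(.Machine$integer.max - 1L, n)
    data.frame(
      name = paste0(prefix, "_contig", idx),
      length = as.integer(lens),
      truth_class = classes,
      mappable_fraction = mf,
      mask_seed = mask_seed,
      stringsAsFactors = FALSE
    )
  })
}

#' Depth-model parameters for the depth simulator
#'
#' @param haploid_depth Expected reads per site per haploid genome copy
#'   (lambda > 0).
#' @param noise `"poisson"` or `"negative_binomial"`; the latter adds
#'   overdispersion `Var = mu + dispersion * mu^2`.
#' @param dispersion Dispersion parameter (> 0), required for
#'   `"negative_binomial"`.
#' @param seed Integer seed for depth sampling.
#' @return A list of class `"ylink_depth_model"`.
#' @export
depth_model <- function(haploid_depth, noise = c("poisson", "negative_binomial"),
                        dispersion = NULL, seed = 1L) {
  noise <- match.arg(noise)
  if (haploid_depth <= 0) stopf("haploid_depth must be > 0")
  if (noise == "negative_binomial" &&
      (is.null(dispersion) || dispersion <= 0)) {
    stopf("negative_binomial noise requires dispersion > 0")
  }
  structure(list(haploid_depth = haploid_depth, noise = noise,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "ylink_depth_model")
}

# Haploid copy number of each chromosome class carried by each sex: a male
# is A/A X Y, a female A/A X/X. Y-linked sequence therefore has half the
# autosomal depth in males and zero depth in females.
.copy_number <- function(sex, truth_class) {
  tab <- list(
    male   = c(AUTOSOME = 2, X = 1, Y = 1),
    female = c(AUTOSOME = 2, X = 2, Y = 0)
  )
  tab[[sex]][truth_class]
}

#' Simulate a per-site depth track for one sex over a genome plan
#'
#' Expected depth at a mappable site is `haploid_depth * copies(sex, class)`:
#' autosomes carry two copies in both sexes, the X one copy in males and two
#' in females, and the Y one copy in males and none in females -- so Y-linked
#' sequence sits at 50% of autosomal depth in a male library and at zero in a
#' female library. Unmappable sites get depth 0 in both sexes (shared mask,
#' drawn from the plan's `mask_seed`).
#'
#' @param plan A genome plan from [build_genome_plan()].
#' @param sex `"male"` or `"female"`.
#' @param model A [depth_model()].
#' @return A depth track: `data.frame` with columns `contig`, `pos` (1-based),
#'   `depth`, and attribute `sample_label`.
#' @export
simulate_depth_tracks <- function(plan, sex, model) {
  if (!is.data.frame(plan) || nrow(plan) == 0) stopf("plan must be non-empty")
  if (!sex %in% c("male", "female")) stopf("unknown sex label: %s", sex)
  stopifnot(inherits(model, "ylink_depth_model"))
  per_contig <- lapply(seq_len(nrow(plan)), function(i) {
    L <- plan$length[i]
    mappable <- with_seed(plan$mask_seed[i], runif(L) < plan$mappable_fraction[i])
    mu <- model$haploid_depth * .copy_number(sex, plan$truth_class[i])
    dseed <- (model$seed %% 500000000L) * 4L +
      2L * (sex == "female") + i %% 2L
    depth <- with_seed(dseed, {
      if (mu == 0) {
        integer(L)
      } else if (model$noise == "poisson") {
        rpois(L, mu)
      } else {
        rnbinom(L, mu = mu, size = 1 / model$dispersion)
      }
    })
    depth[!mappable] <- 0L
    data.frame(contig = plan$name[i], pos = seq_len(L),
               depth = as.integer(depth), stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, per_contig)
  attr(track, "sample_label") <- sex
  track
}

#' Simulate a minimal SAM file of reads over a genome plan
#'
#' Emits a valid minimal SAM text (with `@HD`/`@SQ` header) in which each
#' read is either unmapped or primary-mapped to a plan contig with a MAPQ,
#' together with a sidecar truth table recording whether the
#' heterochromatin-enrichment rule should retain each read (unmapped, or
#' mapped outside the euchromatic reference set).
#'
#' @param plan A genome plan from [build_genome_plan()].
#' @param euchromatic_names Character vector of plan contig names declared
#'   euchromatic (reads mapping there should be discarded by the partition).
#' @param n_reads Number of reads (> 0).
#' @param frac_unmapped Fraction of reads flagged unmapped, in `[0, 1]`.
#' @param seed Integer seed.
#' @param read_length Read length in bp (default 100).
#' @param out_sam,out_truth Optional paths; when given, the SAM text and the
#'   truth TSV are written there.
#' @return Invisibly, a list with `sam` (character vector of SAM lines) and
#'   `truth` (`data.frame` with `read_id`, `retained`, `length`).
#' @export
simulate_read_alignments <- function(plan, euchromatic_names, n_reads,
                                     frac_unmapped, seed, read_length = 100L,
                                     out_sam = NULL, out_truth = NULL) {
  if (n_reads <= 0) stopf("n_reads must be > 0")
  if (frac_unmapped < 0 || frac_unmapped > 1) {
    stopf("frac_unmapped must be in [0, 1]")
  }
  unknown <- setdiff(euchromatic_names, plan$name)
  if (length(unknown)) stopf("euchromatic names not in plan: %s",
                             paste(unknown, collapse = ", "))
  res <- with_seed(seed, {
    unmapped <- runif(n_reads) < frac_unmapped
    contig_i <- sample.int(nrow(plan), n_reads, replace = TRUE,
                           prob = plan$length)
    rl <- pmin(read_length, plan$length[contig_i])
    pos <- floor(runif(n_reads) * (plan$length[contig_i] - rl + 1)) + 1L
    mapq <- sample(20:60, n_reads, replace = TRUE)
    list(unmapped = unmapped, contig = plan$name[contig_i], pos = pos,
         mapq = mapq, rl = rl)
  })
  qname <- sprintf("read%06d", seq_len(n_reads))
  flag <- ifelse(res$unmapped, 4L, 0L)
  rname <- ifelse(res$unmapped, "*", res$contig)
  pos <- ifelse(res$unmapped, 0L, res$pos)
  mapq <- ifelse(res$unmapped, 0L, res$mapq)
  cigar <- ifelse(res$unmapped, "*", paste0(res$rl, "M"))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", plan$name, plan$length))
  body <- paste(qname, flag, rname, pos, mapq, cigar,
                "*", 0L, 0L, "*", "*", sep = "\t")
  retained <- res$unmapped | !(res$contig %in% euchromatic_names)
  truth <- data.frame(read_id = qname, retained = retained,
                      length = as.integer(res$rl), stringsAsFactors = FALSE)
  sam <- c(header, body)
  if (!is.null(out_sam)) writeLines(sam, out_sam)
  if (!is.null(out_truth)) {
    write.table(truth, out_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(sam = sam, truth = truth))
}

#' Parameters for the gene-family forward simulator
#'
#' `conversion_rate` is the per-site, per-generation probability that a site
#' is covered by a gene-conversion tract (the field's "events per site, per
#' generation" unit); tract initiations therefore occur at rate
#' `conversion_rate / tract_mean` per site.
#'
#' @param n_copies Number of gene copies (>= 2).
#' @param L Locus length in bp.
#' @param mu Mutation rate per site per generation.
#' @param conversion_rate Conversion rate per site per generation (`c`).
#' @param tract_mean Mean conversion tract length in bp (geometric tracts;
#'   default 500 bp, within the empirically reported range for Drosophila).
#' @param generations Number of generations to evolve.
#' @param seed Integer seed.
#' @return A list of class `"ylink_family_params"`.
#' @export
family_sim_params <- function(n_copies, L, mu, conversion_rate,
                              tract_mean = 500, generations, seed = 1L) {
  if (n_copies < 2) stopf("n_copies must be >= 2")
  if (L < 1) stopf("L must be >= 1")
  if (mu < 0 || conversion_rate < 0) stopf("rates must be >= 0")
  if (tract_mean < 1) stopf("tract_mean must be >= 1")
  if (generations < 0) stopf("generations must be >= 0")
  structure(list(n_copies = as.integer(n_copies), L = as.integer(L), mu = mu,
                 conversion_rate = conversion_rate, tract_mean = tract_mean,
                 generations = as.integer(generations), seed = as.integer(seed)),
            class = "ylink_family_params")
}

#' Forward-simulate a multicopy gene family under mutation and gene conversion
#'
#' All copies start identical to a single uniform-random ancestor and evolve
#' for `generations` generations. Mutations hit uniform sites at rate `mu`
#' per site per generation, replacing the current base with one of the three
#' alternatives uniformly. Conversion tracts initiate at rate
#' `conversion_rate / tract_mean` per site per copy, pick a uniform donor
#' among the other copies, have geometric lengths with mean `tract_mean`, and
#' overwrite the recipient segment with the donor's current sequence --
#' the homogenizing force of concerted evolution. The full event history is
#' drawn as a marked Poisson process over the simulated interval and applied
#' in time order, which is distributionally equivalent to a per-generation
#' loop and much faster.
#'
#' @param params A [family_sim_params()] object.
#' @return A list of class `"ylink_family_sim"` with elements `sequences`
#'   (a named [Biostrings::DNAStringSet] of the evolved copies), `ancestor`,
#'   and `events` (`data.frame` of every conversion: `generation`, `donor`,
#'   `recipient`, `start`, `end`).
#' @export
simulate_gene_family <- function(params) {
  stopifnot(inherits(params, "ylink_family_params"))
  p <- params
  with_seed(p$seed, {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, p$L, replace = TRUE)
    seqs <- matrix(rep(anc, each = p$n_copies), nrow = p$n_copies)
    TT <- p$generations
    n_mut <- rpois(1, p$n_copies * p$mu * p$L * TT)
    n_conv <- rpois(1, p$n_copies * (p$conversion_rate / p$tract_mean) *
                      p$L * TT)
    ev <- data.frame(
      time = c(runif(n_mut, 0, TT), runif(n_conv, 0, TT)),
      type = rep(c("M", "C"), c(n_mut, n_conv)),
      copy = c(sample.int(p$n_copies, n_mut, replace = TRUE),
               sample.int(p$n_copies, n_conv, replace = TRUE)),
      site = c(sample.int(p$L, n_mut, replace = TRUE),
               sample.int(p$L, n_conv, replace = TRUE)),
      alt = c(sample.int(3L, n_mut, replace = TRUE),
              rep(NA_integer_, n_conv)),
      len = c(rep(NA_integer_, n_mut),
              rgeom(n_conv, prob = 1 / p$tract_mean) + 1L),
      donor = c(rep(NA_integer_, n_mut),
                if (n_conv > 0) {
                  vapply(sample.int(p$n_copies, n_conv, replace = TRUE),
                         function(x) x, integer(1))
                } else integer(0))
    )
    # donor must differ from recipient: resample collisions by shifting
    coll <- which(ev$type == "C" & ev$donor == ev$copy)
    if (length(coll)) {
      shift <- sample.int(p$n_copies - 1L, length(coll), replace = TRUE)
      ev$donor[coll] <- ((ev$copy[coll] - 1L + shift) %% p$n_copies) + 1L
    }
    ev <- ev[order(ev$time), , drop = FALSE]
    n_ev <- nrow(ev)
    ev_type <- ev$type
    ev_copy <- ev$copy
    ev_site <- ev$site
    ev_alt <- ev$alt
    ev_len <- ev$len
    ev_donor <- ev$donor
    ev_time <- ev$time
    log_gen <- integer(n_conv)
    log_donor <- integer(n_conv)
    log_recip <- integer(n_conv)
    log_start <- integer(n_conv)
    log_end <- integer(n_conv)
    k <- 0L
    for (i in seq_len(n_ev)) {
      if (ev_type[i] == "M") {
        cur <- seqs[ev_copy[i], ev_site[i]]
        alts <- bases[bases != cur]
        seqs[ev_copy[i], ev_site[i]] <- alts[ev_alt[i]]
      } else {
        s <- ev_site[i]
        e <- min(p$L, s + ev_len[i] - 1L)
        seqs[ev_copy[i], s:e] <- seqs[ev_donor[i], s:e]
        k <- k + 1L
        log_gen[k] <- ceiling(ev_time[i])
        log_donor[k] <- ev_donor[i]
        log_recip[k] <- ev_copy[i]
        log_start[k] <- s
        log_end[k] <- e
      }
    }
    events <- data.frame(generation = log_gen[seq_len(k)],
                         donor = log_donor[seq_len(k)],
                         recipient = log_recip[seq_len(k)],
                         start = log_start[seq_len(k)],
                         end = log_end[seq_len(k)])
    seq_chr <- apply(seqs, 1, paste, collapse = "")
    names(seq_chr) <- sprintf("copy%03d", seq_len(p$n_copies))
    structure(list(
      sequences = Biostrings::DNAStringSet(seq_chr),
      ancestor = paste(anc, collapse = ""),
      events = events,
      params = p
    ), class = "ylink_family_sim")
  })
}

#' Write a toy RepeatMasker .out annotation file
#'
#' Writes the standard three-header-line, whitespace-column `.out` dialect
#' that [parse_repeatmasker()] reads back losslessly. Intended for building
#' small, fully known repeat-annotation fixtures.
#'
#' @param intervals `data.frame` with columns `contig`, `begin`, `end`
#'   (1-based inclusive), `repeat_class` (Repbase-style `class/family`
#'   string), and optionally `family` (repeat name), `score`, `divergence`.
#' @param path Output file path.
#' @param lengths Optional named vector of contig lengths; when provided,
#'   intervals exceeding a contig's bounds are an error.
#' @return `path`, invisibly.
#' @export
make_repeatmasker_fixture <- function(intervals, path, lengths = NULL) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) > 0) {
    if (any(intervals$begin < 1) || any(intervals$end < intervals$begin)) {
      stopf("intervals must satisfy 1 <= begin <= end")
    }
    if (!is.null(lengths)) {
      lim <- lengths[intervals$contig]
      if (any(is.na(lim)) || any(intervals$end > lim)) {
        stopf("interval exceeds contig bounds")
      }
    }
  }
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence    begin    end          (left)   repeat         class/family      begin   end    (left)    ID",
    "")
  rows <- character(0)
  if (nrow(intervals) > 0) {
    score <- intervals$score %||% NULL
    if (is.null(intervals$score)) score <- rep(1000, nrow(intervals))
    div <- intervals$divergence %||% NULL
    if (is.null(intervals$divergence)) div <- rep(5.0, nrow(intervals))
    fam <- intervals$family
    if (is.null(fam)) fam <- sub("^.*/", "", intervals$repeat_class)
    rleft <- if (is.null(lengths)) rep(0L, nrow(intervals)) else
      as.integer(lengths[intervals$contig] - intervals$end)
    rows <- sprintf(
      "%5d %6.1f %4.1f %4.1f  %-10s %8d %8d %9s +  %-14s %-17s %6d %6d %8s %5d",
      as.integer(score), div, 0, 0, intervals$contig,
      as.integer(intervals$begin), as.integer(intervals$end),
      sprintf("(%d)", rleft), fam, intervals$repeat_class,
      1L, as.integer(intervals$end - intervals$begin + 1L), "(0)",
      seq_len(nrow(intervals)))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a toy Tandem Repeats Finder -ngs .dat file
#'
#' Writes the `-ngs` dialect (an `@contig` header line per sequence followed
#' by space-separated array records) that [parse_trf()] reads back.
#'
#' @param arrays `data.frame` with columns `contig`, `begin`, `end` (1-based
#'   inclusive), `period`, `copy_number`, `consensus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
make_trf_fixture <- function(arrays, path) {
  stopifnot(is.data.frame(arrays))
  out <- character(0)
  for (ctg in unique(arrays$contig)) {
    out <- c(out, paste0("@", ctg))
    sub <- arrays[arrays$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      span <- sub$end[i] - sub$begin[i] + 1L
      seq_field <- substr(strrep(sub$consensus[i],
                                 ceiling(span / nchar(sub$consensus[i]))),
                          1L, span)
      out <- c(out, paste(sub$begin[i], sub$end[i], sub$period[i],
                          format(sub$copy_number[i], nsmall = 1),
                          nchar(sub$consensus[i]), 95, 0,
                          2 * span, 25, 25, 25, 25, 1.9,
                          sub$consensus[i], seq_field))
    }
  }
  writeLines(out, path)
  invisible(path)
}
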