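#' Build a validated run configuration
#'
#' Collects the stage parameters of the synthetic end-to-end demo into one
#' serializable object. Unknown keys are rejected so a typo cannot silently
#' fall back to a default.
#'
#' @param seed Non-negative integer master seed; every stage's randomness is
#'   derived from it.
#' @param output_dir Output directory for artifacts and the manifest.
#' @param n_auto,n_x,n_y Contig counts for the genome plan.
#' @param length_range Contig length range (bp).
#' @param haploid_depth Expected depth per haploid copy.
#' @param window Assignment window size (bp).
#' @param min_eligible_bp Eligible-site threshold for assignment windows.
#' @param n_reads,frac_unmapped Read-simulation parameters.
#' @param family Gene-family simulation parameters, as a
#'   [family_sim_params()] list or `NULL` for defaults.
#' @param log_level `"info"` or `"quiet"`.
#' @param ... Unknown keys: always an error.
#' @return A list of class `"ylink_run_config"`.
#' @export
run_config <- function(seed = 42L, output_dir = tempfile("ylink_run_"),
                       n_auto = 4L, n_x = 2L, n_y = 2L,
                       length_range = c(20000L, 40000L),
                       haploid_depth = 15, window = 10000L,
                       min_eligible_bp = 1000L,
                       n_reads = 2000L, frac_unmapped = 0.1,
                       family = NULL, log_level = c("info", "quiet"), ...) {
  extra <- list(...)
  if (length(extra)) {
    stopf("unknown configuration key(s): %s",
          paste(names(extra), collapse = ", "))
  }
  log_level <- match.arg(log_level)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0) {
    stopf("seed must be a single non-negative integer")
  }
  if (is.null(family)) {
    family <- family_sim_params(n_copies = 20L, L = 1000L, mu = 1e-7,
                                conversion_rate = 5e-5, tract_mean = 500,
                                generations = 50000L,
                                seed = as.integer(seed) + 7L)
  }
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 n_auto = n_auto, n_x = n_x, n_y = n_y,
                 length_range = length_range, haploid_depth = haploid_depth,
                 window = window, min_eligible_bp = min_eligible_bp,
                 n_reads = n_reads, frac_unmapped = frac_unmapped,
                 family = family, log_level = log_level),
            class = "ylink_run_config")
}

.log <- function(config, ...) {
  if (config$log_level != "quiet") message(sprintf(...))
}

#' Run the full synthetic pipeline end to end
#'
#' Executes simulate -> partition -> assign -> evaluate -> gene-family
#' statistics -> repeat summary on synthetic fixtures, writing every
#' artifact under `config$output_dir` plus a `manifest.json` listing each
#' file with its MD5 checksum. Rerunning with the same configuration
#' reproduces identical checksums for all deterministic stages.
#'
#' @param config A [run_config()].
#' @return The manifest as a list (also written to
#'   `output_dir/manifest.json`), with per-stage summary results under
#'   `$results`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "ylink_run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$output_dir, f)
  artifacts <- character(0)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  stage("simulate", {
    .log(config, "simulating genome plan and depth tracks")
    plan <- build_genome_plan(config$n_auto, config$n_x, config$n_y,
                              config$length_range, seed = config$seed)
    model <- depth_model(config$haploid_depth, seed = config$seed + 1L)
    male <- simulate_depth_tracks(plan, "male", model)
    female <- simulate_depth_tracks(plan, "female", model)
    write.table(plan, path("plan.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_depth_tsv(male, path("male.depth.tsv"))
    write_depth_tsv(female, path("female.depth.tsv"))
    euchrom <- plan$name[plan$truth_class != "Y"]
    sim <- simulate_read_alignments(plan, euchrom, config$n_reads,
                                    config$frac_unmapped,
                                    seed = config$seed + 2L,
                                    out_sam = path("reads.sam"),
                                    out_truth = path("reads.truth.tsv"))
    fam <- simulate_gene_family(config$family)
    Biostrings::writeXStringSet(fam$sequences, path("family.fasta"))
    write.table(fam$events, path("family.events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "plan.tsv", "male.depth.tsv",
                    "female.depth.tsv", "reads.sam", "reads.truth.tsv",
                    "family.fasta", "family.events.tsv")
    results$plan <- plan
    results$sim_truth <- sim$truth
    results$family <- fam
  })

  plan <- results$plan

  stage("partition", {
    .log(config, "partitioning reads")
    rule <- partition_rule(plan$name[plan$truth_class != "Y"])
    part <- partition_alignments(path("reads.sam"), rule)
    truth <- results$sim_truth
    summ <- summarize_partition(part, setNames(truth$length, truth$read_id))
    writeLines(part$retained_ids, path("retained.ids"))
    write.table(summ, path("partition.summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "retained.ids", "partition.summary.tsv")
    results$partition <- list(result = part, summary = summ)
  })

  stage("assign", {
    .log(config, "assigning windows from depth ratios")
    male <- read_depth_tsv(path("male.depth.tsv"),
                           lengths = setNames(plan$length, plan$name))
    female <- read_depth_tsv(path("female.depth.tsv"),
                             lengths = setNames(plan$length, plan$name))
    prof <- compute_ratio_profile(female, male)
    windows <- tile_windows(setNames(plan$length, plan$name),
                            window = config$window)
    rec <- assign_units(prof, windows,
                        min_eligible_bp = config$min_eligible_bp)
    write.table(rec, path("assignments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth <- setNames(plan$truth_class[match(windows$contig, plan$name)],
                      windows$unit_id)
    ev <- evaluate_assignments(rec, truth)
    jsonlite::write_json(
      list(confusion = as.list(ev$confusion), sensitivity = ev$sensitivity,
           specificity = ev$specificity,
           false_assignment_rate = ev$false_assignment_rate),
      path("evaluation.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "assignments.tsv", "evaluation.json")
    results$assignment <- list(records = rec, evaluation = ev)
  })

  stage("geneconv", {
    .log(config, "gene-family recombination statistics")
    fam <- results$family
    copies <- filter_fragments(fam$sequences, min_len = 1L)
    sm <- extract_biallelic_sites(copies)
    rm_res <- rmin(sm)
    rho <- hudson_rho(sm)
    cg_r <- cg_from_rho(rho$rho_locus, length(copies), config$family$L)
    cg_s <- cg_from_similarity(copies, mu = config$family$mu)
    fam_json <- list(n_copies = length(copies), S = length(sm$sites),
                     Rmin = rm_res$rmin, rho_locus = rho$rho_locus,
                     theta = rho$theta_locus, c_g_rho = cg_r$c_g,
                     c_g_similarity = cg_s$c_g, d_bar = cg_s$d_bar)
    jsonlite::write_json(fam_json, path("family.stats.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "family.stats.json")
    results$geneconv <- fam_json
  })

  stage("repeats", {
    .log(config, "repeat landscape summary")
    y_ctg <- plan$name[plan$truth_class == "Y"][1]
    a_ctg <- plan$name[plan$truth_class == "AUTOSOME"][1]
    iv <- data.frame(
      contig = c(y_ctg, y_ctg, a_ctg),
      begin = c(101L, 2001L, 501L),
      end = c(1100L, 2600L, 1000L),
      repeat_class = c("LTR/Gypsy", "LINE/I", "DNA/P"),
      stringsAsFactors = FALSE)
    make_repeatmasker_fixture(iv, path("repeats.out"),
                              lengths = setNames(plan$length, plan$name))
    ar <- data.frame(contig = y_ctg, begin = 3001L, end = 3500L,
                     period = 5L, copy_number = 100,
                     consensus = "AAGAG", stringsAsFactors = FALSE)
    make_trf_fixture(ar, path("repeats.dat"))
    comp <- composition_by_group(
      parse_repeatmasker(path("repeats.out")), parse_trf(path("repeats.dat")),
      assignments = setNames(plan$truth_class, plan$name),
      lengths = setNames(plan$length, plan$name))
    write.table(comp$composition, path("composition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "repeats.out", "repeats.dat",
                    "composition.tsv")
    results$composition <- comp
  })

  files <- file.path(config$output_dir, artifacts)
  manifest <- list(
    seed = config$seed,
    artifacts = lapply(seq_along(artifacts), function(i) {
      list(file = artifacts[i],
           md5 = unname(tools::md5sum(files[i])),
           bytes = file.size(files[i]))
    }))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$results <- results
  invisible(manifest)
}

#' Validate input files by format sniffing
#'
#' Light-weight validation of pipeline inputs: per file, detects the format
#' (FASTA / SAM / BED / depth TSV / RepeatMasker .out / TRF .dat), counts
#' records, and reports the first error location. Unreadable or malformed
#' files produce an error entry, never an exception.
#'
#' @param paths Character vector of file paths.
#' @param kinds Optional declared kinds (same length as `paths`), each one
#'   of `"fasta"`, `"sam"`, `"bed"`, `"depth"`, `"rm_out"`, `"trf_dat"`;
#'   `NA` to sniff.
#' @return A `data.frame` (`path`, `kind`, `status`, `n_records`,
#'   `message`).
#' @export
validate_inputs <- function(paths, kinds = NULL) {
  if (is.null(kinds)) kinds <- rep(NA_character_, length(paths))
  stopifnot(length(kinds) == length(paths))
  one <- function(path, kind) {
    entry <- function(status, n = NA_integer_, msg = "") {
      data.frame(path = path, kind = kind %||% NA_character_, status = status,
                 n_records = n, message = msg, stringsAsFactors = FALSE)
    }
    if (!file.exists(path)) return(entry("error", msg = "file not found"))
    lines <- tryCatch(readLines(path, warn = FALSE),
                      error = function(e) NULL)
    if (is.null(lines)) return(entry("error", msg = "unreadable"))
    if (length(lines) == 0 || all(!nzchar(lines))) {
      return(entry("warning", 0L, "empty file"))
    }
    if (is.na(kind)) {
      kind <- if (startsWith(lines[1], ">")) "fasta"
      else if (startsWith(lines[1], "@HD") || startsWith(lines[1], "@SQ")) "sam"
      else if (grepl("^@", lines[1])) "trf_dat"
      else if (grepl("^\\s*SW\\s", lines[1])) "rm_out"
      else {
        f1 <- strsplit(lines[1], "\t")[[1]]
        if (length(f1) == 3 &&
            !is.na(suppressWarnings(as.integer(f1[2]))) &&
            !is.na(suppressWarnings(as.integer(f1[3])))) {
          if (as.integer(f1[3]) > as.integer(f1[2])) "bed" else "depth"
        } else if (length(f1) == 3) "depth" else "bed"
      }
    }
    res <- switch(kind,
      fasta = {
        n <- sum(startsWith(lines, ">"))
        if (n == 0) entry("error", msg = "no FASTA headers") else
          entry("ok", n)
      },
      sam = tryCatch({
        p <- read_sam(lines)
        entry("ok", nrow(p$aln))
      }, error = function(e) entry("error", msg = conditionMessage(e))),
      bed = {
        body <- which(!startsWith(lines, "#") & nzchar(lines))
        bad <- NA_integer_
        for (i in body) {
          f <- strsplit(lines[i], "\t")[[1]]
          s <- suppressWarnings(as.integer(f[2]))
          e <- suppressWarnings(as.integer(f[3]))
          if (length(f) < 3 || is.na(s) || is.na(e) || e < s) {
            bad <- i
            break
          }
        }
        if (!is.na(bad)) {
          entry("error", msg = sprintf("invalid BED record at line %d", bad))
        } else entry("ok", length(body))
      },
      depth = tryCatch({
        d <- read_depth_tsv(path)
        entry("ok", nrow(d))
      }, error = function(e) entry("error", msg = conditionMessage(e))),
      rm_out = tryCatch({
        entry("ok", nrow(parse_repeatmasker(path)))
      }, error = function(e) entry("error", msg = conditionMessage(e))),
      trf_dat = tryCatch({
        entry("ok", nrow(parse_trf(path)))
      }, error = function(e) entry("error", msg = conditionMessage(e))),
      entry("error", msg = sprintf("unknown kind '%s'", kind)))
    res$kind <- kind
    res
  }
  out <- do.call(rbind, lapply(seq_along(paths),
                               function(i) one(paths[i], kinds[i])))
  rownames(out) <- NULL
  out
}
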