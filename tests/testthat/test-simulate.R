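test_that("genome plans honor class counts, bounds, and seed determinism", {
  plan <- build_genome_plan(2, 1, 1, c(5000, 10000), seed = 1)
  expect_equal(plan$truth_class, c("AUTOSOME", "AUTOSOME", "X", "Y"))
  expect_true(all(plan$length >= 5000 & plan$length <= 10000))
  expect_true(all(plan$mappable_fraction >= 0.5 & plan$mappable_fraction <= 1))
  expect_false(anyDuplicated(plan$name) > 0)

  expect_identical(plan, build_genome_plan(2, 1, 1, c(5000, 10000), seed = 1))
  expect_false(identical(plan,
                         build_genome_plan(2, 1, 1, c(5000, 10000), seed = 2)))

  one_y <- build_genome_plan(0, 0, 1, c(1000, 1000), seed = 7)
  expect_equal(nrow(one_y), 1L)
  expect_equal(one_y$truth_class, "Y")
  expect_equal(one_y$length, 1000L)

  expect_error(build_genome_plan(0, 0, 0, c(1000, 1000), seed = 1),
               "at least one contig")
})

test_that("depth scales with sex-specific copy number and the mask is shared", {
  plan <- build_genome_plan(1, 1, 1, c(20000, 20000), seed = 5)
  model <- depth_model(15, seed = 11)
  male <- simulate_depth_tracks(plan, "male", model)
  female <- simulate_depth_tracks(plan, "female", model)

  y_name <- plan$name[plan$truth_class == "Y"]
  expect_true(all(female$depth[female$contig == y_name] == 0L))

  # autosome, male: mean depth ~ 2 lambda (Poisson, CLT bound)
  a_name <- plan$name[plan$truth_class == "AUTOSOME"]
  a_depth <- male$depth[male$contig == a_name]
  # at lambda = 15 a mappable site is never 0 in practice, so conditioning
  # on depth > 0 recovers the mappable sites
  n_map <- sum(a_depth > 0)
  mu <- 30
  expect_lt(abs(mean(a_depth[a_depth > 0]) - mu), 3 * sqrt(mu / n_map))

  # X: male/female mean ratio ~ 0.5
  x_name <- plan$name[plan$truth_class == "X"]
  r <- mean(male$depth[male$contig == x_name]) /
    mean(female$depth[female$contig == x_name])
  expect_lt(abs(r - 0.5), 0.05)

  # the unmappable mask is a property of the contig, not the sample: at
  # lambda = 15 a mappable autosomal site is essentially never 0, so the
  # zero sets of the two sexes coincide exactly on autosomes
  expect_identical(which(male$depth[male$contig == a_name] == 0L),
                   which(female$depth[female$contig == a_name] == 0L))

  expect_error(simulate_depth_tracks(plan, "unknown", model), "sex")
})

test_that("read simulator emits reproducible SAM with a truthful sidecar", {
  plan <- build_genome_plan(1, 0, 1, c(3000, 3000), seed = 2)
  eu <- plan$name[plan$truth_class == "AUTOSOME"]

  all_un <- simulate_read_alignments(plan, eu, 20, frac_unmapped = 1, seed = 3)
  flags <- as.integer(vapply(strsplit(grep("^[^@]", all_un$sam, value = TRUE),
                                      "\t"), `[[`, character(1), 2))
  expect_true(all(bitwAnd(flags, 4L) == 4L))
  expect_true(all(all_un$truth$retained))

  a <- simulate_read_alignments(plan, eu, 100, 0.1, seed = 9)
  b <- simulate_read_alignments(plan, eu, 100, 0.1, seed = 9)
  expect_identical(a$sam, b$sam)

  # all reads mapped to euchromatic contigs -> nothing retained
  only_a <- plan[plan$truth_class == "AUTOSOME", , drop = FALSE]
  m <- simulate_read_alignments(only_a, only_a$name, 50, 0, seed = 4)
  expect_equal(sum(m$truth$retained), 0L)

  expect_error(simulate_read_alignments(plan, eu, 0, 0.5, seed = 1),
               "n_reads")
})

test_that("gene-family simulator obeys the divergence clock and homogenizes", {
  # c = 0, mu = 0: nothing happens
  p0 <- family_sim_params(4, 200, 0, 0, generations = 1000, seed = 1)
  fam0 <- simulate_gene_family(p0)
  expect_equal(nrow(fam0$events), 0L)
  expect_true(all(as.character(fam0$sequences) == fam0$ancestor))

  # neutral clock: mean pairwise divergence ~ 2 mu t within 3 SE over reps
  mu <- 1e-7
  TT <- 50000
  divs <- vapply(1:6, function(s) {
    fam <- simulate_gene_family(
      family_sim_params(8, 1000, mu, 0, generations = TT, seed = 100 + s))
    mean_pairwise_divergence(fam$sequences)
  }, numeric(1))
  se <- sd(divs) / sqrt(length(divs))
  expect_lt(abs(mean(divs) - 2 * mu * TT), 3 * se + 1e-4)

  # conversion homogenizes: strictly smaller divergence in every matched pair
  pairs <- vapply(1:10, function(s) {
    d0 <- mean_pairwise_divergence(simulate_gene_family(
      family_sim_params(8, 1000, mu, 0, generations = TT,
                        seed = 200 + s))$sequences)
    dc <- mean_pairwise_divergence(simulate_gene_family(
      family_sim_params(8, 1000, mu, 1e-3, generations = TT,
                        seed = 200 + s))$sequences)
    dc < d0
  }, logical(1))
  expect_true(all(pairs))

  # conversion event count follows its Poisson law within 4 sqrt
  pc <- family_sim_params(10, 1000, 0, 5e-4, tract_mean = 100,
                          generations = 20000, seed = 31)
  fam <- simulate_gene_family(pc)
  expected <- 10 * (5e-4 / 100) * 1000 * 20000
  expect_lt(abs(nrow(fam$events) - expected), 4 * sqrt(expected))
  expect_true(all(fam$events$donor != fam$events$recipient))

  # constant length, determinism
  expect_true(all(Biostrings::width(fam$sequences) == 1000L))
  expect_identical(as.character(simulate_gene_family(pc)$sequences),
                   as.character(fam$sequences))
})

test_that("RepeatMasker and TRF fixtures round-trip through the parsers", {
  rm_path <- withr::local_tempfile(fileext = ".out")
  iv <- data.frame(contig = "Y_c1", begin = 201L, end = 800L,
                   repeat_class = "LTR/Gypsy", stringsAsFactors = FALSE)
  make_repeatmasker_fixture(iv, rm_path, lengths = c(Y_c1 = 1000L))
  got <- parse_repeatmasker(rm_path)
  expect_equal(nrow(got), 1L)
  expect_equal(got$end - got$begin + 1L, 600L)
  expect_equal(got$class_group, "LTR")
  expect_equal(got$family, "Gypsy")

  make_repeatmasker_fixture(iv[0, , drop = FALSE], rm_path)
  expect_equal(nrow(parse_repeatmasker(rm_path)), 0L)

  iv2 <- data.frame(contig = c("c1", "c2"), begin = c(1L, 51L),
                    end = c(100L, 150L),
                    repeat_class = c("LINE/I", "DNA/P"),
                    stringsAsFactors = FALSE)
  make_repeatmasker_fixture(iv2, rm_path)
  got2 <- parse_repeatmasker(rm_path)
  expect_equal(got2$class_group, c("LINE", "DNA"))
  expect_equal(got2$contig, c("c1", "c2"))

  expect_error(
    make_repeatmasker_fixture(iv, rm_path, lengths = c(Y_c1 = 500L)),
    "bounds")

  trf_path <- withr::local_tempfile(fileext = ".dat")
  ar <- data.frame(contig = "Y_c1", begin = 11L, end = 110L, period = 5L,
                   copy_number = 20, consensus = "AAGAG",
                   stringsAsFactors = FALSE)
  make_trf_fixture(ar, trf_path)
  got3 <- parse_trf(trf_path)
  expect_equal(got3$period, 5L)
  expect_equal(got3$consensus, "AAGAG")
  expect_equal(got3$contig, "Y_c1")

  writeLines("@lonely", trf_path)
  expect_equal(nrow(parse_trf(trf_path)), 0L)
})
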