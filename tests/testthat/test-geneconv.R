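aln <- function(...) {
  x <- c(...)
  names(x) <- sprintf("s%02d", seq_along(x))
  x
}

test_that("fragment filtering uses non-gap length with an inclusive bound", {
  copies <- aln(strrep("A", 300),
                paste0(strrep("-", 21), strrep("C", 279)),  # 279 bp
                paste0(strrep("-", 20), strrep("G", 280)))  # 280 bp
  kept <- filter_fragments(copies, 280)
  expect_setequal(names(kept), c("s01", "s03"))
  expect_equal(attr(kept, "n_dropped"), 1L)
  expect_error(filter_fragments(aln("A---A"), 280), "remain")
})

test_that("biallelic site extraction codes alleles and drops singletons", {
  invariant <- aln("ACGT", "ACGT", "ACGT")
  expect_length(extract_biallelic_sites(invariant)$sites, 0)

  two <- aln("AT", "AT", "GT", "GT")
  sm <- extract_biallelic_sites(two)
  expect_equal(sm$sites, 1L)
  # tie in counts: lexicographically smaller base (A) is the 0 allele
  expect_equal(unname(sm$alleles[, 1]), c(0L, 0L, 1L, 1L))

  singleton <- aln("AT", "AT", "GT")
  expect_length(extract_biallelic_sites(singleton)$sites, 0)
  expect_equal(length(extract_biallelic_sites(singleton,
                                              min_minor = 1)$sites), 1L)

  # gaps and N are missing; a site needs two bases among observed entries
  gappy <- aln("A-", "AN", "GA", "GA")
  smg <- extract_biallelic_sites(gappy)
  expect_equal(smg$sites, 1L)
  expect_equal(sum(is.na(smg$alleles)), 0)
})

test_that("rmin detects four-gamete violations and matches the brute force", {
  single <- random_site_matrix(5, 1)
  expect_equal(rmin(single)$rmin, 0L)

  four <- structure(list(
    sites = 1:2,
    alleles = rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)),
    L = 2L, n_copies = 4L), class = "ylink_site_matrix")
  expect_equal(rmin(four)$rmin, 1L)

  set.seed(404)
  for (i in 1:60) {
    sm <- random_site_matrix(sample(4:10, 1), sample(2:12, 1))
    expect_equal(rmin(sm)$rmin, oracle_rmin(sm$alleles),
                 info = sprintf("random instance %d", i))
  }
})

test_that("rmin is invariant to copy renaming and 0/1 relabeling", {
  set.seed(11)
  for (i in 1:20) {
    sm <- random_site_matrix(8, 10)
    base <- rmin(sm)$rmin
    perm <- sm
    perm$alleles <- perm$alleles[sample(nrow(perm$alleles)), , drop = FALSE]
    expect_equal(rmin(perm)$rmin, base)
    flip <- sm
    cols <- sample(10, 4)
    flip$alleles[, cols] <- 1L - flip$alleles[, cols]
    expect_equal(rmin(flip)$rmin, base)
  }
})

test_that("rho is non-negative, finite, and zero without an LD signal", {
  # two identical haplotype groups: all sites in perfect association
  al <- rbind(matrix(0L, 5, 6), matrix(1L, 5, 6))
  sm <- structure(list(sites = 1:6, alleles = al, L = 1000L, n_copies = 10L),
                  class = "ylink_site_matrix")
  est <- hudson_rho(sm)
  expect_gte(est$rho_locus, 0)
  expect_true(is.finite(est$rho_locus))

  # a variance above the zero-recombination expectation pins rho at 0
  al2 <- rbind(matrix(0L, 8, 6), matrix(1L, 2, 6))
  sm2 <- structure(list(sites = 1:6, alleles = al2, L = 1000L,
                        n_copies = 10L), class = "ylink_site_matrix")
  expect_equal(hudson_rho(sm2)$rho_locus, 0)

  novar <- structure(list(sites = integer(0),
                          alleles = matrix(integer(0), nrow = 5, ncol = 0),
                          L = 100L, n_copies = 5L),
                     class = "ylink_site_matrix")
  expect_warning(z <- hudson_rho(novar), "no variation")
  expect_equal(z$rho_locus, 0)
})

test_that("rho recovery on coalescent simulations matches known behavior", {
  # msprime (via the system python) generates the independent coalescent
  # data; the estimator never sees how they were produced
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- withr::local_tempfile(fileext = ".py")
  out <- withr::local_tempfile(fileext = ".json")
  writeLines(c(
    "import msprime, json, sys",
    "out = {}",
    "for rho, nrep in [(1.0, 60), (5.0, 100), (20.0, 100)]:",
    "    reps = []",
    "    for r in range(nrep):",
    "        ts = msprime.sim_ancestry(samples=25, ploidy=2,",
    "            sequence_length=1000, recombination_rate=rho/4/1000,",
    "            population_size=1, random_seed=90000+r+int(rho*997))",
    "        mts = msprime.sim_mutations(ts, rate=10/4/1000,",
    "            random_seed=91000+r+int(rho*997),",
    "            model=msprime.BinaryMutationModel())",
    "        reps.append(mts.genotype_matrix().T.astype(int).tolist())",
    "    out[str(rho)] = reps",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(out))), script)
  status <- system2(py, script)
  expect_equal(status, 0L)
  dat <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  med <- vapply(dat, function(reps) {
    median(vapply(reps, function(g) {
      m <- do.call(rbind, lapply(g, unlist))
      keep <- colSums(m) >= 2 & colSums(m) <= nrow(m) - 2
      sm <- structure(list(sites = seq_len(sum(keep)),
                           alleles = m[, keep, drop = FALSE],
                           L = 1000L, n_copies = nrow(m)),
                      class = "ylink_site_matrix")
      hudson_rho(sm)$rho_locus
    }, numeric(1)))
  }, numeric(1))
  # at moderate-to-high recombination the median estimate is within a
  # factor of 2 of the truth; at rho = 1 the moment inversion is
  # median-biased upward (S_k^2 is right-skewed), so only the ordering is
  # asserted there
  expect_gt(med[["5.0"]], 5 / 2)
  expect_lt(med[["5.0"]], 5 * 2)
  expect_gt(med[["20.0"]], 20 / 2)
  expect_lt(med[["20.0"]], 20 * 2)
  expect_lt(med[["1.0"]], med[["5.0"]])
  expect_lt(med[["5.0"]], med[["20.0"]])
})

test_that("conversion-rate scalings reproduce the published arithmetic", {
  expect_equal(signif(cg_from_rho(2.67, 107, 857)$c_g, 2), 2.9e-5)
  expect_equal(signif(cg_from_rho(4.04, 406, 1203)$c_g, 2), 8.3e-6)
  expect_equal(cg_from_rho(0, 50, 1000)$c_g, 0)

  # exact arithmetic identity: linear in rho, inverse in n and L
  expect_equal(cg_from_rho(6, 10, 100)$c_g, 3 * cg_from_rho(2, 10, 100)$c_g)
  expect_equal(cg_from_rho(2, 20, 100)$c_g, cg_from_rho(2, 10, 200)$c_g)
  expect_error(cg_from_rho(1, 0, 100), ">= 1")
})

test_that("similarity-based rates follow mu over divergence", {
  copies <- aln(strrep("A", 100),
                paste0(strrep("A", 99), "C"))
  est <- cg_from_similarity(copies, mu = 2.8e-9)
  expect_equal(est$d_bar, 0.01)
  expect_equal(est$c_g, 2.8e-7)

  expect_warning(ident <- cg_from_similarity(aln("ACGT", "ACGT")),
                 "unbounded")
  expect_equal(ident$c_g, Inf)
})

test_that("similarity-route estimates increase with the true conversion rate", {
  mu <- 1e-7
  TT <- 50000
  grid <- 10^seq(log10(2e-5), log10(2e-3), length.out = 10)
  chat <- vapply(seq_along(grid), function(i) {
    fam <- simulate_gene_family(
      family_sim_params(10, 1000, mu, grid[i], generations = TT,
                        seed = 500 + i))
    cg_from_similarity(fam$sequences, mu = mu)$c_g
  }, numeric(1))
  expect_gt(suppressWarnings(cor(grid, chat, method = "spearman")), 0.9)
})

test_that("chimera detection needs long runs of both families' alleles", {
  # 20 diagnostic columns: family a fixed for A, family b fixed for G
  base <- strrep("T", 40)
  mk <- function(pattern) {
    s <- strsplit(base, "")[[1]]
    s[seq(2, 40, by = 2)] <- pattern
    paste(s, collapse = "")
  }
  fam_a <- aln(mk(rep("A", 20)), mk(rep("A", 20)), mk(rep("A", 20)))
  fam_b <- aln(mk(rep("G", 20)), mk(rep("G", 20)), mk(rep("G", 20)))

  pure <- detect_chimeras(fam_a, fam_b, fam_a[1], min_run = 3)
  expect_false(pure$chimeric)

  half <- aln(mk(c(rep("A", 10), rep("G", 10))))
  res <- detect_chimeras(fam_a, fam_b, half, min_run = 3)
  expect_true(res$chimeric)
  # breakpoint is the midpoint between diagnostic columns 20 and 22
  expect_equal(res$breakpoint, 21)

  one_off <- aln(mk(c(rep("A", 12), "G", rep("A", 7))))
  expect_false(detect_chimeras(fam_a, fam_b, one_off, min_run = 3)$chimeric)

  expect_error(detect_chimeras(fam_a, fam_a, fam_a, min_run = 3),
               "underpowered")
})

test_that("shared variants count identical minor alleles at homologous sites", {
  a_dis <- aln("AATT", "AGTT", "AGTT")
  b_dis <- aln("CCAA", "CTAA", "CTAA")
  expect_equal(shared_variants(a_dis, b_dis)$n_shared, 0L)

  same <- shared_variants(a_dis, a_dis)
  expect_equal(same$n_variant_sites, same$n_shared)

  # 5 variant sites in a; b carries the identical minor allele at 2
  fam_a <- aln("ACGTA", "CGTAC", "CGTAC")  # minor alleles: A,C,G,T,A (row 1)
  fam_b <- aln("AGTAC", "CGTAC", "CGGAC")
  got <- shared_variants(fam_a, fam_b)
  expect_equal(got$n_variant_sites, 5L)
  expect_equal(got$n_shared, 2L)

  expect_error(shared_variants(aln("AC"), aln("ACT")), "mismatch")
})
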