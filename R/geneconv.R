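# Multicopy gene-family recombination/gene-conversion statistics.
#
# A "copy set" is an aligned multi-FASTA of gene-family copies, represented
# as a Biostrings::DNAStringSet (gaps "-" and N allowed) of equal widths.

.as_char_matrix <- function(copies) {
  if (inherits(copies, "DNAStringSet")) {
    copies <- as.character(copies)
  }
  if (!is.character(copies) || length(copies) < 1) {
    stopf("copies must be a DNAStringSet or character vector")
  }
  w <- unique(nchar(copies))
  if (length(w) != 1L) stopf("aligned copies must share one alignment length")
  m <- do.call(rbind, strsplit(toupper(copies), ""))
  rownames(m) <- names(copies) %||% sprintf("copy%03d", seq_along(copies))
  m
}

#' Drop short fragments from an aligned copy set
#'
#' Removes sequences whose non-gap length (aligned columns that are not
#' `-`) is below `min_len`. Short fragments carry little information and
#' inflate missing data in downstream site matrices; the default threshold
#' is 280 bp.
#'
#' @param copies Aligned copies ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param min_len Minimum non-gap length to retain (a copy of exactly
#'   `min_len` bp is kept).
#' @return A [Biostrings::DNAStringSet] of the retained copies, with
#'   attribute `n_dropped`.
#' @export
filter_fragments <- function(copies, min_len = 280L) {
  x <- if (inherits(copies, "DNAStringSet")) copies else
    Biostrings::DNAStringSet(copies)
  nongap <- Biostrings::width(x) -
    as.integer(Biostrings::letterFrequency(x, letters = "-"))
  keep <- nongap >= min_len
  if (!any(keep)) stopf("no copies of length >= %d remain", min_len)
  out <- x[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Extract biallelic segregating sites from an aligned copy set
#'
#' Gaps and N are treated as missing. Columns with exactly two distinct
#' bases among non-missing entries and a minor-allele count of at least
#' `min_minor` are emitted, coded 0 for the major and 1 for the minor allele
#' (count ties broken by making the lexicographically smaller base the 0
#' allele). Singleton sites are excluded by default: they cannot create
#' four-gamete violations.
#'
#' @param copies Aligned copies.
#' @param min_minor Minimum minor-allele count (default 2).
#' @param L Locus length used for per-site scaling downstream; defaults to
#'   the alignment length.
#' @return A list of class `"ylink_site_matrix"`: `sites` (alignment column
#'   indices, strictly increasing), `alleles` (copies x sites integer matrix
#'   of 0/1/`NA`), `L`, `n_copies`.
#' @export
extract_biallelic_sites <- function(copies, min_minor = 2L, L = NULL) {
  m <- .as_char_matrix(copies)
  if (nrow(m) < 2) stopf("need at least two sequences")
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1)
  nalleles <- rowSums(counts > 0)
  ord <- t(apply(counts, 1, order, decreasing = TRUE))
  # order() is stable, so ties already resolve to the lexicographically
  # smaller base as the major (0) allele
  major_i <- ord[, 1]
  minor_i <- ord[, 2]
  minor_n <- counts[cbind(seq_len(nrow(counts)), minor_i)]
  sel <- which(nalleles == 2 & minor_n >= min_minor)
  alleles <- matrix(NA_integer_, nrow = nrow(m), ncol = length(sel),
                    dimnames = list(rownames(m), NULL))
  for (k in seq_along(sel)) {
    col <- m[, sel[k]]
    a <- rep(NA_integer_, nrow(m))
    a[col == bases[major_i[sel[k]]]] <- 0L
    a[col == bases[minor_i[sel[k]]]] <- 1L
    alleles[, k] <- a
  }
  structure(list(sites = sel, alleles = alleles,
                 L = as.integer(L %||% ncol(m)), n_copies = nrow(m)),
            class = "ylink_site_matrix")
}

#' Minimum number of recombination events (four-gamete test)
#'
#' Applies the four-gamete test to every pair of sites using
#' pairwise-complete copies: a pair showing all four haplotypes 00, 01, 10,
#' 11 requires at least one recombination or gene-conversion event under
#' infinite sites. Incompatible pairs become intervals; intervals containing
#' another incompatible interval are removed, and the minimum number of
#' events is the size of the maximum set of pairwise-disjoint remaining
#' intervals (greedy selection on sorted right endpoints; disjoint means
#' sharing no site).
#'
#' @param matrix A `"ylink_site_matrix"` from [extract_biallelic_sites()].
#' @return A list with `rmin` (integer >= 0) and `intervals`
#'   (`data.frame` of the selected disjoint incompatible intervals, as
#'   site-matrix indices `left`/`right` and alignment columns
#'   `left_col`/`right_col`).
#' @export
rmin <- function(matrix) {
  stopifnot(inherits(matrix, "ylink_site_matrix"))
  al <- matrix$alleles
  S <- ncol(al)
  empty <- data.frame(left = integer(0), right = integer(0),
                      left_col = integer(0), right_col = integer(0))
  if (S < 2) return(list(rmin = 0L, intervals = empty))
  inc <- list()
  for (i in seq_len(S - 1L)) {
    xi <- al[, i]
    for (j in seq((i + 1L), S)) {
      xj <- al[, j]
      ok <- !is.na(xi) & !is.na(xj)
      if (sum(ok) < 4) next
      h <- unique(xi[ok] * 2L + xj[ok])
      if (length(h) == 4L) inc[[length(inc) + 1L]] <- c(i, j)
    }
  }
  if (length(inc) == 0) return(list(rmin = 0L, intervals = empty))
  iv <- do.call(rbind, inc)
  # keep only minimal intervals: drop any that strictly contains another
  keep <- vapply(seq_len(nrow(iv)), function(k) {
    !any(iv[, 1] >= iv[k, 1] & iv[, 2] <= iv[k, 2] &
           (iv[, 1] > iv[k, 1] | iv[, 2] < iv[k, 2]))
  }, logical(1))
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  sel <- integer(0)
  last_right <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv[k, 1] > last_right) {  # shares no site with the previous pick
      sel <- c(sel, k)
      last_right <- iv[k, 2]
    }
  }
  chosen <- iv[sel, , drop = FALSE]
  list(rmin = length(sel),
       intervals = data.frame(left = chosen[, 1], right = chosen[, 2],
                              left_col = matrix$sites[chosen[, 1]],
                              right_col = matrix$sites[chosen[, 2]]))
}

# Pairwise-difference counts between all rows of a 0/1/NA matrix, counted
# over sites where both rows are non-missing. Returns the vector over pairs
# i < j.
.pairwise_diffs <- function(al) {
  a1 <- (al == 1L)
  a0 <- (al == 0L)
  a1[is.na(a1)] <- FALSE
  a0[is.na(a0)] <- FALSE
  k <- tcrossprod(a1 * 1, a0 * 1)
  k <- k + t(k)
  k[upper.tri(k)]
}

# Locus-averaged two-locus coalescence-time covariance
#   (2 / C^2) * int_0^C (C - x) * g(x) dx,  g(x) = (alpha x + beta) / D(x),
# with D(x) = x^2 + 13x + 18. The three sampling configurations of a pair
# of pairwise coalescence times have (diffusion-approximation) covariances
#   same pair:      g(x) = (x + 18) / D(x)
#   one shared:     g(x) = 6 / D(x)
#   none shared:    g(x) = 4 / D(x)
# which reduce to the exact single-tree values 1, 1/3, 2/9 at x = 0.
.cov_integral <- function(C, alpha, beta) {
  if (C < 1e-6) return(beta / 18)
  s <- sqrt(97)
  r1 <- (-13 + s) / 2
  r2 <- (-13 - s) / 2
  A <- (alpha * r1 + beta) / s
  B <- -(alpha * r2 + beta) / s
  l1 <- log((C - r1) / (-r1))
  l2 <- log((C - r2) / (-r2))
  I1 <- A * l1 + B * l2
  I2 <- A * (C + r1 * l1) + B * (C + r2 * l2)
  (2 / C^2) * (C * I1 - I2)
}

# Neutral-coalescent expectation of the variance of pairwise differences
# S_k^2 (denominator = number of pairs) for sample size n, locus-wide theta,
# and per-locus recombination parameter C. Decomposes S_k^2 into the
# variance of one pairwise difference minus the variance of the mean, with
# exact theta (shared-mutation) terms -- which recombination does not touch
# -- and theta^2 (shared-genealogy) terms decaying with C through the
# two-locus covariances above. Exact at C = 0, where it reduces to the
# classic moments of the mean pairwise difference.
.expected_sksq <- function(C, theta, n) {
  P <- n * (n - 1) / 2
  phi2 <- .cov_integral(C, 1, 18)  # same pair
  phi1 <- .cov_integral(C, 0, 6)   # one shared lineage
  phi0 <- .cov_integral(C, 0, 4)   # disjoint pairs
  var_k <- theta + theta^2 * phi2
  cov1 <- theta / 2 + theta^2 * phi1
  cov0 <- theta / 3 + theta^2 * phi0
  n_cov1 <- n * (n - 1) * (n - 2)            # ordered pair-pairs sharing one
  n_cov0 <- n * (n - 1) * (n - 2) * (n - 3) / 4  # ordered disjoint pair-pairs
  var_kbar <- (P * var_k + n_cov1 * cov1 + n_cov0 * cov0) / P^2
  var_k - var_kbar
}

#' LD-based estimate of the population recombination parameter
#'
#' Estimates the per-locus population recombination parameter `C` (rho) by
#' matching the observed variance of the number of pairwise differences to
#' its neutral-coalescent expectation, following the classic
#' variance-of-pairwise-differences approach: excess identity-by-descent
#' between site pairs inflates that variance at low recombination, and
#' recombination (or, in a tandem gene family, gene conversion) deflates it.
#' The expectation is exact at `C = 0` and decays with `C` through the
#' two-locus coalescence-time covariance; `C` is located by monotone
#' bisection on `[0, 1000]` to a tolerance of `1e-4`. When the observed
#' variance exceeds the `C = 0` expectation the estimate is 0.
#'
#' @param matrix A `"ylink_site_matrix"`.
#' @param n_seqs Number of sequences (defaults to the matrix's copy count).
#' @return A list with `rho_locus`, `theta_locus` (mean pairwise
#'   differences), `sksq` (observed variance of pairwise differences), and
#'   `n_seqs`.
#' @export
hudson_rho <- function(matrix, n_seqs = NULL) {
  stopifnot(inherits(matrix, "ylink_site_matrix"))
  n <- n_seqs %||% matrix$n_copies
  if (n < 3) stopf("need at least 3 sequences")
  k <- .pairwise_diffs(matrix$alleles)
  theta <- mean(k)
  sksq <- mean((k - theta)^2)
  if (theta == 0 || ncol(matrix$alleles) < 2) {
    if (theta == 0) warnf("no variation among copies; rho set to 0")
    return(list(rho_locus = 0, theta_locus = theta, sksq = sksq, n_seqs = n))
  }
  f <- function(C) .expected_sksq(C, theta, n) - sksq
  if (f(0) <= 0) {
    return(list(rho_locus = 0, theta_locus = theta, sksq = sksq, n_seqs = n))
  }
  lo <- 0
  hi <- 1000
  if (f(hi) > 0) {
    return(list(rho_locus = hi, theta_locus = theta, sksq = sksq, n_seqs = n))
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  list(rho_locus = (lo + hi) / 2, theta_locus = theta, sksq = sksq,
       n_seqs = n)
}

#' Gene-conversion rate from the population recombination parameter
#'
#' Converts a per-locus population recombination parameter into a
#' per-site, per-generation gene-conversion rate for an `n_copies`-member
#' family over an `L`-bp locus via `c_g = rho / (n_copies * L)`. This
#' scaling reproduces the published (rho, n, L, c_g) quadruples for the
#' Y-linked families it was built for; see the methods vignette for its
#' status as a reconstruction.
#'
#' @param rho_locus Per-locus rho (>= 0).
#' @param n_copies Number of copies (>= 1).
#' @param L Locus length in bp (>= 1).
#' @return A list of class `"ylink_conversion_rate"` with `c_g`, `method`,
#'   `n_copies`, `L`, `rho_locus`.
#' @examples
#' cg_from_rho(2.67, 107, 857)$c_g   # ~2.9e-5
#' cg_from_rho(4.04, 406, 1203)$c_g  # ~8.3e-6
#' @export
cg_from_rho <- function(rho_locus, n_copies, L) {
  if (n_copies < 1 || L < 1) stopf("n_copies and L must be >= 1")
  if (rho_locus < 0) stopf("rho_locus must be >= 0")
  structure(list(c_g = rho_locus / (n_copies * L), method = "from_rho",
                 n_copies = as.integer(n_copies), L = as.integer(L),
                 rho_locus = rho_locus),
            class = "ylink_conversion_rate")
}

# Mean, over uniform site pairs in a locus of length L, of the probability
# that a geometric(mean tract_mean) conversion tract covers one site of the
# pair but not the other, relative to covering a single site.
.tract_weight <- function(L, tract_mean) {
  r <- tract_mean / L
  1 - 2 * r + 2 * r^2 * (1 - exp(-1 / r))
}

#' Conversion rate from rho and theta for a conversion-driven family
#'
#' For a tandem family homogenized by gene conversion at mutation-drift
#' balance, the copies' genealogy is a coalescent whose timescale is set by
#' conversion itself, so the LD-based `rho` alone is dimensionless in `c`.
#' Combining it with the observed diversity restores the units: with
#' per-site `theta = 4 N mu` and `rho = 4 N r_locus`, where the effective
#' locus-wide exchange rate of conversion is `r_locus ~ 6 w c` (`w` the
#' tract-geometry weight: the chance a tract separates a random site pair),
#' the conversion rate is
#' `c_g = rho * mu / (6 * w * theta_site)`.
#' This is the scaling used to validate rate recovery on families simulated
#' with [simulate_gene_family()]; see the methods vignette for the
#' derivation and its assumptions.
#'
#' @param rho_locus Per-locus rho from [hudson_rho()].
#' @param theta_locus Mean pairwise differences per locus (from the same
#'   fit).
#' @param mu Mutation rate per site per generation.
#' @param L Locus length in bp.
#' @param tract_mean Mean conversion tract length (bp).
#' @return A list of class `"ylink_conversion_rate"` with `c_g`, `method`,
#'   `mu`, `L`, `rho_locus`.
#' @export
cg_from_rho_scaled <- function(rho_locus, theta_locus, mu, L,
                               tract_mean = 500) {
  if (L < 1) stopf("L must be >= 1")
  if (theta_locus <= 0) stopf("theta_locus must be > 0")
  w <- .tract_weight(L, tract_mean)
  theta_site <- theta_locus / L
  structure(list(c_g = rho_locus * mu / (6 * w * theta_site),
                 method = "from_rho_scaled", mu = mu, L = as.integer(L),
                 rho_locus = rho_locus),
            class = "ylink_conversion_rate")
}

#' Mean pairwise divergence of an aligned copy set
#'
#' Per-site divergence averaged over all copy pairs, using only columns
#' where both copies have a non-missing base (gaps and N excluded).
#'
#' @param copies Aligned copies.
#' @return Mean pairwise divergence (proportion of differing shared sites).
#' @export
mean_pairwise_divergence <- function(copies) {
  m <- .as_char_matrix(copies)
  if (nrow(m) < 2) stopf("need at least two sequences")
  bases <- c("A", "C", "G", "T")
  obs <- matrix(m %in% bases, nrow = nrow(m))
  shared <- tcrossprod(obs * 1)
  match_n <- Reduce(`+`, lapply(bases, function(b) {
    x <- (m == b) * 1
    tcrossprod(x)
  }))
  sh <- shared[upper.tri(shared)]
  ma <- match_n[upper.tri(match_n)]
  ok <- sh > 0
  if (!any(ok)) stopf("no pair shares a non-missing column")
  mean(1 - ma[ok] / sh[ok])
}

#' Gene-conversion rate from sequence similarity
#'
#' Under mutation-conversion balance in a homogenized multicopy family, the
#' standing divergence among copies reflects the ratio of the mutation rate
#' to the rate at which conversion overwrites sites. The default estimator
#' is `c_g = mu / d_bar` with `d_bar` the mean pairwise divergence; an
#' alternative including copy number (`mu * n / d_bar`) is selectable.
#'
#' @param copies Aligned copies.
#' @param mu Mutation rate per site per generation (default 2.8e-9).
#' @param formula `"mu_over_d"` (default) or `"mu_n_over_d"`.
#' @return A list of class `"ylink_conversion_rate"` with `c_g` (`Inf` with
#'   a warning when the copies are identical), `method`, `mu`, `d_bar`,
#'   `n_copies`.
#' @export
cg_from_similarity <- function(copies, mu = 2.8e-9,
                               formula = c("mu_over_d", "mu_n_over_d")) {
  formula <- match.arg(formula)
  m <- .as_char_matrix(copies)
  d_bar <- mean_pairwise_divergence(copies)
  if (d_bar == 0) {
    warnf("identical copies: similarity-based c_g is unbounded")
    cg <- Inf
  } else {
    cg <- switch(formula, mu_over_d = mu / d_bar,
                 mu_n_over_d = mu * nrow(m) / d_bar)
  }
  structure(list(c_g = cg, method = "from_similarity", mu = mu,
                 d_bar = d_bar, n_copies = nrow(m)),
            class = "ylink_conversion_rate")
}

# Majority-base consensus of each alignment column among non-missing
# entries; returns list(base, freq, n_obs).
.family_consensus <- function(m) {
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1)
  n_obs <- rowSums(counts)
  best <- max.col(counts, ties.method = "first")
  freq <- counts[cbind(seq_len(nrow(counts)), best)] / pmax(n_obs, 1)
  list(base = bases[best], freq = freq, n_obs = n_obs)
}

#' Detect chimeric copies between two gene families
#'
#' Diagnostic columns are those where the two family consensuses differ and
#' each family's consensus allele frequency is at least `purity`. Each query
#' copy's diagnostic positions are labeled by the family consensus they
#' match; a query is chimeric when it carries at least `min_run` consecutive
#' diagnostic positions of EACH family label -- the signature of an
#' intergenic gene-conversion or recombination breakpoint. The reported
#' breakpoint is the alignment-column midpoint between the two flanking
#' runs.
#'
#' @param family_a,family_b Aligned copy sets sharing one coordinate system.
#' @param query Aligned copies to scan (same coordinates).
#' @param min_run Minimum consecutive diagnostic positions per label
#'   (default 3).
#' @param purity Minimum within-family consensus allele frequency for a
#'   column to be diagnostic (default 0.9).
#' @return A `data.frame` (`copy`, `chimeric`, `breakpoint`, `max_run_a`,
#'   `max_run_b`).
#' @export
detect_chimeras <- function(family_a, family_b, query, min_run = 3L,
                            purity = 0.9) {
  ma <- .as_char_matrix(family_a)
  mb <- .as_char_matrix(family_b)
  mq <- .as_char_matrix(query)
  if (ncol(ma) != ncol(mb) || ncol(ma) != ncol(mq)) {
    stopf("families and query must share one alignment coordinate system")
  }
  ca <- .family_consensus(ma)
  cb <- .family_consensus(mb)
  diag_cols <- which(ca$base != cb$base & ca$freq >= purity &
                       cb$freq >= purity & ca$n_obs > 0 & cb$n_obs > 0)
  if (length(diag_cols) < min_run) {
    stopf("only %d diagnostic column(s); chimera test underpowered",
          length(diag_cols))
  }
  out <- lapply(seq_len(nrow(mq)), function(q) {
    b <- mq[q, diag_cols]
    lab <- ifelse(b == ca$base[diag_cols], "a",
                  ifelse(b == cb$base[diag_cols], "b", NA_character_))
    cols <- diag_cols[!is.na(lab)]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) {
      return(data.frame(copy = rownames(mq)[q], chimeric = FALSE,
                        breakpoint = NA_real_, max_run_a = 0L,
                        max_run_b = 0L, stringsAsFactors = FALSE))
    }
    r <- rle(lab)
    qual <- r$lengths >= min_run
    has_a <- any(qual & r$values == "a")
    has_b <- any(qual & r$values == "b")
    chim <- has_a && has_b
    bp <- NA_real_
    if (chim) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      qi <- which(qual)
      # first adjacent pair of qualifying runs with different labels
      for (u in seq_len(length(qi) - 1L)) {
        i1 <- qi[u]; i2 <- qi[u + 1L]
        if (r$values[i1] != r$values[i2]) {
          bp <- (cols[ends[i1]] + cols[starts[i2]]) / 2
          break
        }
      }
    }
    data.frame(copy = rownames(mq)[q], chimeric = chim, breakpoint = bp,
               max_run_a = max(c(0L, r$lengths[r$values == "a"])),
               max_run_b = max(c(0L, r$lengths[r$values == "b"])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count variant sites of one family shared with another
#'
#' Variant sites of family A are its biallelic alignment columns; a variant
#' is shared when family B segregates (or is fixed for) the identical minor
#' allele at the homologous column -- the signature of exchange or shared
#' ancestry between the families.
#'
#' @param family_a,family_b Aligned copy sets on common coordinates.
#' @param min_minor Minimum minor-allele count in family A for a column to
#'   count as variant (default 1: all variants).
#' @return A list with `n_variant_sites` and `n_shared`.
#' @export
shared_variants <- function(family_a, family_b, min_minor = 1L) {
  ma <- .as_char_matrix(family_a)
  mb <- .as_char_matrix(family_b)
  if (ncol(ma) != ncol(mb)) stopf("alignment coordinate mismatch")
  bases <- c("A", "C", "G", "T")
  ca <- vapply(bases, function(b) colSums(ma == b), numeric(ncol(ma)))
  cb <- vapply(bases, function(b) colSums(mb == b), numeric(ncol(mb)))
  if (ncol(ma) == 1L) { ca <- matrix(ca, nrow = 1); cb <- matrix(cb, nrow = 1) }
  nall <- rowSums(ca > 0)
  ord <- t(apply(ca, 1, order, decreasing = TRUE))
  minor_i <- ord[, 2]
  minor_n <- ca[cbind(seq_len(nrow(ca)), minor_i)]
  variant <- which(nall == 2 & minor_n >= min_minor)
  shared <- vapply(variant, function(s) {
    cb[s, minor_i[s]] > 0
  }, logical(1))
  list(n_variant_sites = length(variant), n_shared = sum(shared))
}
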