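# Shared fixture builders (everything is generated in code; no binary data).

# Minimal SAM text from a record table.
toy_sam <- function(refs, records) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)))
  body <- vapply(records, function(r) {
    paste(r$qname, r$flag %||% 0L, r$rname %||% "*", r$pos %||% 0L,
          r$mapq %||% 60L, r$cigar %||% "100M", "*", 0L, 0L, "*", "*",
          sep = "\t")
  }, character(1))
  c(header, body)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rec <- function(qname, flag = 0L, rname = "*", pos = 0L, mapq = 60L,
                cigar = "100M") {
  list(qname = qname, flag = flag, rname = rname, pos = pos, mapq = mapq,
       cigar = cigar)
}

# A depth track built directly from vectors (one contig).
toy_track <- function(contig, depth) {
  data.frame(contig = contig, pos = seq_along(depth),
             depth = as.integer(depth), stringsAsFactors = FALSE)
}

# Independent four-gamete scan: for every site pair, tabulate haplotypes
# over pairwise-complete rows by explicit enumeration.
oracle_incompatible_pairs <- function(al) {
  S <- ncol(al)
  out <- list()
  if (S < 2) return(out)
  for (i in seq_len(S - 1)) {
    for (j in seq(i + 1, S)) {
      seen <- c("00" = FALSE, "01" = FALSE, "10" = FALSE, "11" = FALSE)
      for (r in seq_len(nrow(al))) {
        x <- al[r, i]
        y <- al[r, j]
        if (!is.na(x) && !is.na(y)) seen[paste0(x, y)] <- TRUE
      }
      if (all(seen)) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

# Exhaustive maximum set of pairwise-disjoint intervals (no shared site),
# by recursive include/exclude search over all subsets.
oracle_max_disjoint <- function(ivs) {
  if (length(ivs) == 0) return(0L)
  best <- 0L
  recurse <- function(idx, picked_right) {
    if (length(idx) == 0) return(0L)
    k <- idx[1]
    rest <- idx[-1]
    skip <- recurse(rest, picked_right)
    take <- 0L
    if (ivs[[k]][1] > picked_right) {
      take <- 1L + recurse(rest, ivs[[k]][2])
    }
    max(skip, take)
  }
  recurse(seq_along(ivs), -Inf)
}

# Brute-force Rmin oracle on a 0/1/NA allele matrix.
oracle_rmin <- function(al) {
  ivs <- oracle_incompatible_pairs(al)
  ord <- order(vapply(ivs, `[`, numeric(1), 1))
  oracle_max_disjoint(ivs[ord])
}

# Random allele matrix with missing data, for property tests.
random_site_matrix <- function(n_copies, n_sites, p_minor = 0.4,
                               p_missing = 0.1) {
  al <- matrix(rbinom(n_copies * n_sites, 1, p_minor), nrow = n_copies)
  al[runif(n_copies * n_sites) < p_missing] <- NA
  structure(list(sites = seq_len(n_sites), alleles = al,
                 L = n_sites, n_copies = n_copies),
            class = "ylink_site_matrix")
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from choose() directly.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_
  n2 <- b + d
  k <- a + b
  lo <- max(0, k - n2)
  hi <- min(k, m)
  tabs <- lo:hi
  logp <- lchoose(m, tabs) + lchoose(n2, k - tabs) - lchoose(m + n2, k)
  p <- exp(logp)
  p_obs <- p[tabs == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}
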