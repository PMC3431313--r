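# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the code paths they check.

# upper Poisson tail P(X >= k) by direct pmf summation
oracle_pois_upper <- function(k, lambda) {
  if (k == 0) return(1)
  sum(dpois(seq(k, k + 2000L), lambda))
}

# upper binomial tail P(X >= k) by direct pmf summation
oracle_binom_upper <- function(k, n, pi) {
  if (k == 0) return(1)
  sum(dbinom(seq(k, n), n, pi))
}

# maximal runs of >= min_run consecutive same-family genes, by a linear scan
# over the gene order (independent of detect_clusters' grouping logic)
oracle_cluster_runs <- function(chrom, family, min_run = 3) {
  runs <- list()
  for (ch in unique(chrom)) {
    f <- family[chrom == ch]
    i <- 1L
    while (i <= length(f)) {
      if (is.na(f[i])) { i <- i + 1L; next }
      j <- i
      while (j < length(f) && !is.na(f[j + 1L]) && f[j + 1L] == f[i]) j <- j + 1L
      if (j - i + 1L >= min_run) {
        runs[[length(runs) + 1L]] <- list(chrom = ch, family = f[i],
                                          n = j - i + 1L)
      }
      i <- j + 1L
    }
  }
  runs
}

# count of A intervals overlapping any B interval, all-pairs quadratic scan
oracle_overlap_count <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) hit <- TRUE
    }
    n <- n + hit
  }
  n
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# quick annotation builder (0-based half-open coordinates)
make_annotation <- function(chrom, start, end, strand = NULL, gene_id = NULL,
                            family_id = NULL, chrom_sizes = NULL) {
  n <- length(start)
  strand <- strand %||% rep("+", n)
  gene_id <- gene_id %||% sprintf("g%03d", seq_len(n))
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   gene_id = gene_id, stringsAsFactors = FALSE)
  if (!is.null(family_id)) df$family_id <- family_id
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(end, chrom, function(e) max(e) + 10000)
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  genome_annotation(df, chrom_sizes)
}

# build a window_pvalues object directly from score vectors (p = 10^-score)
fake_pvals <- function(scores, width = 100) {
  chrom_sizes <- setNames(lengths(scores) * width, names(scores))
  structure(list(p = lapply(scores, function(s) 10^(-s)),
                 score = scores,
                 lambda = lapply(scores, function(s) rep(1, length(s))),
                 width = width, chrom_sizes = chrom_sizes, lambda_min = 1),
            class = "window_pvalues")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
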