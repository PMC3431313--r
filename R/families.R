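## Gene-family handling: catalog, cluster detection (runs of >= 3 adjacent
## same-family genes), exact binomial enrichment, family x sample z-score
## matrices and hierarchical ordering.

#' Build a gene-family catalog
#'
#' @param map data.frame with `gene_id` and `family_id` columns (one row per
#'   gene; genes listed under several families keep their first assignment,
#'   with a message).
#' @return a `family_catalog`: named list `families` (family_id -> gene ids)
#'   plus the flat `map` data.frame.
#' @export
family_catalog <- function(map) {
  stopifnot(all(c("gene_id", "family_id") %in% names(map)))
  map <- map[!is.na(map$family_id) & nzchar(map$family_id), , drop = FALSE]
  dup <- duplicated(map$gene_id)
  if (any(dup)) {
    message(sprintf("%d gene(s) listed in multiple families; keeping first assignment",
                    length(unique(map$gene_id[dup]))))
    map <- map[!dup, , drop = FALSE]
  }
  structure(list(families = split(map$gene_id, map$family_id),
                 map = map[c("gene_id", "family_id")]),
            class = "family_catalog")
}

## family id per gene_id, NA for non-members
family_of <- function(catalog, gene_ids) {
  idx <- match(gene_ids, catalog$map$gene_id)
  catalog$map$family_id[idx]
}

#' Detect gene-family clusters
#'
#' A cluster is a maximal run of at least `min_run` consecutive genes of one
#' family in chromosomal gene order. Any intervening gene of a different
#' family (or of no family) breaks the run; `max_intervening` relaxes this
#' by allowing that many consecutive non-member genes inside a run.
#'
#' @param annotation a [genome_annotation()] (genes sorted by chrom, start).
#' @param catalog a [family_catalog()]; if omitted, the annotation's
#'   `family_id` column is used.
#' @param min_run minimum genes per cluster (default 3).
#' @param max_intervening tolerated consecutive non-member genes within a
#'   run (default 0, the strict side-by-side reading).
#' @return a `cluster_set` data.frame: `cluster_id`, `family_id`, `chrom`,
#'   `start`, `end` (span of member genes), `n_genes`, `gene_ids`
#'   (list column).
#' @export
detect_clusters <- function(annotation, catalog = NULL, min_run = 3,
                            max_intervening = 0) {
  genes <- as.data.frame(annotation)
  fam <- if (is.null(catalog)) genes$family_id else
    family_of(catalog, genes$gene_id)
  rows <- list()
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    f <- fam[gi]
    i <- 1L
    while (i <= length(gi)) {
      if (is.na(f[i])) { i <- i + 1L; next }
      # extend a run of family f[i] allowing gaps of <= max_intervening
      members <- i
      j <- i + 1L; gap <- 0L
      while (j <= length(gi)) {
        if (!is.na(f[j]) && f[j] == f[i]) {
          members <- c(members, j); gap <- 0L
        } else if (is.na(f[j]) && gap < max_intervening) {
          gap <- gap + 1L
        } else break
        j <- j + 1L
      }
      if (length(members) >= min_run) {
        idx <- gi[members]
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = f[i], chrom = ch,
          start = min(genes$start[idx]), end = max(genes$end[idx]),
          n_genes = length(members), stringsAsFactors = FALSE)
        rows[[length(rows)]]$gene_ids <- list(genes$gene_id[idx])
        i <- max(members) + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_genes = integer(0),
               gene_ids = I(list()), stringsAsFactors = FALSE)
  out <- cbind(cluster_id = if (nrow(out)) paste0("cluster", seq_len(nrow(out)))
               else character(0), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Gene ids belonging to any cluster
#' @param clusters a `cluster_set` from [detect_clusters()].
#' @return character vector of gene ids.
#' @export
clustered_genes <- function(clusters) {
  unique(unlist(clusters$gene_ids, use.names = FALSE))
}

#' Exact one-sided binomial enrichment p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, pi)`: the probability of observing at
#' least `k` successes among `n` draws at background proportion `pi`.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @param pi background success proportion in (0, 1).
#' @return the exact upper-tail p-value.
#' @export
binomial_enrichment <- function(k, n, pi) {
  if (!is.numeric(pi) || any(pi <= 0) || any(pi >= 1)) {
    stop2("`pi` must be in (0, 1)")
  }
  if (any(k < 0) || any(k > n)) stop2("need 0 <= k <= n")
  pmin(pbinom(k - 1, n, pi, lower.tail = FALSE), 1)
}

#' Proportion enrichment report
#'
#' Shared report shape for "k of n at background pi" enrichments: the
#' observed fraction, the integer-rounded percentage, and the exact
#' binomial upper-tail p-value.
#'
#' @param k observed members.
#' @param n group size.
#' @param pi background proportion in (0, 1).
#' @return list: `k`, `n`, `pi`, `fraction`, `percent`, `p` (NA when
#'   `n = 0`).
#' @export
enrichment_report <- function(k, n, pi) {
  list(k = k, n = n, pi = pi,
       fraction = if (n > 0) k / n else NA_real_,
       percent = if (n > 0) round(100 * k / n) else NA_integer_,
       p = if (n > 0) binomial_enrichment(k, n, pi) else NA_real_)
}

#' Family and cluster enrichment among target genes
#'
#' Tests whether target genes are enriched for gene-family members relative
#' to the genome-wide family fraction, and whether target family members are
#' enriched for clustered genes relative to the genome-wide clustered
#' fraction, both by exact binomial upper tails.
#'
#' @param targets a `target_table` from [classify_targets()].
#' @param catalog a [family_catalog()].
#' @param annotation a [genome_annotation()] supplying the gene universe.
#' @param clusters a `cluster_set`; computed from the annotation when
#'   omitted.
#' @return list with `family` and `clustered` reports, each holding `k`,
#'   `n`, `pi`, `fraction`, `percent` (rounded to integer), `p`. An empty
#'   target set yields `n = 0` with `p = NA` and `undefined = TRUE`.
#' @export
family_enrichment <- function(targets, catalog, annotation, clusters = NULL) {
  genes <- as.data.frame(annotation)
  fam <- family_of(catalog, genes$gene_id)
  in_family <- !is.na(fam)
  pi_f <- mean(in_family)
  if (is.null(clusters)) clusters <- detect_clusters(annotation, catalog)
  clust_ids <- clustered_genes(clusters)
  fam_genes <- genes$gene_id[in_family]
  pi_c <- if (length(fam_genes)) mean(fam_genes %in% clust_ids) else NA_real_
  tgt <- targets$gene_id[targets$target]
  tgt_fam <- tgt[tgt %in% fam_genes]
  out <- list(
    family = enrichment_report(length(tgt_fam), length(tgt), pi_f),
    clustered = enrichment_report(sum(tgt_fam %in% clust_ids),
                                  length(tgt_fam), pi_c),
    genome_family_fraction = pi_f,
    genome_clustered_fraction = pi_c,
    undefined = length(tgt) == 0L)
  out
}

#' Compare binding levels of clustered versus non-clustered family genes
#'
#' Two-group summary (median, quartiles) and a two-sided Wilcoxon rank-sum
#' test (exact when both groups have at most 10 observations and no ties).
#'
#' @param scores named numeric vector of per-gene binding scores.
#' @param clustered_ids gene ids in the clustered group.
#' @param nonclustered_ids gene ids in the non-clustered group.
#' @return list with per-group `summary` (n, median, q1, q3) and `p` from
#'   the rank-sum test.
#' @export
binding_level_comparison <- function(scores, clustered_ids, nonclustered_ids) {
  a <- scores[names(scores) %in% clustered_ids]
  b <- scores[names(scores) %in% nonclustered_ids]
  if (!length(a) || !length(b)) stop2("both groups must be non-empty")
  qs <- function(v) list(n = length(v), median = median(v),
                         q1 = unname(quantile(v, 0.25)),
                         q3 = unname(quantile(v, 0.75)))
  exact <- length(a) <= 10 && length(b) <= 10 && !anyDuplicated(c(a, b))
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact)$p.value)
  list(clustered = qs(a), nonclustered = qs(b), p = p)
}

#' Mean binding score per gene over genic regions
#'
#' @param pvals a `window_pvalues` object.
#' @param annotation a [genome_annotation()].
#' @param flank genic flank in bp (default 3000).
#' @return named numeric vector: mean window score (window midpoints inside
#'   the gene's genic region), NA when no window falls inside.
#' @export
gene_binding_scores <- function(pvals, annotation, flank = 3000) {
  genes <- as.data.frame(annotation)
  cs <- chrom_sizes(annotation)
  w <- pvals$width
  out <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    s <- pvals$score[[ch]]
    if (is.null(s)) next
    lo <- pmax(0, genes$start[i] - flank)
    hi <- pmin(cs[[ch]], genes$end[i] + flank)
    # windows whose midpoint lies in [lo, hi)
    first <- max(1, ceiling((lo - w / 2) / w) + 1)
    last <- min(length(s), ceiling((hi - w / 2) / w))
    if (first > last) next
    out[i] <- mean(s[seq.int(first, last)])
  }
  setNames(out, genes$gene_id)
}

#' Family-by-sample enrichment z-score matrix
#'
#' For each sample track, averages the window scores over every family's
#' genic regions (mean over contributing windows, correcting for family
#' size), then standardizes across families within the sample. Families
#' with no covered window in some sample are dropped and reported.
#'
#' @param tracks named list of `window_pvalues` objects, one per sample.
#' @param annotation a [genome_annotation()].
#' @param catalog a [family_catalog()].
#' @param flank genic flank in bp (default 3000).
#' @return numeric matrix, families x samples, of z-scores; dropped families
#'   in attribute `dropped`.
#' @export
family_zscore_matrix <- function(tracks, annotation, catalog, flank = 3000) {
  if (!length(tracks)) stop2("need at least one sample track")
  fams <- names(catalog$families)
  genes <- as.data.frame(annotation)
  raw <- sapply(tracks, function(tr) {
    sc <- gene_binding_scores(tr, annotation, flank)
    vapply(fams, function(f) {
      v <- sc[names(sc) %in% catalog$families[[f]]]
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
  })
  raw <- matrix(raw, nrow = length(fams),
                dimnames = list(fams, names(tracks)))
  keep <- !apply(raw, 1L, anyNA)
  dropped <- fams[!keep]
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) < 2L) stop2("fewer than 2 families with coverage")
  # standardize each sample across families; a constant column has no
  # between-family contrast and maps to all-zero z-scores
  z <- apply(raw, 2L, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  dimnames(z) <- dimnames(raw)
  attr(z, "dropped") <- dropped
  z
}

#' Hierarchical ordering of an enrichment matrix
#'
#' Agglomerative clustering with correlation distance (1 - Pearson r) and
#' average linkage. Constant rows/columns (undefined correlation) are
#' dropped with a warning.
#'
#' @param mat numeric matrix (families x samples).
#' @param axis `"families"` (rows) or `"samples"` (columns).
#' @return list with `order` (labels in dendrogram order), `tree` (an
#'   [stats::hclust] object), and `dropped` labels.
#' @export
hierarchical_order <- function(mat, axis = c("families", "samples")) {
  axis <- match.arg(axis)
  m <- if (axis == "families") t(mat) else mat
  sds <- apply(m, 2L, sd)
  dropped <- colnames(m)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warn2("dropping constant %s: %s", axis, paste(dropped, collapse = ", "))
    m <- m[, !(colnames(m) %in% dropped), drop = FALSE]
  }
  if (ncol(m) < 2L) stop2("need at least 2 non-constant %s", axis)
  d <- as.dist(1 - cor(m))
  tree <- hclust(d, method = "average")
  list(order = tree$labels[tree$order], tree = tree, dropped = dropped)
}
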