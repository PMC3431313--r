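## Peak-set comparison: any-overlap sharing, permutation exclusivity test
## (uniform relocation or circular shift null), and generic annotation-term
## enrichment with BH correction.

## Vectorised any-overlap of query intervals [s, e) against a reduced,
## sorted, disjoint union (us, ue). Used in the permutation hot loop.
overlaps_union <- function(s, e, us, ue) {
  if (!length(us)) return(rep(FALSE, length(s)))
  j <- findInterval(s, us)
  hit <- j >= 1L & ue[pmax(j, 1L)] > s
  nxt <- j + 1L
  hit | (nxt <= length(us) & us[pmin(nxt, length(us))] < e)
}

#' Overlap between two interval sets
#'
#' An element of A is "shared" iff it overlaps at least 1 bp of any element
#' of B (half-open coordinates).
#'
#' @param a,b interval data.frames with `chrom`, `start`, `end` (e.g.
#'   `peak_set`s or [load_intervals()] output).
#' @param strict_chroms error (rather than count zero overlap) when A uses a
#'   chromosome absent from B and vice versa; default FALSE.
#' @return list: `n_a`, `n_b`, `shared` (count of A elements overlapping B),
#'   `fraction` (`shared / n_a`).
#' @export
overlap_fraction <- function(a, b, strict_chroms = FALSE) {
  if (strict_chroms) {
    off <- union(setdiff(unique(a$chrom), unique(b$chrom)),
                 setdiff(unique(b$chrom), unique(a$chrom)))
    if (length(off)) {
      stop2("chromosome name mismatch between sets: %s",
            paste(off, collapse = ", "))
    }
  }
  shared <- 0L
  for (ch in unique(a$chrom)) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    shared <- shared + sum(overlaps_any0(ai$start, ai$end, bi$start, bi$end))
  }
  list(n_a = nrow(a), n_b = nrow(b), shared = shared,
       fraction = if (nrow(a)) shared / nrow(a) else NA_real_)
}

#' Permutation test for peak-set exclusivity
#'
#' Tests whether A overlaps B less than expected by chance. The null
#' relocates each A interval uniformly at random within its chromosome
#' (per-chromosome counts and lengths preserved; relocated intervals may
#' overlap each other). The alternative `"circular"` null applies one random
#' circular shift per chromosome, preserving inter-interval spacing. The
#' empirical one-sided p-value for under-overlap uses the add-one
#' correction, `p = (1 + #[shared_perm <= shared_obs]) / (n_perm + 1)`.
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`).
#' @param chrom_sizes named chromosome lengths covering all of A's
#'   chromosomes.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param null `"uniform"` (default) or `"circular"`.
#' @return list: observed `shared`, `fraction`, `n_a`, `n_b`, `p`
#'   (exclusivity), `null_shared` (the permutation distribution), `n_perm`.
#' @export
exclusivity_test <- function(a, b, chrom_sizes, n_perm = 1000, seed = 1,
                             null = c("uniform", "circular")) {
  null <- match.arg(null)
  if (n_perm < 1) stop2("`n_perm` must be at least 1")
  obs <- overlap_fraction(a, b)
  chroms <- unique(a$chrom)
  missing <- setdiff(chroms, names(chrom_sizes))
  if (length(missing)) {
    stop2("chrom_sizes lacks: %s", paste(missing, collapse = ", "))
  }
  # per-chromosome precomputation: A lengths, reduced B union
  pre <- lapply(chroms, function(ch) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    len <- ai$end - ai$start
    L <- chrom_sizes[[ch]]
    if (any(len > L)) {
      stop2("interval longer than chromosome '%s' (%s bp)", ch, L)
    }
    bu <- reduce_intervals0(b$start[b$chrom == ch], b$end[b$chrom == ch])
    list(len = len, L = L, us = bu$start, ue = bu$end,
         start = ai$start)
  })
  null_shared <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      tot <- 0L
      for (pc in pre) {
        if (!length(pc$len)) next
        if (null == "uniform") {
          s <- floor(runif(length(pc$len)) * (pc$L - pc$len + 1))
        } else {
          shift <- floor(runif(1) * pc$L)
          s <- (pc$start + shift) %% pc$L
          # wrap: intervals running past the end are re-anchored at 0
          s <- ifelse(s + pc$len > pc$L, 0, s)
        }
        tot <- tot + sum(overlaps_union(s, s + pc$len, pc$us, pc$ue))
      }
      tot
    }, integer(1))
  })
  p <- (1 + sum(null_shared <= obs$shared)) / (n_perm + 1)
  c(obs, list(p = p, null_shared = null_shared, n_perm = n_perm,
              null = null))
}

#' Annotation-term enrichment with BH correction
#'
#' For each term, tests whether the gene set contains more term members than
#' expected from the term's prevalence in the universe, by an exact binomial
#' upper tail; p-values are Benjamini-Hochberg adjusted across terms.
#'
#' @param genes character vector, the gene set (must be within `universe`).
#' @param terms named list: term -> character vector of member genes.
#' @param universe character vector, the gene universe.
#' @return data.frame: term, k (set members in term), n (set size),
#'   prevalence, p, fdr; sorted by p.
#' @export
term_enrichment <- function(genes, terms, universe) {
  if (!length(universe)) stop2("empty gene universe")
  genes <- unique(genes)
  out_of <- setdiff(genes, universe)
  if (length(out_of)) {
    stop2("%d gene(s) outside the universe (e.g. %s)",
          length(out_of), out_of[1L])
  }
  n <- length(genes)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(terms[[tm]], universe)
    pi <- length(members) / length(universe)
    k <- length(intersect(genes, members))
    p <- if (pi <= 0) 1 else if (pi >= 1) 1 else binomial_enrichment(k, n, pi)
    data.frame(term = tm, k = k, n = n, prevalence = pi, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
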