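make_family_ann <- function(fams, chrom = "chr1") {
  n <- length(fams)
  make_annotation(rep(chrom, n), seq_len(n) * 10000,
                  seq_len(n) * 10000 + 2000,
                  family_id = fams,
                  chrom_sizes = setNames((n + 2) * 10000, chrom))
}

test_that("cluster detection finds maximal adjacent same-family runs", {
  ann <- make_family_ann(c("A", "A", "A", "B"))
  cl <- detect_clusters(ann)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$family_id, "A")
  expect_equal(cl$n_genes, 3L)

  # an intervening gene of another family breaks the run
  ann2 <- make_family_ann(c("A", "B", "A", "A"))
  expect_equal(nrow(detect_clusters(ann2)), 0L)
  # ... unless max_intervening relaxes the strict reading (NA gene between)
  ann3 <- make_family_ann(c("A", NA, "A", "A"))
  expect_equal(nrow(detect_clusters(ann3)), 0L)
  expect_equal(detect_clusters(ann3, max_intervening = 1)$n_genes, 3L)
})

test_that("cluster detection agrees with a run-length oracle on random genomes", {
  set.seed(202)
  for (trial in 1:1000) {
    fams <- sample(c(NA, "A", "B", "C"), 20, replace = TRUE,
                   prob = c(0.3, 0.3, 0.2, 0.2))
    chrom <- sort(sample(c("chr1", "chr2"), 20, replace = TRUE))
    ann <- make_annotation(chrom, seq_len(20) * 5000, seq_len(20) * 5000 + 800,
                           family_id = fams,
                           chrom_sizes = c(chr1 = 2e5, chr2 = 2e5))
    got <- detect_clusters(ann)
    # re-derive family order per chromosome after annotation sorting
    df <- as.data.frame(ann)
    want <- oracle_cluster_runs(df$chrom, df$family_id)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$family_id, vapply(want, `[[`, "", "family"))
      expect_equal(got$n_genes, vapply(want, function(w) as.integer(w$n), 1L))
    }
  }
})

test_that("binomial enrichment matches the exact tail", {
  expect_equal(binomial_enrichment(10, 10, 0.5), 2^-10)
  expect_equal(binomial_enrichment(0, 20, 0.3), 1)
  expect_equal(binomial_enrichment(8, 20, 0.3), oracle_binom_upper(8, 20, 0.3),
               tolerance = 1e-12)
  # grid agreement to <= 1e-12 relative error up to n = 5000
  for (n in c(10, 100, 1000, 5000)) {
    for (frac in c(0.01, 0.3, 0.7)) {
      k <- round(frac * n)
      for (pi in c(0.05, 0.28, 0.5)) {
        o <- oracle_binom_upper(k, n, pi)
        if (o < 1e-280) next
        expect_lt(abs(binomial_enrichment(k, n, pi) - o) / o, 1e-12)
      }
    }
  }
  expect_error(binomial_enrichment(3, 10, 1.2), "pi")
})

test_that("family enrichment reproduces observed fractions and calibrates under the null", {
  # planted: targets drawn only from clustered family genes -> tiny p
  cfg <- sim_config(seed = 5)
  sim <- simulate_dataset(cfg)
  catalog <- family_catalog(as.data.frame(sim$annotation))
  tt <- data.frame(gene_id = sim$annotation$gene_id,
                   category = ifelse(sim$annotation$gene_id %in%
                                       clustered_genes(sim$clusters),
                                     "genic", "none"))
  tt$target <- tt$category != "none"
  fe <- family_enrichment(tt, catalog, sim$annotation, sim$clusters)
  expect_equal(fe$family$fraction, 1)  # clustered genes are family members
  expect_lt(fe$family$p, 1e-6)
  expect_lt(fe$clustered$p, 1e-6)

  # null: uniformly random targets give a roughly uniform p
  set.seed(77)
  ps <- vapply(1:200, function(s) {
    ids <- sample(sim$annotation$gene_id, 80)
    t0 <- data.frame(gene_id = sim$annotation$gene_id, category = "none",
                     stringsAsFactors = FALSE)
    t0$category[t0$gene_id %in% ids] <- "genic"
    t0$target <- t0$category != "none"
    family_enrichment(t0, catalog, sim$annotation, sim$clusters)$family$p
  }, numeric(1))
  expect_gt(median(ps), 0.25)
  expect_lt(median(ps), 0.75)

  # empty target set is flagged, not an error
  t0 <- data.frame(gene_id = "gX", category = "none", target = FALSE)
  expect_true(family_enrichment(t0, catalog, sim$annotation,
                                sim$clusters)$undefined)
})

test_that("rank-sum comparison of clustered vs non-clustered binding", {
  sc <- setNames(c(1, 2, 3, 4, 5, 6), paste0("g", 1:6))
  r <- binding_level_comparison(sc, paste0("g", 4:6), paste0("g", 1:3))
  expect_equal(r$p, 0.1)  # exact two-sided rank-sum for {4,5,6} vs {1,2,3}
  expect_gt(r$clustered$median, r$nonclustered$median)

  same <- binding_level_comparison(setNames(1:20, paste0("g", 1:20)),
                                   paste0("g", seq(1, 20, 2)),
                                   paste0("g", seq(2, 20, 2)))
  expect_gt(same$p, 0.5)
  expect_error(binding_level_comparison(sc, character(0), paste0("g", 1:3)),
               "non-empty")
})

test_that("family z-score matrix standardizes each sample across families", {
  fams <- rep(sprintf("f%02d", 1:11), each = 3)
  ann <- make_family_ann(fams)
  catalog <- family_catalog(as.data.frame(ann))
  n_win <- chrom_sizes(ann)[["chr1"]] / 100

  # all scores equal -> all z-scores zero (sd via scale() is 0/0; families
  # are equal so center at 0) ... constant input is the degenerate case
  flat <- fake_pvals(list(chr1 = rep(4, n_win)))
  z0 <- family_zscore_matrix(list(s1 = flat, s2 = flat), ann, catalog)
  expect_true(all(z0 == 0))

  # one hot family among 11 -> its z exceeds 3
  s <- rep(0, n_win)
  hot <- as.data.frame(ann)[fams == "f01", ]
  for (i in seq_len(nrow(hot))) {
    idx <- (hot$start[i] %/% 100):((hot$end[i] %/% 100) + 1)
    s[idx] <- 10
  }
  z <- family_zscore_matrix(list(s1 = fake_pvals(list(chr1 = s))), ann, catalog)
  expect_gt(z["f01", "s1"], 3)
  # column standardization is exact
  expect_equal(mean(z[, "s1"]), 0, tolerance = 1e-12)
  expect_equal(sd(z[, "s1"]), 1, tolerance = 1e-12)
})

test_that("hierarchical ordering merges correlated profiles first", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1.1, 2.1, 2.9, 4.2, 5),
             c = c(5, 1, 4, 0, 2))
  rownames(m) <- paste0("f", 1:5)
  h <- hierarchical_order(m, axis = "samples")
  expect_equal(sort(h$tree$labels[-h$tree$merge[1, ]]), c("a", "b"))

  # rows 1,2 highly correlated, row 3 anti-correlated with both
  h2 <- hierarchical_order(rbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2.1, 2.9, 4),
                                 r3 = c(4, 3, 2, 1)), axis = "families")
  expect_equal(sort(h2$tree$labels[-h2$tree$merge[1, ]]), c("r1", "r2"))

  # permuting the input rows leaves the merge heights unchanged
  m3 <- matrix(rnorm(40), nrow = 8,
               dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  set.seed(1)
  perm <- sample(8)
  h3a <- hierarchical_order(m3, axis = "families")
  h3b <- hierarchical_order(m3[perm, ], axis = "families")
  expect_equal(sort(h3a$tree$height), sort(h3b$tree$height))

  # constant columns are dropped with a warning
  m4 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), k = c(2, 2, 2))
  expect_warning(h4 <- hierarchical_order(m4, axis = "samples"), "constant")
  expect_equal(h4$dropped, "k")
})
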