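test_that("config validation enforces the documented invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(block_enrichment = 1), "block_enrichment")
  expect_error(sim_config(fraction_clustered = 1.2), "fraction_clustered")
  expect_error(sim_config(background_rate = 0), "background_rate")
  expect_error(sim_config(n_genes = 10, n_families = 2, family_sizes = 8),
               "exceed")
  # genome too small for the genes
  tiny <- sim_config(n_chroms = 1, chrom_length = 20000, n_genes = 50,
                     n_families = 0)
  expect_error(generate_genome(tiny), "cannot hold")
})

test_that("genome generation places genes and plants clusters as configured", {
  # empty case
  g0 <- generate_genome(sim_config(n_genes = 0, n_families = 0))
  expect_equal(nrow(g0), 0L)
  expect_equal(length(chrom_sizes(g0)), 2L)

  # fraction_clustered = 1 with one family of 5 -> exactly one 5-gene cluster
  cfg <- sim_config(n_chroms = 1, n_genes = 30, n_families = 1,
                    family_sizes = 5, fraction_clustered = 1, seed = 42)
  ann <- generate_genome(cfg)
  cl <- detect_clusters(ann)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_genes, 5L)

  # genes are sorted and non-overlapping within chromosomes
  ann2 <- generate_genome(sim_config(seed = 6))
  for (ch in unique(ann2$chrom)) {
    g <- ann2[ann2$chrom == ch, ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }

  # determinism: same seed, byte-identical tables
  expect_identical(as.data.frame(generate_genome(sim_config(seed = 7))),
                   as.data.frame(generate_genome(sim_config(seed = 7))))
  expect_false(identical(as.data.frame(generate_genome(sim_config(seed = 7))),
                         as.data.frame(generate_genome(sim_config(seed = 8)))))
})

test_that("planted blocks span clusters with the stated flank and avoid genes", {
  cfg <- sim_config(seed = 13)
  ann <- generate_genome(cfg)

  # zero blocks requested
  none <- plant_blocks(ann, sim_config(seed = 13, n_intergenic_blocks = 0),
                       over_clusters = FALSE)
  expect_equal(nrow(none), 0L)

  truth <- plant_blocks(ann, cfg)
  cl <- detect_clusters(ann)
  cb <- truth[truth$kind == "cluster", ]
  expect_equal(nrow(cb), nrow(cl))
  # block = cluster span +/- 3 kb (away from chromosome edges)
  for (i in seq_len(nrow(cl))) {
    j <- which(cb$family_id == cl$family_id[i])
    expect_equal(cb$start[j], max(0, cl$start[i] - 3000))
    expect_equal(cb$end[j], cl$end[i] + 3000)
  }
  expect_true(all(truth$enrichment > 1))

  # intergenic blocks are >= 3 kb from every gene: brute-force distance scan
  ib <- truth[truth$kind == "intergenic", ]
  expect_equal(nrow(ib), 2L)
  genes <- as.data.frame(ann)
  for (i in seq_len(nrow(ib))) {
    g <- genes[genes$chrom == ib$chrom[i], ]
    dist <- pmax(g$start - ib$end[i], ib$start[i] - g$end, 0)
    overlapping <- g$start < ib$end[i] & ib$start[i] < g$end
    expect_false(any(overlapping))
    expect_true(all(dist >= 3000))
  }

  # intergenic block on a gene-free chromosome works the same way
  free <- generate_genome(sim_config(n_genes = 0, n_families = 0,
                                     n_chroms = 1, seed = 2))
  ib2 <- plant_blocks(free, sim_config(n_genes = 0, n_families = 0,
                                       n_chroms = 1, seed = 2,
                                       n_intergenic_blocks = 1),
                      over_clusters = FALSE)
  expect_equal(nrow(ib2), 1L)
  expect_equal(ib2$end - ib2$start, 10000)

  # requesting cluster blocks without clusters is an error
  flat <- generate_genome(sim_config(fraction_clustered = 0, seed = 1))
  expect_error(plant_blocks(flat, sim_config(fraction_clustered = 0)),
               "no cluster")
})

test_that("window counts follow the configured Poisson means", {
  # null construction: fold 1 everywhere -> chip and input means agree
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e7, n_genes = 0,
                    n_families = 0, n_intergenic_blocks = 0, seed = 3)
  ann <- generate_genome(cfg)
  truth <- plant_blocks(ann, cfg, over_clusters = FALSE)
  wc <- simulate_window_counts(ann, truth, cfg)
  n <- length(wc$chip$chr1)
  expect_equal(n, 1e5)
  se <- sqrt(2 * cfg$background_rate / n)
  expect_lt(abs(mean(wc$chip$chr1) - mean(wc$input$chr1)), 3 * se)

  # inside a fold-4 block with rate 5 the chip mean is ~20
  cfg2 <- sim_config(seed = 10)
  sim <- simulate_dataset(cfg2)
  ch <- sim$truth$chrom[1]
  tr <- sim$truth[sim$truth$chrom == ch, ]
  mids <- (seq_along(sim$counts$chip[[ch]]) - 1) * 100 + 50
  inb <- rep(FALSE, length(mids))
  for (i in seq_len(nrow(tr))) {
    inb <- inb | (mids >= tr$start[i] & mids < tr$end[i])
  }
  m <- mean(sim$counts$chip[[ch]][inb])
  expect_lt(abs(m - 20), 3 * sqrt(20 / sum(inb)))

  # depths are the configured library totals, and counts are reproducible
  expect_equal(sim$counts$chip_depth, cfg2$chip_depth)
  sim2 <- simulate_window_counts(sim$annotation, sim$truth, cfg2)
  expect_identical(sim$counts$chip, sim2$chip)
  expect_identical(sim$counts$input, sim2$input)
})

test_that("expression couples to block membership as planted", {
  # no repression -> block and non-block genes have equal mean log expression
  cfg0 <- sim_config(repression_strength = 0, seed = 15)
  sim0 <- simulate_dataset(cfg0)
  e0 <- sim0$expression
  n1 <- sum(e0$in_block); n0 <- sum(!e0$in_block)
  d0 <- mean(log(e0$control[e0$in_block])) -
    mean(log(e0$control[!e0$in_block]))
  sdn <- sqrt(cfg0$noise_sd^2 + cfg0$condition_noise_sd^2)
  expect_lt(abs(d0), 3 * sdn * sqrt(1 / n1 + 1 / n0))

  # repression 2 reproduces a ~2 log-unit deficit
  cfg2 <- sim_config(seed = 16)
  sim2 <- simulate_dataset(cfg2)
  e2 <- sim2$expression
  d2 <- mean(log(e2$control[!e2$in_block])) -
    mean(log(e2$control[e2$in_block]))
  expect_lt(abs(d2 - 2),
            3 * sdn * sqrt(1 / sum(e2$in_block) + 1 / sum(!e2$in_block)))

  # derepression lifts exactly the sampled non-clustered share in the KD
  expect_true(all(e2$derepressed ==
                    (e2$in_block & !e2$clustered & e2$derepressed)))
  lifted <- e2$kd[e2$derepressed] / e2$control[e2$derepressed]
  if (length(lifted)) expect_gt(min(lifted), 1.5)
  kept <- e2$in_block & e2$clustered
  expect_lt(mean(log(e2$kd[kept] / e2$control[kept])), 0.5)

  # same seed, same table
  expect_identical(simulate_expression(sim2$annotation, sim2$truth, cfg2),
                   sim2$expression)
})
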