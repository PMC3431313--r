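test_that("expression quantification is reads per kb per million", {
  expect_equal(unname(quantify_expression(c(g1 = 1000), c(g1 = 1000), 1e6)),
               1000)
  expect_equal(unname(quantify_expression(c(g1 = 0), c(g1 = 500), 1e6)), 0)
  v1 <- quantify_expression(c(a = 50, b = 200), c(a = 1500, b = 800), 2e6)
  v2 <- quantify_expression(c(a = 50, b = 200), c(a = 1500, b = 800), 4e6)
  expect_equal(v1, 2 * v2)  # doubling the library halves every value
  expect_error(quantify_expression(c(a = 1), c(a = 100), 0), "library_size")
  expect_error(quantify_expression(c(a = -1), c(a = 100), 1e6), "nonnegative")
})

test_that("binding-expression curve bins genes and correlates at gene level", {
  ids <- sprintf("g%04d", 1:1000)
  b <- setNames(seq(0, 5, length.out = 1000), ids)
  # expression = exp(-binding) so log1p-expression is monotone decreasing
  e <- setNames(expm1(5 - b), ids)
  bc <- binding_expression_curve(b, e, bin = 100)
  expect_equal(bc$r, -1)
  expect_equal(nrow(bc$curve), 10L)
  expect_equal(bc$curve$n, rep(100L, 10))
  # bin means match a direct group-by
  ord <- order(b, ids)
  want <- as.numeric(tapply(e[ord], rep(1:10, each = 100), mean))
  expect_equal(bc$curve$mean_expression, want)
  # final short bin: ceil(n/B) bins
  bc2 <- binding_expression_curve(b, e, bin = 300)
  expect_equal(nrow(bc2$curve), 4L)
  expect_equal(bc2$curve$n, c(300L, 300L, 300L, 100L))

  # independent binding and expression: negligible correlation
  set.seed(31)
  bn <- setNames(rnorm(1e4), sprintf("n%05d", 1:1e4))
  en <- setNames(exp(rnorm(1e4)), names(bn))
  expect_lt(abs(binding_expression_curve(bn, en)$r), 0.05)

  cb <- setNames(rep(2, 10), sprintf("c%02d", 1:10))
  ce <- setNames(exp(rnorm(10)), names(cb))
  expect_true(binding_expression_curve(cb, ce)$r_undefined)
})

test_that("planted repression yields a negative, mostly monotone curve", {
  # continuous coupling 2 with lognormal noise sd 0.5
  set.seed(9)
  ids <- sprintf("g%04d", 1:2000)
  b <- setNames(rnorm(2000), ids)
  e <- setNames(exp(4 - 2 * b + rnorm(2000, 0, 0.5)), ids)
  bc <- binding_expression_curve(b, e, bin = 200)
  expect_lt(bc$r, 0)
  expect_gte(mean(diff(bc$curve$mean_expression) <= 0), 0.8)

  # the generator's block-wise repression shows the same signal: the most
  # bound genes sit well below the least bound
  sim <- simulate_dataset(sim_config(seed = 9))
  pv <- poisson_enrichment(sim$counts)
  binding <- gene_binding_scores(pv, sim$annotation)
  ctrl <- setNames(sim$expression$control, sim$expression$gene_id)
  bcg <- binding_expression_curve(binding, ctrl, bin = 30)
  expect_lt(bcg$r, 0)
  top <- nrow(bcg$curve)
  expect_lt(bcg$curve$mean_expression[top], bcg$curve$mean_expression[1])
})

test_that("target-vs-random expression contrast calibrates and detects", {
  genes <- sprintf("g%03d", 1:300)
  set.seed(123)
  # null: targets are a random subset -> p rarely small
  ps <- vapply(1:100, function(s) {
    tt <- data.frame(gene_id = genes, category = "none",
                     stringsAsFactors = FALSE)
    tt$category[sample(300, 50)] <- "genic"
    tt$target <- tt$category != "none"
    e <- setNames(exp(rnorm(300)), genes)
    target_expression_contrast(e, tt, categories = "genic", seed = s)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)

  # planted: repressed targets sit below the random control
  tt <- data.frame(gene_id = genes, category = "none",
                   stringsAsFactors = FALSE)
  tt$category[1:50] <- "genic"
  tt$target <- tt$category != "none"
  e <- setNames(exp(rnorm(300) - 2 * (seq_along(genes) <= 50)), genes)
  res <- target_expression_contrast(e, tt, categories = "genic", seed = 1)
  expect_lt(res$median, res$random_median)
  expect_lt(res$p, 0.01)

  expect_warning(
    target_expression_contrast(e, tt, categories = "both", seed = 1),
    "empty")
})

test_that("fold-change classes follow the 1.5-fold rule and are antisymmetric", {
  ctrl <- c(a = 10, b = 16, c = 10, d = 0)
  kd <- c(a = 16, b = 10, c = 13, d = 0)
  calls <- classify_deregulated(ctrl, kd)
  expect_equal(calls$class, c("up", "down", "unchanged", "unchanged"))
  expect_equal(calls$fc[1], 16.1 / 10.1)

  # swapping conditions maps up <-> down exactly
  set.seed(4)
  c1 <- setNames(exp(rnorm(500, 2)), sprintf("g%03d", 1:500))
  c2 <- setNames(exp(rnorm(500, 2)), names(c1))
  fwd <- classify_deregulated(c1, c2)
  rev <- classify_deregulated(c2, c1)
  expect_equal(fwd$class == "up", rev$class == "down")
  expect_equal(fwd$class == "unchanged", rev$class == "unchanged")
  expect_error(classify_deregulated(c(a = -1), c(a = 1)), "nonnegative")
})

test_that("deregulation breakdown reports shares of up-regulated targets", {
  # forced construction: all block genes non-clustered and fully derepressed
  cfg <- sim_config(seed = 21, fraction_clustered = 0, derepressed_fraction = 1,
                    n_intergenic_blocks = 0, repression_strength = 2,
                    condition_noise_sd = 0)
  ann <- generate_genome(cfg)
  genes <- as.data.frame(ann)
  # hand-plant a block over three dispersed genes
  truth <- data.frame(chrom = genes$chrom[1], start = genes$start[1] - 1000,
                      end = genes$end[3] + 1000, enrichment = 4,
                      kind = "cluster", family_id = NA,
                      stringsAsFactors = FALSE)
  class(truth) <- c("block_truth", "data.frame")
  expr <- simulate_expression(ann, truth, cfg)
  expect_true(all(expr$kd[expr$in_block] / expr$control[expr$in_block] >
                    1.5))
  calls <- classify_deregulated(setNames(expr$control, expr$gene_id),
                                setNames(expr$kd, expr$gene_id))
  tt <- data.frame(gene_id = expr$gene_id,
                   category = ifelse(expr$in_block, "genic", "none"),
                   stringsAsFactors = FALSE)
  tt$target <- tt$category != "none"
  clusters <- detect_clusters(ann)
  bd <- deregulation_breakdown(calls, tt, clusters = clusters)
  expect_equal(bd$targets$percent_up, 100)
  expect_equal(bd$clustered$fraction, 1)  # non-clustered share of up targets
})
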