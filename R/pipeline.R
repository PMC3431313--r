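## End-to-end orchestration: simulate (optional) -> enrichment test ->
## peaks -> blocks -> targets -> families -> expression -> overlap, with a
## manifest that allows a bit-identical re-run.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: 100-bp
#' windows, p < 0.001 peaks, 3-kb genic flank and intergenic buffer,
#' density 1 peak/kb, 5-kb blocks, clusters of >= 3 genes, 1.5-fold
#' deregulation, 2000-gene expression bins.
#'
#' @param sim a [sim_config()] (used when no input files are given).
#' @param width window width (bp).
#' @param alpha peak p-value cutoff.
#' @param flank genic flank (bp).
#' @param buffer intergenic distance (bp).
#' @param density target-locus density threshold (peaks/kb).
#' @param block_width block profile width (bp).
#' @param min_run minimum cluster size (genes).
#' @param theta deregulation fold-change threshold.
#' @param expr_bin genes per expression bin.
#' @param n_perm exclusivity permutations.
#' @param seed seed for the pipeline's own randomness (shuffle control,
#'   random gene sets, exclusivity permutations).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), width = 100, alpha = 0.001,
                            flank = 3000, buffer = 3000, density = 1.0,
                            block_width = 5000, min_run = 3, theta = 1.5,
                            expr_bin = 2000, n_perm = 1000, seed = 1L) {
  structure(list(sim = sim, width = width, alpha = alpha, flank = flank,
                 buffer = buffer, density = density,
                 block_width = block_width, min_run = min_run, theta = theta,
                 expr_bin = expr_bin, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the block-mapping pipeline
#'
#' Simulates a dataset from `config$sim` (or uses supplied inputs), runs the
#' windowed Poisson enrichment test, calls peaks, profiles 5-kb blocks,
#' classifies target loci and genes, tests family/cluster enrichment,
#' integrates expression (binding curve, knockdown deregulation calls and
#' breakdown), and tests exclusivity of the peaks against a comparison
#' interval set (default: the complement-style check against planted
#' intergenic truth is skipped when no comparison set is given). All tables
#' are written under `out_dir` together with a JSON manifest echoing every
#' parameter and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param counts optional [window_counts()] to use instead of simulating.
#' @param annotation optional [genome_annotation()] (required with
#'   `counts`).
#' @param expression optional expression data.frame (`gene_id`, `control`,
#'   `kd`).
#' @param compare_peaks optional interval data.frame for the exclusivity
#'   test.
#' @return (invisibly) a list with every stage result and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir(),
                         counts = NULL, annotation = NULL,
                         expression = NULL, compare_peaks = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    truth <- NULL
    if (is.null(counts)) {
      sim <- simulate_dataset(config$sim)
      annotation <- sim$annotation
      counts <- sim$counts
      truth <- sim$truth
      if (is.null(expression)) expression <- sim$expression
      write_annotation(annotation, file.path(out_dir, "genes.tsv"))
      write_intervals(data.frame(chrom = truth$chrom, start = truth$start,
                                 end = truth$end, name = truth$kind,
                                 score = truth$enrichment),
                      file.path(out_dir, "truth_blocks.bed"))
      write_expression(expression[c("gene_id", "control", "kd")],
                       file.path(out_dir, "expression.tsv"))
    } else if (is.null(annotation)) {
      stop2("`annotation` is required when `counts` is supplied")
    }

    stage <- "callpeaks"
    pvals <- poisson_enrichment(counts)
    peaks <- call_peaks(pvals, alpha = config$alpha)
    write_track(score_track(pvals), file.path(out_dir, "scores.bedgraph"))
    write_intervals(peaks, file.path(out_dir, "peaks.bed"))

    stage <- "blocks"
    blocks <- block_profile(pvals, block_width = config$block_width,
                            shuffle_seed = config$seed)

    stage <- "targets"
    genic <- peak_density(genic_regions(annotation, config$flank), peaks,
                          config$density)
    intergenic <- peak_density(intergenic_regions(annotation, config$buffer),
                               peaks, config$density)
    targets <- classify_targets(annotation, genic, intergenic)
    write.table(targets, file.path(out_dir, "targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "families"
    catalog <- family_catalog(as.data.frame(annotation))
    clusters <- detect_clusters(annotation, catalog, min_run = config$min_run)
    fam <- if (length(catalog$families) >= 1L) {
      family_enrichment(targets, catalog, annotation, clusters)
    } else NULL

    stage <- "expression"
    expr_res <- NULL
    if (!is.null(expression)) {
      binding <- gene_binding_scores(pvals, annotation, config$flank)
      ctrl <- setNames(expression$control, expression$gene_id)
      kd <- setNames(expression$kd, expression$gene_id)
      curve <- binding_expression_curve(binding, ctrl, bin = config$expr_bin)
      calls <- classify_deregulated(ctrl, kd, theta = config$theta)
      breakdown <- deregulation_breakdown(calls, targets, catalog, clusters)
      write.table(calls, file.path(out_dir, "deregulation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(curve$curve, file.path(out_dir, "binding_expression.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      expr_res <- list(curve = curve, calls = calls, breakdown = breakdown)
    }

    stage <- "overlap"
    overlap <- NULL
    if (!is.null(compare_peaks)) {
      overlap <- exclusivity_test(peaks, compare_peaks,
                                  chrom_sizes(annotation),
                                  n_perm = config$n_perm, seed = config$seed)
    }

    list(annotation = annotation, truth = truth, pvals = pvals,
         peaks = peaks, blocks = blocks, genic = genic,
         intergenic = intergenic, targets = targets, clusters = clusters,
         family_enrichment = fam, expression = expr_res, overlap = overlap)
  }, error = function(e) {
    stop2("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("h1blocks")),
    parameters = config[setdiff(names(config), "sim")],
    sim = unclass(config$sim),
    n_peaks = nrow(res$peaks),
    n_targets = summarize_targets(res$targets)$n_targets,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
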