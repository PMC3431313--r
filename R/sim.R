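## Synthetic-data generator: genomes with clustered gene families, planted
## multi-kb enrichment blocks, Poisson window counts, and expression coupled
## to block membership, so every pipeline stage is testable without external
## data. Each stage draws from its own seeded stream, so changing one stage
## leaves the others bit-identical.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: a 2-Mb genome (2 chromosomes of 1 Mb), 300 genes, 10 families of
#' 12 genes with half of each family planted as a cluster, fold-4 enrichment
#' blocks over every cluster plus 2 intergenic-only blocks, an input
#' background of 5 reads per 100-bp window, and log-scale repression of 2
#' for block genes with gene-level lognormal noise (sd 0.5).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes total genes across the genome.
#' @param gene_length_mean mean gene length in bp.
#' @param n_families number of gene families.
#' @param family_sizes genes per family (scalar or vector of length
#'   `n_families`).
#' @param fraction_clustered share of each family's genes placed as one run
#'   of adjacent genes (runs shorter than 3 are left dispersed).
#' @param block_enrichment ChIP fold enrichment inside planted blocks (> 1).
#' @param background_rate expected input reads per 100-bp window.
#' @param chip_depth,input_depth library totals; their ratio scales the ChIP
#'   rate.
#' @param repression_strength log-scale expression decrease for block genes
#'   (>= 0).
#' @param derepressed_fraction share of non-clustered block genes whose
#'   repression is lifted in the knockdown condition.
#' @param noise_sd sd of the per-gene log-expression noise shared across
#'   conditions.
#' @param condition_noise_sd sd of the independent per-condition noise.
#' @param baseline_log_expr baseline natural-log expression.
#' @param n_intergenic_blocks intergenic-only blocks to plant.
#' @param intergenic_block_length their length in bp.
#' @param window_width window width in bp.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 1e6, n_genes = 300,
                       gene_length_mean = 2000, n_families = 10,
                       family_sizes = 12, fraction_clustered = 0.5,
                       block_enrichment = 4, background_rate = 5,
                       chip_depth = 1e6, input_depth = 1e6,
                       repression_strength = 2, derepressed_fraction = 0.8,
                       noise_sd = 0.5, condition_noise_sd = 0.1,
                       baseline_log_expr = log(100),
                       n_intergenic_blocks = 2,
                       intergenic_block_length = 10000,
                       window_width = 100, seed = 1L) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, gene_length_mean = gene_length_mean,
              n_families = n_families,
              family_sizes = rep_len(family_sizes, n_families),
              fraction_clustered = fraction_clustered,
              block_enrichment = block_enrichment,
              background_rate = background_rate,
              chip_depth = chip_depth, input_depth = input_depth,
              repression_strength = repression_strength,
              derepressed_fraction = derepressed_fraction,
              noise_sd = noise_sd, condition_noise_sd = condition_noise_sd,
              baseline_log_expr = baseline_log_expr,
              n_intergenic_blocks = n_intergenic_blocks,
              intergenic_block_length = intergenic_block_length,
              window_width = window_width, seed = as.integer(seed))
  for (f in c("n_chroms", "chrom_length", "gene_length_mean", "window_width")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] <= 0) {
      stop2("`%s` must be a positive count", f)
    }
  }
  for (f in c("n_genes", "n_families", "n_intergenic_blocks")) {
    if (!is_count(cfg[[f]])) stop2("`%s` must be a nonnegative count", f)
  }
  if (cfg$n_families > 0 && any(cfg$family_sizes < 0)) {
    stop2("family sizes must be nonnegative")
  }
  if (sum(cfg$family_sizes) > cfg$n_genes) {
    stop2("family sizes (%d genes) exceed n_genes (%d)",
          sum(cfg$family_sizes), cfg$n_genes)
  }
  check_proportion(cfg$fraction_clustered, "fraction_clustered")
  check_proportion(cfg$derepressed_fraction, "derepressed_fraction")
  if (cfg$block_enrichment <= 1) stop2("`block_enrichment` must exceed 1")
  if (cfg$background_rate <= 0) stop2("`background_rate` must be positive")
  if (cfg$chip_depth <= 0 || cfg$input_depth <= 0) {
    stop2("library depths must be positive")
  }
  if (cfg$repression_strength < 0) {
    stop2("`repression_strength` must be nonnegative")
  }
  class(cfg) <- "sim_config"
  cfg
}

## stage-specific derived seeds (kept well below 2^31)
stage_seed <- function(config, stage) {
  (config$seed %% 100000L) * 10L +
    match(stage, c("genome", "blocks", "counts", "expression"))
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes along each chromosome with random spacing,
#' then assigns family labels so that a `fraction_clustered` share of each
#' family's genes forms one run of adjacent genes (a planted cluster; runs
#' shorter than 3 stay dispersed) and the rest are scattered over free
#' slots.
#'
#' @param config a [sim_config()].
#' @return a [genome_annotation()] with `family_id` set (NA = no family).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- setNames(rep(config$chrom_length, config$n_chroms),
                 paste0("chr", seq_len(config$n_chroms)))
  if (config$n_genes == 0L) {
    return(genome_annotation(
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), gene_id = character(0),
                 family_id = character(0), stringsAsFactors = FALSE), cs))
  }
  per_chrom <- diff(floor(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1)))
  with_seed(stage_seed(config, "genome"), {
    min_gap <- 500
    genes <- list()
    for (ci in seq_len(config$n_chroms)) {
      n <- per_chrom[ci]
      if (n == 0L) next
      len <- pmax(200, round(stats::rgamma(n, shape = 4,
                                           rate = 4 / config$gene_length_mean)))
      slack <- config$chrom_length - sum(len) - (n + 1) * min_gap
      if (slack < 0) {
        stop2(paste0("chromosome length %s cannot hold %d genes of mean ",
                     "length %s with %s-bp minimum gaps"),
              config$chrom_length, n, config$gene_length_mean, min_gap)
      }
      cuts <- sort(runif(n))
      extra <- floor(diff(c(0, cuts, 1)) * slack)
      gaps <- min_gap + extra
      starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, head(len, -1L)))
      genes[[ci]] <- data.frame(
        chrom = names(cs)[ci], start = starts, end = starts + len,
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    genes$family_id <- NA_character_
    # family labels: planted cluster runs first, then dispersed members
    chrom_of <- genes$chrom
    free <- rep(TRUE, nrow(genes))
    fam_names <- if (config$n_families > 0)
      sprintf("fam%02d", seq_len(config$n_families)) else character(0)
    sizes <- config$family_sizes
    for (fi in seq_along(fam_names)) {
      n_cl <- round(config$fraction_clustered * sizes[fi])
      if (n_cl >= 3) {
        starts_ok <- which(vapply(seq_len(nrow(genes)), function(s) {
          idx <- s:(s + n_cl - 1L)
          max(idx) <= nrow(genes) && all(free[idx]) &&
            length(unique(chrom_of[idx])) == 1L
        }, logical(1)))
        if (!length(starts_ok)) {
          stop2("no room to plant a cluster of %d genes for %s",
                n_cl, fam_names[fi])
        }
        s <- starts_ok[sample.int(length(starts_ok), 1L)]
        idx <- s:(s + n_cl - 1L)
        genes$family_id[idx] <- fam_names[fi]
        free[idx] <- FALSE
        sizes[fi] <- sizes[fi] - n_cl
      }
    }
    for (fi in seq_along(fam_names)) {
      if (sizes[fi] == 0L) next
      slots <- which(free)
      if (length(slots) < sizes[fi]) {
        stop2("not enough free gene slots to disperse family %s", fam_names[fi])
      }
      pick <- slots[sample.int(length(slots), sizes[fi])]
      genes$family_id[pick] <- fam_names[fi]
      free[pick] <- FALSE
    }
    genome_annotation(genes, cs)
  })
}

#' Plant enrichment blocks
#'
#' One block per detected gene-family cluster, spanning the cluster's genes
#' plus `flank` bp on each side, plus `config$n_intergenic_blocks` blocks
#' placed at least `min_gene_distance` bp from every gene. Each block
#' carries the configured fold enrichment.
#'
#' @param annotation a [genome_annotation()] (typically from
#'   [generate_genome()]).
#' @param config a [sim_config()].
#' @param over_clusters plant cluster blocks (default TRUE); requesting them
#'   with no cluster present is an error.
#' @param flank cluster flank in bp (default 3000).
#' @param min_gene_distance minimum distance of intergenic blocks from any
#'   gene (default 3000).
#' @return a `block_truth` data.frame: `chrom`, `start`, `end`,
#'   `enrichment`, `kind` (cluster/intergenic), `family_id`.
#' @export
plant_blocks <- function(annotation, config, over_clusters = TRUE,
                         flank = 3000, min_gene_distance = 3000) {
  stopifnot(inherits(config, "sim_config"))
  cs <- chrom_sizes(annotation)
  rows <- list()
  if (over_clusters) {
    clusters <- detect_clusters(annotation)
    if (!nrow(clusters)) {
      stop2("blocks over clusters requested but the annotation has no cluster")
    }
    rows[[1]] <- data.frame(
      chrom = clusters$chrom,
      start = pmax(0, clusters$start - flank),
      end = pmin(unname(cs[clusters$chrom]), clusters$end + flank),
      enrichment = config$block_enrichment,
      kind = "cluster", family_id = clusters$family_id,
      stringsAsFactors = FALSE)
  }
  if (config$n_intergenic_blocks > 0) {
    genes <- as.data.frame(annotation)
    len <- config$intergenic_block_length
    cand <- list()
    for (ch in names(cs)) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      comp <- complement_intervals0(pmax(0, g$start - min_gene_distance),
                                    pmin(cs[[ch]], g$end + min_gene_distance),
                                    cs[[ch]])
      comp <- comp[comp$end - comp$start >= len, , drop = FALSE]
      if (nrow(comp)) {
        cand[[ch]] <- data.frame(chrom = ch, start = comp$start,
                                 end = comp$end, stringsAsFactors = FALSE)
      }
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) < 1L) {
      stop2("no intergenic interval of %s bp at least %s bp from any gene",
            len, min_gene_distance)
    }
    picks <- with_seed(stage_seed(config, "blocks"), {
      # sample distinct candidate regions, then a start within each
      k <- config$n_intergenic_blocks
      if (nrow(cand) < k) {
        stop2("only %d intergenic interval(s) can hold a %s-bp block; %d requested",
              nrow(cand), len, k)
      }
      sel <- sample.int(nrow(cand), k)
      starts <- cand$start[sel] +
        floor(runif(k) * (cand$end[sel] - cand$start[sel] - len + 1))
      data.frame(chrom = cand$chrom[sel], start = starts, end = starts + len,
                 enrichment = config$block_enrichment, kind = "intergenic",
                 family_id = NA_character_, stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- picks
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               enrichment = numeric(0), kind = character(0),
               family_id = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("block_truth", "data.frame")
  out
}

#' Simulate ChIP and input window counts
#'
#' Input counts are Poisson with mean `background_rate` per window; ChIP
#' counts are Poisson with mean
#' `background_rate * (chip_depth/input_depth) * fold`, where the fold is
#' the block enrichment for windows whose midpoint lies in a planted block
#' and 1 elsewhere. The returned depths are the configured library totals
#' (the simulated genome emulates an excerpt of a larger genome, so realized
#' sums over the excerpt do not define the library scaling).
#'
#' @param annotation a [genome_annotation()] (supplies chromosome sizes).
#' @param truth a `block_truth` from [plant_blocks()] (may have zero rows).
#' @param config a [sim_config()].
#' @return a [window_counts()] object.
#' @export
simulate_window_counts <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- chrom_sizes(annotation)
  w <- config$window_width
  ratio <- config$chip_depth / config$input_depth
  with_seed(stage_seed(config, "counts"), {
    chip <- list(); input <- list()
    for (ch in names(cs)) {
      n <- floor(cs[[ch]] / w)
      mids <- (seq_len(n) - 1) * w + w / 2
      fold <- rep(1, n)
      tr <- truth[truth$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(tr))) {
        fold[mids >= tr$start[i] & mids < tr$end[i]] <- tr$enrichment[i]
      }
      input[[ch]] <- rpois(n, config$background_rate)
      chip[[ch]] <- rpois(n, config$background_rate * ratio * fold)
    }
    window_counts(chip, input, width = w, chrom_sizes = cs,
                  chip_depth = config$chip_depth,
                  input_depth = config$input_depth)
  })
}

## genes whose genic region (gene +/- flank) overlaps a planted block
block_genes <- function(annotation, truth, flank = 3000) {
  genes <- as.data.frame(annotation)
  hit <- rep(FALSE, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    hit[gi] <- overlaps_any0(pmax(0, genes$start[gi] - flank),
                             genes$end[gi] + flank, tr$start, tr$end)
  }
  genes$gene_id[hit]
}

#' True target genes implied by the planted blocks
#'
#' A gene is a true target iff its genic region (gene body +/- `flank`)
#' overlaps a planted block, or it is the nearest flanking gene on either
#' side of an intergenic block. This is the ground truth against which
#' target-gene recovery is scored.
#'
#' @param annotation a [genome_annotation()].
#' @param truth a `block_truth` from [plant_blocks()].
#' @param flank genic flank in bp (default 3000).
#' @return character vector of gene ids.
#' @export
true_target_genes <- function(annotation, truth, flank = 3000) {
  genes <- as.data.frame(annotation)
  ids <- block_genes(annotation, truth, flank)
  inter <- truth[truth$kind == "intergenic", , drop = FALSE]
  for (i in seq_len(nrow(inter))) {
    g <- genes[genes$chrom == inter$chrom[i], , drop = FALSE]
    left <- g$gene_id[g$end <= inter$start[i]]
    if (length(left)) ids <- c(ids, left[length(left)])
    right <- g$gene_id[g$start >= inter$end[i]]
    if (length(right)) ids <- c(ids, right[1L])
  }
  unique(ids)
}

#' Simulate expression for control and knockdown conditions
#'
#' Control log-expression is
#' `baseline - repression_strength * in_block + gene_noise`, with in-block
#' membership from [true_target_genes()]'s genic-overlap rule. In the
#' knockdown, the repression term is removed for a `derepressed_fraction`
#' share of the non-clustered block genes and retained for clustered block
#' genes. Both conditions share the per-gene noise (lognormal across genes)
#' plus a small independent condition noise, then exponentiate.
#'
#' @param annotation a [genome_annotation()].
#' @param truth a `block_truth` from [plant_blocks()].
#' @param config a [sim_config()].
#' @return data.frame: `gene_id`, `control`, `kd`, plus bookkeeping columns
#'   `in_block`, `clustered`, `derepressed`.
#' @export
simulate_expression <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- as.data.frame(annotation)
  in_block <- genes$gene_id %in% block_genes(annotation, truth)
  clustered <- genes$gene_id %in% clustered_genes(detect_clusters(annotation))
  with_seed(stage_seed(config, "expression"), {
    n <- nrow(genes)
    gene_noise <- rnorm(n, 0, config$noise_sd)
    cand <- which(in_block & !clustered)
    n_dr <- round(config$derepressed_fraction * length(cand))
    derep <- rep(FALSE, n)
    if (n_dr > 0) derep[cand[sample.int(length(cand), n_dr)]] <- TRUE
    base <- config$baseline_log_expr + gene_noise
    log_ctrl <- base - config$repression_strength * in_block +
      rnorm(n, 0, config$condition_noise_sd)
    repressed_kd <- in_block & !derep
    log_kd <- base - config$repression_strength * repressed_kd +
      rnorm(n, 0, config$condition_noise_sd)
    data.frame(gene_id = genes$gene_id, control = exp(log_ctrl),
               kd = exp(log_kd), in_block = in_block, clustered = clustered,
               derepressed = derep, stringsAsFactors = FALSE)
  })
}

#' Run the full generator
#'
#' Convenience wrapper: genome, blocks, window counts, expression, plus the
#' derived truth (clusters and true target genes).
#'
#' @param config a [sim_config()].
#' @return list: `config`, `annotation`, `truth`, `counts`, `expression`,
#'   `clusters`, `true_targets`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  annotation <- generate_genome(config)
  truth <- plant_blocks(annotation, config)
  counts <- simulate_window_counts(annotation, truth, config)
  expression <- simulate_expression(annotation, truth, config)
  list(config = config, annotation = annotation, truth = truth,
       counts = counts, expression = expression,
       clusters = detect_clusters(annotation),
       true_targets = true_target_genes(annotation, truth))
}
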