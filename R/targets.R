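## Target classification: genic regions (gene +/- 3 kb), distal intergenic
## regions (>= 3 kb from any gene), peak density per region, and the
## four-way per-gene target category.

#' Genic regions (gene bodies extended by a flank)
#'
#' One region per gene, both genomic ends extended by `flank` bp and clipped
#' to the chromosome. Overlapping regions of neighbouring genes are kept
#' separate: target status is scored per gene.
#'
#' @param annotation a [genome_annotation()].
#' @param flank flank in bp (default 3000).
#' @return a `region_set` data.frame: `chrom`, `start`, `end`, `kind`
#'   (`"genic"`), `gene_id`.
#' @export
genic_regions <- function(annotation, flank = 3000) {
  genes <- as.data.frame(annotation)
  cs <- chrom_sizes(annotation)
  out <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, genes$start - flank),
    end = pmin(unname(cs[genes$chrom]), genes$end + flank),
    kind = rep("genic", nrow(genes)),
    gene_id = genes$gene_id,
    stringsAsFactors = FALSE)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Distal intergenic regions
#'
#' The complement of all gene bodies padded by `buffer` bp on each side, so
#' every reported interval is at least `buffer` bp away from every gene.
#' Zero-length results are dropped.
#'
#' @param annotation a [genome_annotation()].
#' @param buffer minimum distance to any gene in bp (default 3000).
#' @return a `region_set` data.frame: `chrom`, `start`, `end`, `kind`
#'   (`"intergenic"`), `gene_id` (NA).
#' @export
intergenic_regions <- function(annotation, buffer = 3000) {
  genes <- as.data.frame(annotation)
  cs <- chrom_sizes(annotation)
  rows <- lapply(names(cs), function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    comp <- complement_intervals0(pmax(0, g$start - buffer),
                                  pmin(cs[[ch]], g$end + buffer), cs[[ch]])
    comp <- comp[comp$end > comp$start, , drop = FALSE]
    if (!nrow(comp)) return(NULL)
    data.frame(chrom = ch, start = comp$start, end = comp$end,
               kind = "intergenic", gene_id = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

#' Peak density and target status of regions
#'
#' Counts the peaks whose window midpoint lies inside each region (midpoint
#' assignment guarantees each 100-bp peak is counted once even where regions
#' abut), converts to peaks per kb, and flags regions meeting the density
#' threshold as target loci.
#'
#' @param regions a `region_set` from [genic_regions()] or
#'   [intergenic_regions()].
#' @param peaks a `peak_set` from [call_peaks()].
#' @param threshold minimum peaks per kb for a target locus (default 1.0,
#'   closed: `density >= threshold`).
#' @return `regions` with `peak_count`, `density`, and logical `target`
#'   columns appended; zero-length regions are excluded with a warning.
#' @export
peak_density <- function(regions, peaks, threshold = 1.0) {
  zero <- regions$end <= regions$start
  if (any(zero)) {
    warn2("%d zero-length region(s) excluded", sum(zero))
    regions <- regions[!zero, , drop = FALSE]
  }
  mid <- (peaks$start + peaks$end) / 2
  counts <- integer(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    pm <- mid[peaks$chrom == ch]
    if (!length(pm)) next
    # midpoint containment: start <= mid < end
    ir <- as_iranges0(regions$start[ri], regions$end[ri])
    pts <- IRanges::IRanges(start = floor(pm) + 1L, width = 1L)
    counts[ri] <- IRanges::countOverlaps(ir, pts)
  }
  regions$peak_count <- counts
  regions$density <- counts / ((regions$end - regions$start) / 1000)
  regions$target <- regions$density >= threshold
  regions
}

#' Classify genes into target categories
#'
#' A gene is `"genic"` if its own genic region is a target locus,
#' `"intergenic"` if it is the nearest gene on either side of a target
#' intergenic region, `"both"` if both hold, and `"none"` otherwise.
#' Flanking genes of an intergenic region are found by position alone,
#' regardless of strand.
#'
#' @param annotation a [genome_annotation()].
#' @param genic `region_set` with densities from
#'   `peak_density(genic_regions(...), peaks)`.
#' @param intergenic `region_set` with densities from
#'   `peak_density(intergenic_regions(...), peaks)`.
#' @return a `target_table` data.frame: `gene_id`, `category`
#'   (genic/intergenic/both/none), logical `target`.
#' @export
classify_targets <- function(annotation, genic, intergenic) {
  if (is.null(genic$target) || is.null(intergenic$target)) {
    stop2("regions must carry densities; run peak_density() first")
  }
  genes <- as.data.frame(annotation)
  genic_hit <- genes$gene_id %in% genic$gene_id[genic$target]
  inter_hit <- rep(FALSE, nrow(genes))
  tgt_inter <- intergenic[intergenic$target, , drop = FALSE]
  for (ch in unique(tgt_inter$chrom)) {
    g <- which(genes$chrom == ch)
    if (!length(g)) next
    regs <- tgt_inter[tgt_inter$chrom == ch, , drop = FALSE]
    gs <- genes$start[g]; ge <- genes$end[g]
    for (i in seq_len(nrow(regs))) {
      left <- which(ge <= regs$start[i])
      if (length(left)) inter_hit[g[left[which.max(ge[left])]]] <- TRUE
      right <- which(gs >= regs$end[i])
      if (length(right)) inter_hit[g[right[which.min(gs[right])]]] <- TRUE
    }
  }
  category <- ifelse(genic_hit & inter_hit, "both",
              ifelse(genic_hit, "genic",
              ifelse(inter_hit, "intergenic", "none")))
  out <- data.frame(gene_id = genes$gene_id, category = category,
                    target = category != "none", stringsAsFactors = FALSE)
  class(out) <- c("target_table", "data.frame")
  out
}

#' Summarize a target table
#'
#' Per-category counts and their total; the three non-none categories are
#' disjoint, so the total target count is their sum.
#'
#' @param targets a `target_table` from [classify_targets()] (any data.frame
#'   with a `category` column works).
#' @return list with `counts` (named: genic, intergenic, both, none) and
#'   `n_targets` (sum of the three target categories).
#' @export
summarize_targets <- function(targets) {
  lev <- c("genic", "intergenic", "both", "none")
  counts <- table(factor(targets$category, levels = lev))
  counts <- setNames(as.integer(counts), lev)
  list(counts = counts,
       n_targets = sum(counts[c("genic", "intergenic", "both")]))
}
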