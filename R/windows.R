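## Core statistic: per-window one-sided Poisson enrichment of ChIP over
## input, peak calling at a raw p-value cutoff, 5-kb block profiling, and
## promoter bin matrices.

#' Tile a genome into fixed windows
#'
#' Windows are anchored at coordinate 0 and non-overlapping; the final
#' partial window of each chromosome is dropped so every window is exactly
#' `width` bp.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param width window width in bp (default 100).
#' @return a `window_grid`: list with `width`, `chrom_sizes`, and `n_windows`
#'   (named integer vector, `floor(length/width)` per chromosome).
#' @export
tile_windows <- function(chrom_sizes, width = 100) {
  if (!is_count(width) || width <= 0) stop2("`width` must be a positive integer")
  n <- floor(chrom_sizes / width)
  if (any(n == 0)) {
    warn2("chromosome(s) shorter than one window: %s",
          paste(names(chrom_sizes)[n == 0], collapse = ", "))
  }
  structure(list(width = width, chrom_sizes = chrom_sizes,
                 n_windows = setNames(as.integer(n), names(chrom_sizes))),
            class = "window_grid")
}

#' Bundle ChIP and input window counts
#'
#' @param chip,input `window_track`s (from [load_track()] or the simulator)
#'   on the same grid, or named lists of per-chromosome count vectors.
#' @param width window width in bp.
#' @param chrom_sizes named chromosome lengths; taken from `chip` when it is
#'   a `window_track`.
#' @param chip_depth,input_depth total library read counts used for the
#'   ChIP/input scaling factor; default is the sum of the respective counts.
#' @return a `window_counts` object.
#' @export
window_counts <- function(chip, input, width = 100, chrom_sizes = NULL,
                          chip_depth = NULL, input_depth = NULL) {
  if (inherits(chip, "window_track")) {
    chrom_sizes <- chrom_sizes %||% chip$chrom_sizes
    width <- chip$width
    chip <- chip$values
  }
  if (inherits(input, "window_track")) input <- input$values
  if (is.null(chrom_sizes)) stop2("`chrom_sizes` is required")
  if (!identical(names(chip), names(input))) {
    stop2("chip and input tracks cover different chromosomes")
  }
  for (ch in names(chip)) {
    if (length(chip[[ch]]) != length(input[[ch]])) {
      stop2("chip/input length mismatch on chromosome '%s'", ch)
    }
    if (any(chip[[ch]] < 0) || any(input[[ch]] < 0)) {
      stop2("negative counts on chromosome '%s'", ch)
    }
  }
  chip_depth <- chip_depth %||% sum(unlist(chip, use.names = FALSE))
  input_depth <- input_depth %||% sum(unlist(input, use.names = FALSE))
  if (chip_depth <= 0 || input_depth <= 0) {
    stop2("library depths must be positive (chip %s, input %s)",
          chip_depth, input_depth)
  }
  structure(list(chip = chip, input = input, width = width,
                 chrom_sizes = chrom_sizes,
                 chip_depth = chip_depth, input_depth = input_depth),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d chromosome(s), %s windows of %d bp\n",
              length(x$chip), sum(lengths(x$chip)), x$width))
  cat(sprintf("  chip depth %s, input depth %s\n", x$chip_depth, x$input_depth))
  invisible(x)
}

## One-sided upper Poisson tail P(X >= k), numerically stable and floored so
## -log10(p) stays finite. k = 0 gives exactly 1.
poisson_upper_tail <- function(k, lambda) {
  p <- ppois(k - 1, lambda, lower.tail = FALSE)
  pmin(pmax(p, 1e-300), 1)
}

#' Per-window Poisson enrichment test of ChIP over input
#'
#' For each window with ChIP count k and input count m, the expected ChIP
#' count under no enrichment is the library-size-scaled local input,
#' `lambda = m * Nc/Ni`, floored by the scaled genome-wide mean input rate
#' `lambda_min = mean(m) * Nc/Ni` so that zero-input windows cannot produce
#' spurious significance. The one-sided p-value is `P(X >= k)` for
#' `X ~ Poisson(lambda)`; the score is `-log10(p)`.
#'
#' @param counts a [window_counts()] object.
#' @return a `window_pvalues` object: per-chromosome vectors `p`, `score`,
#'   `lambda`, plus the grid metadata.
#' @export
poisson_enrichment <- function(counts) {
  stopifnot(inherits(counts, "window_counts"))
  ratio <- counts$chip_depth / counts$input_depth
  all_input <- unlist(counts$input, use.names = FALSE)
  if (length(all_input) == 0L) stop2("no windows in counts")
  mean_input <- mean(all_input)
  if (mean_input <= 0) {
    stop2("input track is all zero; supply a lambda floor by editing the input")
  }
  lambda_min <- mean_input * ratio
  p <- list(); score <- list(); lambda <- list()
  for (ch in names(counts$chip)) {
    lam <- pmax(counts$input[[ch]] * ratio, lambda_min)
    pv <- poisson_upper_tail(counts$chip[[ch]], lam)
    p[[ch]] <- pv
    score[[ch]] <- -log10(pv)
    lambda[[ch]] <- lam
  }
  structure(list(p = p, score = score, lambda = lambda,
                 width = counts$width, chrom_sizes = counts$chrom_sizes,
                 lambda_min = lambda_min),
            class = "window_pvalues")
}

#' @export
print.window_pvalues <- function(x, ...) {
  cat(sprintf("window_pvalues: %s windows of %d bp, lambda floor %.3f\n",
              sum(lengths(x$p)), x$width, x$lambda_min))
  invisible(x)
}

#' Call significant peaks
#'
#' A peak is a single window with `p < alpha` (the paper-style raw cutoff;
#' no multiple-testing correction, no merging of adjacent windows).
#'
#' @param pvals a `window_pvalues` object from [poisson_enrichment()].
#' @param alpha significance cutoff in (0, 1); default 0.001.
#' @return a `peak_set`: data.frame `chrom`, `start`, `end`, `score`
#'   (`-log10 p`) with attributes `alpha` and `width`.
#' @export
call_peaks <- function(pvals, alpha = 0.001) {
  stopifnot(inherits(pvals, "window_pvalues"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop2("`alpha` must be in (0, 1)")
  }
  out <- lapply(names(pvals$p), function(ch) {
    idx <- which(pvals$p[[ch]] < alpha)
    data.frame(chrom = rep(ch, length(idx)),
               start = (idx - 1) * pvals$width,
               end = idx * pvals$width,
               score = pvals$score[[ch]][idx],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "width") <- pvals$width
  attr(res, "chrom_sizes") <- pvals$chrom_sizes
  class(res) <- c("peak_set", "data.frame")
  res
}

#' 5-kb block significance profile
#'
#' Tiles each chromosome into non-overlapping `block_width` windows anchored
#' at 0 and averages the per-100-bp `-log10 p` scores inside each (windows
#' with no signal contribute 0). A control profile is computed after
#' shuffling the scores uniformly over grid positions within each
#' chromosome, preserving the score multiset.
#'
#' @param pvals a `window_pvalues` object.
#' @param block_width block width in bp; must be a multiple of the window
#'   width (default 5000).
#' @param shuffle_seed seed for the shuffled control.
#' @param breaks histogram break points for the average-score axis; default
#'   0 to the observed maximum in steps of 0.5.
#' @return a `block_profile` object: data.frame of block averages
#'   (`chrom`, `start`, `end`, `mean_score`, `control_mean_score`) plus
#'   histograms (`hist`, `control_hist`) over `breaks`.
#' @export
block_profile <- function(pvals, block_width = 5000, shuffle_seed = 1,
                          breaks = NULL) {
  stopifnot(inherits(pvals, "window_pvalues"))
  if (block_width %% pvals$width != 0) {
    stop2("`block_width` (%s) must be a multiple of the window width (%s)",
          block_width, pvals$width)
  }
  k <- block_width %/% pvals$width
  rows <- list()
  for (ch in names(pvals$score)) {
    s <- pvals$score[[ch]]
    n_block <- length(s) %/% k
    if (n_block == 0L) next
    use <- s[seq_len(n_block * k)]
    obs <- colMeans(matrix(use, nrow = k))
    shuf <- with_seed(shuffle_seed + match(ch, names(pvals$score)), sample(s))
    ctrl <- colMeans(matrix(shuf[seq_len(n_block * k)], nrow = k))
    rows[[ch]] <- data.frame(
      chrom = rep(ch, n_block),
      start = (seq_len(n_block) - 1) * block_width,
      end = seq_len(n_block) * block_width,
      mean_score = obs, control_mean_score = ctrl,
      stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, rows)
  rownames(blocks) <- NULL
  if (is.null(breaks)) {
    top <- max(blocks$mean_score, blocks$control_mean_score, 0.5)
    breaks <- seq(0, ceiling(top * 2) / 2, by = 0.5)
  }
  bin <- function(v) {
    h <- hist(v, breaks = breaks, plot = FALSE, right = FALSE,
              include.lowest = TRUE)
    h$counts
  }
  structure(list(blocks = blocks, breaks = breaks,
                 hist = bin(blocks$mean_score),
                 control_hist = bin(blocks$control_mean_score),
                 block_width = block_width),
            class = "block_profile")
}

#' Promoter bin matrix around TSS
#'
#' Tiles an 8-kb promoter region from `-up` to `+down` bp around each
#' annotated TSS into `(up+down)/bin` bins of `bin` bp (default 16 bins of
#' 500 bp from -5.5 kb to +2.5 kb) and averages the window scores inside
#' each. Strand-aware: for minus-strand genes the TSS is the gene end and
#' bins run toward lower coordinates, mirrored so that column 1 is always
#' the most upstream bin. Bins extending beyond the chromosome (or the
#' window grid) are NA.
#'
#' @param pvals a `window_pvalues` object.
#' @param annotation a [genome_annotation()] with strands.
#' @param up,down extent upstream/downstream of the TSS in bp.
#' @param bin bin width in bp; must divide `up + down` and be a multiple of
#'   the window width.
#' @return numeric matrix, genes x bins, rownames = gene ids.
#' @export
promoter_bin_matrix <- function(pvals, annotation, up = 5500, down = 2500,
                                bin = 500) {
  stopifnot(inherits(pvals, "window_pvalues"))
  if ((up + down) %% bin != 0) stop2("`bin` must divide up + down")
  if (bin %% pvals$width != 0) {
    stop2("`bin` must be a multiple of the window width")
  }
  n_bins <- (up + down) %/% bin
  wpb <- bin %/% pvals$width
  genes <- as.data.frame(annotation)
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins,
                dimnames = list(genes$gene_id, paste0("bin", seq_len(n_bins))))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    s <- pvals$score[[ch]]
    if (is.null(s)) next
    tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i]
    if (genes$strand[i] == "+") {
      bin_starts <- tss - up + (seq_len(n_bins) - 1) * bin
    } else {
      # most upstream bin (column 1) lies at higher coordinates
      bin_starts <- tss + up - seq_len(n_bins) * bin
    }
    for (b in seq_len(n_bins)) {
      bs <- bin_starts[b]
      if (bs < 0 || bs %% pvals$width != 0) {
        if (bs >= 0) warn2("gene '%s': TSS off the window grid; bins skipped",
                           genes$gene_id[i])
        next
      }
      idx <- bs %/% pvals$width + seq_len(wpb)
      if (max(idx) > length(s)) next
      mat[i, b] <- mean(s[idx])
    }
  }
  mat
}

#' Extract the score track of a `window_pvalues` object
#' @param pvals a `window_pvalues` object.
#' @return a `window_track` of `-log10 p` scores (writable via
#'   [write_track()]).
#' @export
score_track <- function(pvals) {
  new_track(pvals$score, pvals$width, pvals$chrom_sizes)
}

#' @importFrom graphics hist
NULL
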