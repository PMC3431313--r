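## Readers and writers for the small set of plain-text formats the pipeline
## touches. Internal coordinates are 0-based, half-open everywhere; BED and
## bedGraph are already in that convention, so conversion happens only for
## 1-based dialects (none currently shipped).

#' Construct a genome annotation
#'
#' A genome annotation is a data.frame of gene records with 0-based half-open
#' coordinates plus a named vector of chromosome sizes, the container that
#' every downstream stage (genic/intergenic regions, cluster detection,
#' promoter matrices) consumes.
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`), `gene_id`, and optionally `family_id` (NA = no family).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return A `genome_annotation`: the gene data.frame sorted by
#'   (chrom, start), with `chrom_sizes` attached as an attribute.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  stopifnot(is.data.frame(genes))
  need <- c("chrom", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop2("annotation is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop2("`chrom_sizes` must be a named vector of chromosome lengths")
  }
  if (!"family_id" %in% names(genes)) {
    genes$family_id <- rep(NA_character_, nrow(genes))
  }
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id)) {
      dup <- genes$gene_id[duplicated(genes$gene_id)][1L]
      rows <- which(genes$gene_id == dup)
      stop2("duplicate gene_id '%s' at rows %s", dup,
            paste(rows, collapse = " and "))
    }
    bad_chrom <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(bad_chrom)) {
      stop2("genes on chromosomes absent from chrom_sizes: %s",
            paste(bad_chrom, collapse = ", "))
    }
    if (any(genes$start < 0) || any(genes$start >= genes$end)) {
      bad <- which(genes$start < 0 | genes$start >= genes$end)[1L]
      stop2("invalid gene coordinates at row %d: start=%s end=%s",
            bad, genes$start[bad], genes$end[bad])
    }
    over <- genes$end > chrom_sizes[genes$chrom]
    if (any(over)) {
      bad <- which(over)[1L]
      stop2("gene '%s' (row %d) ends at %s beyond chromosome '%s' length %s",
            genes$gene_id[bad], bad, genes$end[bad], genes$chrom[bad],
            chrom_sizes[genes$chrom[bad]])
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      stop2("strand must be '+' or '-'")
    }
    genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  attr(genes, "chrom_sizes") <- chrom_sizes
  class(genes) <- c("genome_annotation", "data.frame")
  genes
}

#' Chromosome sizes of an annotation or track
#' @param x a `genome_annotation` or windowed-track object.
#' @return named numeric vector of chromosome lengths (bp).
#' @export
chrom_sizes <- function(x) {
  cs <- attr(x, "chrom_sizes", exact = TRUE) %||% x$chrom_sizes
  if (is.null(cs)) stop2("object carries no chromosome sizes")
  cs
}

#' Load a gene annotation from TSV or BED
#'
#' The TSV dialect has a header line with columns
#' `chrom, start, end, strand, gene_id[, family_id]` in 0-based half-open
#' coordinates. BED (6 columns) uses `name` as the gene id. Gzipped files are
#' read transparently.
#'
#' @param path file path.
#' @param chrom_sizes named vector of chromosome lengths; required so
#'   coordinates can be validated.
#' @param format `"tsv"` or `"bed"`; default guesses from the extension.
#' @return a [genome_annotation()].
#' @export
load_annotation <- function(path, chrom_sizes,
                            format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "tsv"
  }
  if (!file.exists(path)) stop2("annotation file not found: %s", path)
  if (format == "tsv") {
    df <- tryCatch(
      read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                 quote = "", comment.char = ""),
      error = function(e) stop2("malformed annotation TSV '%s': %s",
                                path, conditionMessage(e)))
    genes <- df
  } else {
    df <- tryCatch(
      read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                 quote = "", comment.char = "#"),
      error = function(e) stop2("malformed BED file '%s': %s",
                                path, conditionMessage(e)))
    if (ncol(df) < 6L) stop2("BED annotation needs 6 columns, got %d", ncol(df))
    genes <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                        strand = df[[6]], gene_id = df[[4]],
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1L]
    lines <- which(genes$gene_id == dup) + (format == "tsv")  # header offset
    stop2("duplicate gene_id '%s' in %s at lines %s", dup, path,
          paste(lines, collapse = " and "))
  }
  known <- intersect(unique(genes$chrom), names(chrom_sizes))
  if (nrow(genes) && !length(known)) {
    warn2("no chromosome of '%s' matches chrom_sizes names (chr-prefix mismatch?)",
          path)
  }
  genome_annotation(genes, chrom_sizes)
}

#' Write a gene annotation as TSV
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df$start <- fmt_coord(df$start); df$end <- fmt_coord(df$end)
  write.table(df[c("chrom", "start", "end", "strand", "gene_id", "family_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## A count/score track: named list of per-chromosome numeric vectors, one
## entry per 100-bp window, plus the grid metadata.
new_track <- function(values, width, chrom_sizes) {
  structure(list(values = values, width = width, chrom_sizes = chrom_sizes),
            class = "window_track")
}

#' Load a windowed count or score track from bedGraph/TSV
#'
#' Each row covers one or more whole grid windows (`start` and `end` must be
#' multiples of `width`); a row spanning k windows assigns its value to each.
#' Windows not covered by any row are zero. The final partial window of each
#' chromosome is not part of the grid.
#'
#' @param path bedGraph (or equivalent 4-column TSV) path; gz transparent.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param width window width in bp (default 100).
#' @return a `window_track`: per-chromosome value vectors of length
#'   `floor(length/width)`.
#' @export
load_track <- function(path, chrom_sizes, width = 100) {
  if (!file.exists(path)) stop2("track file not found: %s", path)
  n_win <- floor(chrom_sizes / width)
  values <- lapply(n_win, function(n) numeric(n))
  names(values) <- names(chrom_sizes)
  info <- file.info(path)
  raw <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               comment.char = "#", quote = ""),
    error = function(e) {
      if (info$size == 0 || length(readLines(path, n = 1L)) == 0L) NULL
      else stop2("malformed track file '%s': %s", path, conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    warn2("track file '%s' is empty; returning zero-filled track", path)
    return(new_track(values, width, chrom_sizes))
  }
  if (ncol(raw) < 4L) stop2("track '%s' needs 4 columns, got %d", path, ncol(raw))
  chrom <- raw[[1]]; start <- raw[[2]]; end <- raw[[3]]; val <- raw[[4]]
  bad <- which(start %% width != 0 | end %% width != 0 | end <= start)
  if (length(bad)) {
    stop2("track '%s' line %d: interval [%s,%s) not aligned to the %d-bp grid",
          path, bad[1L], start[bad[1L]], end[bad[1L]], width)
  }
  if (any(val < 0)) {
    stop2("track '%s' line %d: negative value %s", path,
          which(val < 0)[1L], val[which(val < 0)[1L]])
  }
  unknown <- setdiff(unique(chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop2("track '%s' refers to unknown chromosomes: %s", path,
          paste(unknown, collapse = ", "))
  }
  for (i in seq_along(chrom)) {
    idx <- seq.int(start[i] %/% width + 1L, end[i] %/% width)
    if (max(idx) > length(values[[chrom[i]]])) {
      stop2("track '%s' line %d: interval beyond chromosome '%s' grid",
            path, i, chrom[i])
    }
    values[[chrom[i]]][idx] <- val[i]
  }
  new_track(values, width, chrom_sizes)
}

#' Write a windowed track as bedGraph
#'
#' Adjacent windows with equal values are merged into runs; zero-valued runs
#' are written too, so `load_track(write_track(x))` is the identity on the
#' grid.
#'
#' @param track a `window_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths) * track$width
    starts <- c(0, head(ends, -1L))
    writeLines(paste(chrom, fmt_coord(starts), fmt_coord(ends),
                     format(r$values, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write an interval set as BED or bedGraph
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name` and
#'   `score` columns (0-based half-open).
#' @param path output path.
#' @param format `"bed"` (chrom start end name score) or `"bedgraph"`
#'   (chrom start end score).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  if (nrow(x) && any(x$start >= x$end)) stop2("invalid interval: start >= end")
  if (!is.null(x$score) && anyNA(x$score)) stop2("NA scores are not allowed")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x)) {
    score <- x$score %||% rep(0, nrow(x))
    if (format == "bed") {
      name <- x$name %||% paste0("iv", seq_len(nrow(x)))
      writeLines(paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end), name,
                       format(score, scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
    } else {
      writeLines(paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end),
                       format(score, scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Load an interval set from BED or bedGraph
#'
#' @param path file path (gz transparent).
#' @param format `"bed"` or `"bedgraph"`; default guesses from the extension.
#' @return data.frame with `chrom`, `start`, `end`, `name` (BED only),
#'   `score`, sorted by (chrom, start). Empty files yield zero rows.
#' @export
load_intervals <- function(path, format = c("auto", "bed", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bdg)(\\.gz)?$", path)) "bedgraph" else "bed"
  }
  if (!file.exists(path)) stop2("interval file not found: %s", path)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first)) return(empty)
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  if (format == "bed") {
    out$name <- if (ncol(df) >= 4L) as.character(df[[4]]) else
      paste0("iv", seq_len(nrow(df)))
    out$score <- if (ncol(df) >= 5L) df[[5]] else 0
  } else {
    out$name <- paste0("iv", seq_len(nrow(df)))
    out$score <- if (ncol(df) >= 4L) df[[4]] else 0
  }
  bad <- which(out$start < 0 | out$start >= out$end)
  if (length(bad)) {
    stop2("interval file '%s' line %d: invalid interval [%s,%s)",
          path, bad[1L], out$start[bad[1L]], out$end[bad[1L]])
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an expression table as TSV
#' @param expr data.frame with `gene_id` and one column per condition.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an expression table from TSV
#' @param path TSV with header `gene_id` plus condition columns.
#' @return data.frame.
#' @export
load_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop2("expression table needs a gene_id column")
  if (any(vapply(df[setdiff(names(df), "gene_id")],
                 function(v) any(v < 0), logical(1)))) {
    stop2("negative expression values in %s", path)
  }
  df
}
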