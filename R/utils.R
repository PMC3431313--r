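`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats ppois pbinom rpois rnorm runif cor hclust as.dist
#'   wilcox.test p.adjust quantile median sd setNames
#' @importFrom utils read.table write.table head
NULL

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

warn2 <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop2("`%s` must be a single value in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

## Local RNG scope: run `expr` under `seed` without disturbing the caller's
## RNG state. Each generator stage derives its own stream this way.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Interval helpers ---------------------------------------------------------
## Internal convention everywhere: 0-based, half-open [start, end).

as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

## Reduce a set of 0-based half-open intervals to a disjoint sorted union,
## returned as a data.frame(start, end).
reduce_intervals0 <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- IRanges::reduce(as_iranges0(start, end))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

## Complement of a union of 0-based intervals within [0, chrom_length).
complement_intervals0 <- function(start, end, chrom_length) {
  if (length(start) == 0L) {
    return(data.frame(start = 0, end = chrom_length))
  }
  g <- IRanges::gaps(IRanges::reduce(as_iranges0(start, end)),
                     start = 1L, end = as.integer(chrom_length))
  data.frame(start = IRanges::start(g) - 1L, end = IRanges::end(g))
}

## Any-overlap indicator of query intervals against a subject set (both
## 0-based half-open, same chromosome).
overlaps_any0 <- function(q_start, q_end, s_start, s_end) {
  if (length(q_start) == 0L) return(logical(0))
  if (length(s_start) == 0L) return(rep(FALSE, length(q_start)))
  IRanges::overlapsAny(as_iranges0(q_start, q_end),
                       as_iranges0(s_start, s_end))
}

## Format coordinates without scientific notation for file output.
fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
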