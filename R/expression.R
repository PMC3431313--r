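## Binding-expression integration: RPKM-style quantification, binned
## binding-vs-expression curves, target-vs-random contrasts, 1.5-fold
## knockdown deregulation calls and their family/cluster breakdown.

#' Quantify per-gene expression (reads per kb per million)
#'
#' `value = count / (length/1000) / (library_size/1e6)`.
#'
#' @param counts named numeric vector of per-gene read counts.
#' @param lengths named numeric vector of gene lengths in bp (> 0).
#' @param library_size total mapped reads (> 0); default `sum(counts)`.
#' @return named numeric vector of expression values.
#' @export
quantify_expression <- function(counts, lengths, library_size = sum(counts)) {
  if (any(counts < 0)) stop2("read counts must be nonnegative")
  if (any(lengths <= 0)) stop2("gene lengths must be positive")
  if (length(library_size) != 1L || library_size <= 0) {
    stop2("`library_size` must be a single positive number")
  }
  lengths <- lengths[names(counts)]
  counts / (lengths / 1000) / (library_size / 1e6)
}

#' Binding-expression curve over gene bins
#'
#' Sorts genes by binding score (ascending, ties broken by gene id), splits
#' them into consecutive bins of `bin` genes (the last bin may be smaller),
#' and reports the mean expression per bin together with the gene-level
#' Pearson correlation between binding and (by default) `log1p` expression.
#'
#' @param binding named numeric vector of per-gene binding scores.
#' @param expression named numeric vector of per-gene expression.
#' @param bin genes per bin (default 2000).
#' @param transform `"log1p"` (default) or `"none"` applied to expression
#'   before the correlation.
#' @param level `"gene"` (default) computes r across genes; `"bin"` across
#'   bin means.
#' @return list with `curve` (data.frame: bin, n, mean_binding,
#'   mean_expression), `r`, and `r_undefined` (TRUE when binding is
#'   constant).
#' @export
binding_expression_curve <- function(binding, expression, bin = 2000,
                                     transform = c("log1p", "none"),
                                     level = c("gene", "bin")) {
  transform <- match.arg(transform)
  level <- match.arg(level)
  ids <- intersect(names(binding), names(expression))
  ids <- ids[!is.na(binding[ids]) & !is.na(expression[ids])]
  if (length(ids) < 2L) stop2("need at least 2 genes with both values")
  b <- binding[ids]; e <- expression[ids]
  ord <- order(b, ids)
  b <- b[ord]; e <- e[ord]
  grp <- ceiling(seq_along(b) / bin)
  curve <- data.frame(
    bin = seq_len(max(grp)),
    n = as.integer(table(grp)),
    mean_binding = as.numeric(tapply(b, grp, mean)),
    mean_expression = as.numeric(tapply(e, grp, mean)))
  et <- if (transform == "log1p") log1p(e) else e
  r_undefined <- sd(b) == 0
  r <- if (r_undefined) NA_real_ else if (level == "gene") {
    if (sd(et) == 0) NA_real_ else cor(b, et)
  } else {
    cm <- if (transform == "log1p") log1p(curve$mean_expression) else
      curve$mean_expression
    if (nrow(curve) < 3L || sd(cm) == 0) NA_real_ else
      cor(curve$mean_binding, cm)
  }
  list(curve = curve, r = r, r_undefined = r_undefined)
}

#' Expression of target categories versus random genes
#'
#' For each target category, compares expression against a size-matched
#' random gene set drawn (seeded) from the full gene universe, by a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param expression named numeric vector of per-gene expression.
#' @param targets a `target_table` from [classify_targets()].
#' @param categories categories to test (default genic, intergenic, both).
#' @param seed seed for the random control draw.
#' @return data.frame: category, n, mean, median, random_mean,
#'   random_median, p. Empty categories are skipped with a warning.
#' @export
target_expression_contrast <- function(expression, targets,
                                       categories = c("genic", "intergenic",
                                                      "both"),
                                       seed = 1) {
  universe <- intersect(targets$gene_id, names(expression))
  rows <- list()
  for (ct in categories) {
    ids <- intersect(targets$gene_id[targets$category == ct], universe)
    if (!length(ids)) {
      warn2("category '%s' is empty; skipped", ct)
      next
    }
    ctrl <- with_seed(seed + match(ct, categories),
                      sample(universe, length(ids)))
    a <- expression[ids]; b <- expression[ctrl]
    p <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = FALSE)$p.value)
    rows[[ct]] <- data.frame(category = ct, n = length(ids),
                             mean = mean(a), median = median(a),
                             random_mean = mean(b), random_median = median(b),
                             p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify knockdown deregulation by fold change
#'
#' Fold change is computed on pseudocounted values,
#' `fc = (kd + c) / (control + c)`; genes with `fc >= theta` are `"up"`,
#' `fc <= 1/theta` are `"down"`, the rest `"unchanged"`.
#'
#' @param control,kd named numeric vectors of nonnegative expression values
#'   over the same gene universe.
#' @param theta fold-change threshold (default 1.5).
#' @param pseudocount added to both conditions (default 0.1).
#' @return a `deregulation_calls` data.frame: `gene_id`, `control`, `kd`,
#'   `fc`, `class`.
#' @export
classify_deregulated <- function(control, kd, theta = 1.5, pseudocount = 0.1) {
  ids <- intersect(names(control), names(kd))
  if (!length(ids)) stop2("control and kd share no genes")
  control <- control[ids]; kd <- kd[ids]
  if (any(control < 0) || any(kd < 0)) stop2("expression must be nonnegative")
  if (theta <= 1) stop2("`theta` must exceed 1")
  fc <- (kd + pseudocount) / (control + pseudocount)
  cls <- ifelse(fc >= theta, "up", ifelse(fc <= 1 / theta, "down", "unchanged"))
  out <- data.frame(gene_id = ids, control = unname(control),
                    kd = unname(kd), fc = unname(fc), class = unname(cls),
                    stringsAsFactors = FALSE)
  class(out) <- c("deregulation_calls", "data.frame")
  out
}

#' Breakdown of deregulated genes by target status, family and cluster
#'
#' Reports the up-regulated share among all deregulated genes and among
#' deregulated target genes, and the family / clustered composition of
#' up-regulated targets with a binomial p-value against the composition of
#' all targets.
#'
#' @param calls a `deregulation_calls` data.frame.
#' @param targets a `target_table` from [classify_targets()].
#' @param catalog optional [family_catalog()] for the family split.
#' @param clusters optional `cluster_set` for the clustered split.
#' @return list with `all` and `targets` up/total summaries (each with
#'   `up`, `total`, `percent_up`) plus optional `family` and `clustered`
#'   composition reports. Zero deregulated targets yield an `empty = TRUE`
#'   flag.
#' @export
deregulation_breakdown <- function(calls, targets, catalog = NULL,
                                   clusters = NULL) {
  dereg <- calls[calls$class != "unchanged", , drop = FALSE]
  up_share <- function(df) {
    total <- nrow(df); up <- sum(df$class == "up")
    list(up = up, total = total,
         percent_up = if (total > 0) round(100 * up / total) else NA_integer_)
  }
  tgt_ids <- targets$gene_id[targets$target]
  dereg_tgt <- dereg[dereg$gene_id %in% tgt_ids, , drop = FALSE]
  out <- list(all = up_share(dereg), targets = up_share(dereg_tgt),
              empty = nrow(dereg_tgt) == 0L)
  up_tgt <- dereg_tgt$gene_id[dereg_tgt$class == "up"]
  if (!is.null(catalog) && nrow(dereg_tgt)) {
    fam_all <- !is.na(family_of(catalog, tgt_ids))
    fam_up <- !is.na(family_of(catalog, up_tgt))
    out$family <- enrichment_report(sum(!fam_up), length(fam_up),
                                    max(1e-12, min(1 - 1e-12, mean(!fam_all))))
    names(out$family)[1:2] <- c("k", "n")
    out$family$what <- "non-family among up-regulated targets"
  }
  if (!is.null(clusters) && nrow(dereg_tgt)) {
    cl <- clustered_genes(clusters)
    cl_all <- tgt_ids %in% cl
    cl_up <- up_tgt %in% cl
    out$clustered <- enrichment_report(sum(!cl_up), length(cl_up),
                                       max(1e-12, min(1 - 1e-12, mean(!cl_all))))
    out$clustered$what <- "non-clustered among up-regulated targets"
  }
  out
}
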