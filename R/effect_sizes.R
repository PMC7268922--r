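# Per-(gene, study) effect sizes: log2 fold change, Welch-type standard
# error, z-score; QQ diagnostics of the z-score distribution.

row_stats <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  s2 <- if (n > 1L) rowSums((m - mu)^2) / (n - 1L) else rep(0, nrow(m))
  list(mean = mu, var = s2, n = n)
}

# Effect records for every gene of `genes` measured in `study`.
study_effects <- function(study, genes, se_floor = 1e-6) {
  stopifnot(inherits(study, "expression_study"))
  present <- intersect(genes, study$gene_ids)
  if (!length(present)) {
    return(data.frame(gene = character(), study_id = character(),
                      y = numeric(), se = numeric(), z = numeric(),
                      n_case = integer(), n_control = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- study$matrix[present, , drop = FALSE]
  case <- row_stats(m[, study$sample_groups == "case", drop = FALSE])
  ctrl <- row_stats(m[, study$sample_groups == "control", drop = FALSE])
  y <- case$mean - ctrl$mean
  se <- pmax(sqrt(case$var / case$n + ctrl$var / ctrl$n), se_floor)
  data.frame(gene = present, study_id = study$study_id,
             y = unname(y), se = unname(se), z = unname(y / se),
             n_case = study$n_case, n_control = study$n_control,
             stringsAsFactors = FALSE)
}

#' Effect size of one gene in one study
#'
#' The effect-size index is the log2 fold change
#' `y = mean(log2 expr, case) - mean(log2 expr, control)`, with a
#' Welch-type standard error `se = sqrt(s2_case/n_case + s2_ctrl/n_ctrl)`
#' (unbiased per-arm sample variances) and `z = y / se`. A floor of
#' `se_floor` keeps weights finite for degenerate zero-variance arms.
#'
#' @param study A preprocessed [expression_study].
#' @param gene Gene symbol.
#' @param se_floor Lower bound on the standard error (log2 scale).
#' @return One-row data frame (gene, study_id, y, se, z, n_case,
#'   n_control), or `NULL` if the gene is not measured in the study.
#' @export
effect_for_gene <- function(study, gene, se_floor = 1e-6) {
  rec <- study_effects(study, gene, se_floor)
  if (!nrow(rec)) return(NULL)
  rec
}

#' Effect-size table across a study collection
#'
#' One record per (gene, study) pair in which the gene is measured;
#' unmeasured pairs simply contribute no row, so a gene's number of
#' studies `k` can vary. Rows are ordered by gene, then by the order of
#' `studies`.
#'
#' @param studies List of preprocessed [expression_study] objects.
#' @param genes Character vector of gene symbols (defaults to the union of
#'   genes measured anywhere).
#' @param se_floor Standard-error floor, see [effect_for_gene()].
#' @return Data frame of effect records.
#' @export
effects_table <- function(studies, genes = NULL, se_floor = 1e-6) {
  if (!length(studies)) stop("at least one study required")
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(studies, `[[`, "gene_ids"))))
  if (!length(genes)) stop("empty gene list")
  genes <- unique(toupper(genes))
  parts <- lapply(seq_along(studies), function(i) {
    rec <- study_effects(studies[[i]], genes, se_floor)
    rec$.study_order <- i
    rec
  })
  out <- do.call(rbind, parts)
  out <- out[order(match(out$gene, genes), out$.study_order), ]
  out$.study_order <- NULL
  rownames(out) <- NULL
  out
}

#' Write an effects table to TSV
#' @param effects Data frame from [effects_table()].
#' @param path Output path.
#' @export
write_effects <- function(effects, path) {
  write.table(effects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' QQ points of per-gene z-scores against the standard normal
#'
#' Sorts the observed z-scores ascending and pairs them with standard
#' normal quantiles at plotting positions `(i - 0.5) / m`. Plotting is
#' left to the caller; the returned table is the diagnostic.
#'
#' @param x A preprocessed [expression_study] (z-scores are computed for
#'   all of its genes) or a numeric vector of z-scores.
#' @param se_floor Standard-error floor used when computing z from a
#'   study.
#' @return Data frame with columns `theoretical` and `observed`.
#' @export
qq_points <- function(x, se_floor = 1e-6) {
  z <- if (inherits(x, "expression_study"))
    study_effects(x, x$gene_ids, se_floor)$z
  else as.numeric(x)
  z <- z[is.finite(z)]
  m <- length(z)
  if (m < 2L) stop("need at least two z-scores")
  data.frame(theoretical = qnorm((seq_len(m) - 0.5) / m),
             observed = sort(z))
}
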