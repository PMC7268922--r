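# Cross-study pooling of per-gene effects: inverse-variance fixed-effect
# model, DerSimonian-Laird random-effect model, Cochran Q / I-squared
# heterogeneity with the truncation-driven model-selection rule, the
# top-50% partial analysis, and the asymmetric fold-change significance
# filter.

CI_Z <- qnorm(0.975)  # 1.959964..., the 95% normal multiplier

check_effects <- function(effects, min_k = 1L) {
  if (is.null(effects) || !nrow(effects)) stop("empty effects set")
  stopifnot(all(c("y", "se") %in% names(effects)))
  if (any(!is.finite(effects$y)) || any(!is.finite(effects$se)))
    stop("non-finite effect or standard error")
  if (any(effects$se <= 0)) stop("all standard errors must be > 0")
  if (nrow(effects) < min_k)
    stop("need at least ", min_k, " studies for this model")
  invisible(effects)
}

new_mega_result <- function(effects, model, pooled, se_pooled, het,
                            weights, tau2, analysis = "full") {
  z <- pooled / se_pooled
  structure(list(
    gene = if ("gene" %in% names(effects)) effects$gene[1L] else NA_character_,
    analysis = analysis,
    model = model,
    k = nrow(effects),
    pooled_lfc = pooled,
    se_pooled = se_pooled,
    ci_low = pooled - CI_Z * se_pooled,
    ci_high = pooled + CI_Z * se_pooled,
    p = 2 * pnorm(-abs(z)),
    Q = het$Q,
    df = het$df,
    isq = het$isq,
    p_q = het$p_q,
    tau2 = tau2,
    weights = weights,
    effects = effects
  ), class = "mega_result")
}

# Heterogeneity is always a property of the full study set under
# fixed-effect weights: Q, df = k - 1, isq truncated at 0, and the
# chi-square upper-tail probability of Q (1 when k = 1).
heterogeneity <- function(y, w, pooled) {
  k <- length(y)
  Q <- sum(w * (y - pooled)^2)
  df <- k - 1L
  isq <- if (Q <= df || Q <= 0) 0 else 100 * (Q - df) / Q
  p_q <- if (df == 0L) 1 else pchisq(Q, df, lower.tail = FALSE)
  list(Q = Q, df = df, isq = isq, p_q = p_q)
}

#' Fixed-effect pooling of per-study effects
#'
#' Standard inverse-variance pooling: weights `w_i = 1/se_i^2`, pooled
#' effect `sum(w y)/sum(w)`, `se_pooled = 1/sqrt(sum(w))`, 95% normal CI,
#' two-sided normal p-value for pooled effect = 0, plus Cochran's
#' `Q = sum(w (y - pooled)^2)` with `df = k - 1`, the truncated
#' heterogeneity percentage `isq = max(0, 100 (Q - df)/Q)` and the
#' chi-square upper-tail probability `p_q` that within-study variance
#' alone explains Q.
#'
#' @param effects Data frame of effect records with columns `y`, `se`
#'   (and optionally `gene`, `study_id`).
#' @return A `mega_result` (see [mega()]).
#' @export
fixed_effect <- function(effects) {
  check_effects(effects, 1L)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$y) / sum(w)
  het <- heterogeneity(effects$y, w, pooled)
  weights <- w / sum(w)
  if ("study_id" %in% names(effects)) names(weights) <- effects$study_id
  new_mega_result(effects, "fixed", pooled, 1 / sqrt(sum(w)), het,
                  weights, tau2 = 0)
}

#' Random-effect (DerSimonian-Laird) pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df)/C)` with `C = sum(w) - sum(w^2)/sum(w)`
#' computed from the fixed-effect weights; the pooled effect, CI and
#' p-value then use `w*_i = 1/(se_i^2 + tau2)`. The heterogeneity block
#' (`Q`, `df`, `isq`, `p_q`) is reported from the fixed-effect weights:
#' it describes the collection, not the chosen model.
#'
#' @inheritParams fixed_effect
#' @return A `mega_result` with `model = "random"` and the `tau2`
#'   estimate.
#' @export
random_effect <- function(effects) {
  check_effects(effects, 2L)
  w <- 1 / effects$se^2
  pooled_fe <- sum(w * effects$y) / sum(w)
  het <- heterogeneity(effects$y, w, pooled_fe)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$Q - het$df) / C)
  ws <- 1 / (effects$se^2 + tau2)
  pooled <- sum(ws * effects$y) / sum(ws)
  weights <- ws / sum(ws)
  if ("study_id" %in% names(effects)) names(weights) <- effects$study_id
  new_mega_result(effects, "random", pooled, 1 / sqrt(sum(ws)), het,
                  weights, tau2 = tau2)
}

#' Pool one gene's effects with heterogeneity-driven model selection
#'
#' In `"auto"` mode the fixed-effect heterogeneity is computed first; if
#' the truncated `isq` is 0 (i.e. `Q <= df`, no excess between-study
#' variance) the fixed-effect result is returned, otherwise the
#' DerSimonian-Laird random-effect result. `"fixed"` and `"random"` force
#' the respective model.
#'
#' @inheritParams fixed_effect
#' @param mode `"auto"`, `"fixed"` or `"random"`.
#' @return A `mega_result`: list with fields `gene`, `analysis`
#'   (`"full"`/`"partial"`), `model`, `k`, `pooled_lfc`, `se_pooled`,
#'   `ci_low`, `ci_high`, `p`, `Q`, `df`, `isq`, `p_q`, `tau2`,
#'   `weights` (normalized, summing to 1) and the `effects` pooled.
#' @export
mega <- function(effects, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  switch(mode,
    fixed = fixed_effect(effects),
    random = random_effect(effects),
    auto = {
      fe <- fixed_effect(effects)
      if (fe$isq == 0) fe else random_effect(effects)
    })
}

#' Select the top 50% of studies for a gene
#'
#' Keeps the `floor(k/2)` records with the largest absolute effect size
#' (at least one record when `k = 1`): a gene measured in 9 studies pools
#' 4, in 8 studies also 4. Ties on `|y|` are broken by smaller `se`, then
#' by `study_id` lexicographic order, so the selected set is invariant to
#' the input row order.
#'
#' @inheritParams fixed_effect
#' @return The selected subset of `effects`.
#' @export
partial_select <- function(effects) {
  check_effects(effects, 1L)
  k <- nrow(effects)
  n_keep <- max(1L, k %/% 2L)
  sid <- if ("study_id" %in% names(effects)) effects$study_id
         else as.character(seq_len(k))
  ord <- order(-abs(effects$y), effects$se, sid)
  out <- effects[ord[seq_len(n_keep)], , drop = FALSE]
  out[order(match(out$study_id %||% rownames(out), sid)), , drop = FALSE]
}

#' Partial mega-analysis of one gene
#'
#' Pools only the per-gene top 50% of datasets (ranked by absolute effect
#' size, [partial_select()]), a sensitivity analysis that surfaces genes
#' altered in some but not all studies.
#'
#' @inheritParams mega
#' @return A `mega_result` with `analysis = "partial"`.
#' @export
partial_mega <- function(effects, mode = c("auto", "fixed", "random")) {
  res <- mega(partial_select(effects), mode)
  res$analysis <- "partial"
  res
}

#' Asymmetric fold-change significance filter
#'
#' A pooled result is significant iff `p < alpha` and the pooled log2
#' fold change is strictly above `up` or strictly below `down`. The
#' default bounds 0.49 / -0.74 correspond to an expression increase or
#' decrease of more than 40% (log2(1.4) ~ 0.49, log2(0.6) ~ -0.74);
#' boundary values do not pass. No multiple-testing correction is applied
#' at this stage: the filter operates on raw pooled p-values against a
#' stringent `alpha`.
#'
#' @param result A `mega_result`, or a numeric pooled LFC (with `p`
#'   supplied).
#' @param alpha Raw p-value threshold.
#' @param up,down Log2 fold-change bounds; `up > 0 > down`.
#' @param p P-value(s) when `result` is numeric.
#' @return Logical.
#' @export
significance_filter <- function(result, alpha = 1e-7, up = 0.49,
                                down = -0.74, p = NULL) {
  stopifnot(is.finite(alpha), is.finite(up), is.finite(down), up > 0,
            down < 0)
  if (inherits(result, "mega_result")) {
    lfc <- result$pooled_lfc
    p <- result$p
  } else {
    lfc <- as.numeric(result)
    if (is.null(p)) stop("supply p-values alongside numeric effect sizes")
  }
  p < alpha & (lfc > up | lfc < down)
}

#' @export
print.mega_result <- function(x, ...) {
  cat(sprintf(
    "<mega_result> %s [%s %s-effect] k=%d LFC=%.3f (95%% CI %.3f..%.3f) p=%.3g\n  Q=%.3f df=%d ISq=%.2f%% p-Q=%.3g tau2=%.4f\n",
    x$gene, x$analysis, x$model, x$k, x$pooled_lfc, x$ci_low, x$ci_high,
    x$p, x$Q, x$df, x$isq, x$p_q, x$tau2))
  invisible(x)
}

#' Full + partial mega-analysis over all genes of an effects table
#'
#' Runs, per gene, the full mega-analysis and the partial (top 50%)
#' mega-analysis, and reports both as rows of one table mirroring the
#' usual per-gene report: analysis type, significance call, model chosen,
#' number of studies pooled, pooled LFC with CI and p, and the
#' heterogeneity block. A gene's overall `gene_significant` flag is true
#' if either analysis passes the filter (a gene may satisfy the criteria
#' in the partial analysis only).
#'
#' @param effects Effects table from [effects_table()].
#' @param mode Model-selection mode, see [mega()].
#' @param alpha,up,down Significance-filter thresholds, see
#'   [significance_filter()].
#' @return Data frame with one `"MA"` and one `"partial-MA"` row per gene.
#' @export
mega_table <- function(effects, mode = "auto", alpha = 1e-7, up = 0.49,
                       down = -0.74) {
  check_effects(effects, 1L)
  if (!"gene" %in% names(effects)) effects$gene <- "gene"
  rows <- lapply(split(effects, effects$gene), function(eff) {
    full <- mega(eff, mode)
    part <- partial_mega(eff, mode)
    do.call(rbind, lapply(list(full, part), function(r) {
      data.frame(
        gene = r$gene,
        analysis = if (r$analysis == "full") "MA" else "partial-MA",
        significant = significance_filter(r, alpha, up, down),
        model = r$model, k = r$k,
        pooled_lfc = r$pooled_lfc, se_pooled = r$se_pooled,
        ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
        Q = r$Q, df = r$df, isq = r$isq, p_q = r$p_q, tau2 = r$tau2,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$gene, unique(effects$gene)), out$analysis), ]
  sig <- tapply(out$significant, out$gene, any)
  out$gene_significant <- unname(sig[out$gene])
  rownames(out) <- NULL
  out
}

#' Per-study forest table of a pooled result
#'
#' The quantities of a forest plot: each study's effect size with its 95%
#' CI and its normalized meta-analytic weight (weights sum to 1).
#'
#' @param result A `mega_result`.
#' @return Data frame with columns `study_id`, `y`, `ci_low`, `ci_high`,
#'   `weight`.
#' @export
forest_table <- function(result) {
  stopifnot(inherits(result, "mega_result"))
  eff <- result$effects
  data.frame(
    study_id = eff$study_id %||% as.character(seq_len(nrow(eff))),
    y = eff$y,
    ci_low = eff$y - CI_Z * eff$se,
    ci_high = eff$y + CI_Z * eff$se,
    weight = unname(result$weights),
    stringsAsFactors = FALSE)
}
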