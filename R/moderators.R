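# Study-level moderator regression: per-gene OLS of effect sizes on total
# sample size, study year, and region (dummy-coded, tested as a whole
# factor).

# Continent grouping for the default country labels; used when the raw
# region factor has too many levels (or singleton levels) for the number
# of studies at hand.
default_region_map <- c(
  "Spain" = "Europe", "United Kingdom" = "Europe", "Hungary" = "Europe",
  "Netherlands" = "Europe", "United States" = "North America",
  "Australia" = "Oceania")

#' Encode study regions as treatment-coded design columns
#'
#' Dummy (treatment) coding against the most frequent level as reference.
#' If the raw labels have more than `max_levels` distinct levels, or any
#' level is carried by a single study, labels are first merged through
#' `merge_map` (default: a continent map) and the merge is recorded in
#' the returned note. Labels absent from the map are kept as-is.
#'
#' @param regions Character vector, one label per study.
#' @param max_levels Maximum distinct levels before merging kicks in.
#' @param merge_map Named character vector mapping labels to coarser
#'   groups.
#' @return List with `columns` (n x (levels - 1) indicator matrix),
#'   `levels`, `reference` and `note`.
#' @export
region_encode <- function(regions, max_levels = 3L,
                          merge_map = default_region_map) {
  regions <- as.character(regions)
  if (!length(regions)) stop("at least one region label required")
  note <- "regions used as given"
  tab <- table(regions)
  if (length(tab) > max_levels || any(tab == 1L)) {
    mapped <- ifelse(regions %in% names(merge_map),
                     merge_map[regions], regions)
    if (!identical(unname(mapped), regions)) {
      note <- sprintf("regions merged to coarser groups (%s)",
                      paste(unique(sprintf("%s->%s",
                                           regions[mapped != regions],
                                           mapped[mapped != regions])),
                            collapse = ", "))
      regions <- unname(mapped)
      tab <- table(regions)
    }
  }
  lev <- names(sort(tab, decreasing = TRUE))  # most frequent first
  f <- factor(regions, levels = lev)
  cols <- if (length(lev) > 1L) {
    m <- sapply(lev[-1L], function(l) as.numeric(f == l))
    m <- matrix(m, nrow = length(regions),
                dimnames = list(NULL, paste0("region", lev[-1L])))
    m
  } else {
    matrix(numeric(0), nrow = length(regions), ncol = 0L)
  }
  list(columns = cols, levels = lev, reference = lev[1L], note = note)
}

#' Regress one gene's per-study effects on study-level moderators
#'
#' Ordinary least squares of the per-study log2 fold changes on an
#' intercept, the total sample size (`n_case + n_control`), the study
#' year, and treatment-coded region dummies. Region is tested as a whole
#' factor by the F-test comparing the full model against the model
#' without the region columns; the numeric moderators get t-based
#' p-values and 95% CIs at the residual degrees of freedom. Inverse-
#' variance weighting is available via `weighted`.
#'
#' @param effects Effect records of a single gene (columns `study_id`,
#'   `y`, `se`, optionally `gene`).
#' @param metadata Data frame with columns `study_id`, `region`, `year`,
#'   `n_case`, `n_control`.
#' @param weighted Use weights `1/se^2` instead of OLS.
#' @param max_levels,merge_map Region-encoding controls, see
#'   [region_encode()].
#' @return List of class `moderator_fit`: `gene`, `coefficients`,
#'   `ci_low`/`ci_high` (numeric predictors), `p_values` (named
#'   `sample_size`, `year`, `region`), `n_studies_used`, `design_note`.
#' @export
fit_moderators <- function(effects, metadata, weighted = FALSE,
                           max_levels = 3L,
                           merge_map = default_region_map) {
  check_effects(effects, 1L)
  if ("gene" %in% names(effects) && length(unique(effects$gene)) > 1L)
    stop("fit_moderators expects the effects of a single gene")
  need <- c("study_id", "region", "year", "n_case", "n_control")
  if (!all(need %in% names(metadata)))
    stop("metadata needs columns ", paste(need, collapse = ", "))
  idx <- match(effects$study_id, metadata$study_id)
  if (anyNA(idx)) stop("metadata missing for some studies")
  md <- metadata[idx, ]
  n <- nrow(effects)
  enc <- region_encode(md$region, max_levels, merge_map)
  dat <- data.frame(y = effects$y,
                    n_total = md$n_case + md$n_control,
                    year = md$year)
  X <- cbind(dat$n_total, dat$year, enc$columns)
  n_par <- ncol(X) + 1L  # + intercept
  if (n < n_par + 2L)
    stop("need at least ", n_par + 2L,
         " studies for ", n_par, " parameters")
  if (qr(cbind(1, X))$rank < n_par) {
    culprit <- if (ncol(enc$columns) &&
                   qr(cbind(1, dat$n_total, dat$year))$rank == 3L)
      "region (one study per level?); merge levels via merge_map"
    else "sample size/year (constant or collinear)"
    stop("rank-deficient moderator design: ", culprit)
  }
  dat <- cbind(dat, enc$columns)
  form_full <- stats::as.formula(paste(
    "y ~ n_total + year",
    if (ncol(enc$columns)) paste("+", paste0("`", colnames(enc$columns),
                                             "`", collapse = " + "))
    else ""))
  w <- if (weighted) 1 / effects$se^2 else NULL
  fit <- lm(form_full, data = dat, weights = w)
  fit0 <- lm(y ~ n_total + year, data = dat, weights = w)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(confint(fit, level = 0.95))
  p_region <- if (ncol(enc$columns)) {
    a <- anova(fit0, fit)
    a[["Pr(>F)"]][2L]
  } else NA_real_
  cf <- coef(fit)
  structure(list(
    gene = if ("gene" %in% names(effects)) effects$gene[1L]
           else NA_character_,
    coefficients = cf,
    ci_low = ci[, 1L],
    ci_high = ci[, 2L],
    p_values = c(sample_size = sm$coefficients["n_total", 4L],
                 year = sm$coefficients["year", 4L],
                 region = p_region),
    n_studies_used = n,
    design_note = sprintf("%s; reference level '%s'; %s",
                          enc$note, enc$reference,
                          if (weighted) "inverse-variance weighted"
                          else "unweighted OLS"),
    fit = fit
  ), class = "moderator_fit")
}

#' Moderator fits for every gene of an effects table
#'
#' @param effects Multi-gene effects table ([effects_table()]).
#' @param metadata Study metadata, see [fit_moderators()].
#' @param ... Passed to [fit_moderators()].
#' @return Data frame, one row per (gene, factor): estimate and CI for
#'   the numeric factors, the whole-factor p for region.
#' @export
moderators_table <- function(effects, metadata, ...) {
  check_effects(effects, 1L)
  if (!"gene" %in% names(effects)) effects$gene <- "gene"
  rows <- lapply(split(effects, effects$gene), function(eff) {
    f <- fit_moderators(eff, metadata, ...)
    data.frame(
      gene = f$gene,
      factor = c("sample_size", "year", "region"),
      estimate = c(f$coefficients["n_total"], f$coefficients["year"], NA),
      ci_low = c(f$ci_low["n_total"], f$ci_low["year"], NA),
      ci_high = c(f$ci_high["n_total"], f$ci_high["year"], NA),
      p = unname(f$p_values),
      n_studies_used = f$n_studies_used,
      design_note = f$design_note,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.moderator_fit <- function(x, ...) {
  cat(sprintf(
    "<moderator_fit> %s (k=%d): p[sample_size]=%.3g p[year]=%.3g p[region]=%.3g\n  %s\n",
    x$gene, x$n_studies_used, x$p_values["sample_size"],
    x$p_values["year"], x$p_values["region"], x$design_note))
  invisible(x)
}
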