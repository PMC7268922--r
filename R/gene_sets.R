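# Set arithmetic on curated gene lists, hypergeometric overlap
# significance, and GMT-based over-representation with BH correction.

#' Partition two gene sets
#'
#' Splits `A` and `B` into the disjoint parts A-only, common, B-only
#' covering their union, and reports sizes plus the percentage of `A`
#' not shared with `B` (e.g. senescence genes not previously implicated
#' in the disease).
#'
#' @param A,B Non-empty character vectors (case-normalized internally).
#' @return List with `A_only`, `common`, `B_only` (sorted character
#'   vectors), their sizes `n_A`, `n_B`, `n_overlap`, and `pct_A_only`.
#' @export
partition_sets <- function(A, B) {
  if (!length(A) || !length(B)) stop("input gene sets must be non-empty")
  A <- unique(toupper(A)); B <- unique(toupper(B))
  common <- intersect(A, B)
  list(A_only = sort(setdiff(A, B)),
       common = sort(common),
       B_only = sort(setdiff(B, A)),
       n_A = length(A), n_B = length(B), n_overlap = length(common),
       pct_A_only = 100 * (length(A) - length(common)) / length(A))
}

#' Hypergeometric overlap significance
#'
#' Upper-tail probability of observing at least `n_overlap` common genes
#' between a set of size `n_A` and a set of size `n_B` drawn from a
#' universe of `n_universe` genes:
#' `P(X >= n_overlap)` for `X ~ Hypergeometric(n_A, n_universe - n_A,
#' n_B)`, evaluated in log space for numerical stability. The universe
#' size is part of the result because the p-value is meaningless without
#' it.
#'
#' @param n_A,n_B,n_overlap,n_universe Counts; must be feasible
#'   (`n_overlap <= min(n_A, n_B)`,
#'   `n_A + n_B - n_overlap <= n_universe`).
#' @param A,B Optional label sets used only to populate the partition
#'   fields of the result.
#' @return List of class `overlap_result` with the counts, `p_overlap`,
#'   and (when sets are given) `A_only`, `common`, `B_only`.
#' @export
hypergeom_overlap <- function(n_A, n_B, n_overlap, n_universe,
                              A = NULL, B = NULL) {
  cnt <- c(n_A, n_B, n_overlap, n_universe)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if (n_A > n_universe || n_B > n_universe)
    stop("set larger than the universe")
  if (n_overlap > min(n_A, n_B))
    stop("overlap exceeds the smaller set")
  # also covers overlaps below the universe-forced minimum:
  # n_overlap < n_A + n_B - n_universe iff this fails
  if (n_A + n_B - n_overlap > n_universe)
    stop("sets cannot fit in the universe with this overlap")
  p <- phyper(n_overlap - 1, n_A, n_universe - n_A, n_B,
              lower.tail = FALSE)
  part <- if (!is.null(A) && !is.null(B)) partition_sets(A, B)
  structure(list(n_A = n_A, n_B = n_B, n_overlap = n_overlap,
                 n_universe = n_universe, p_overlap = p,
                 A_only = part$A_only, common = part$common,
                 B_only = part$B_only),
            class = "overlap_result")
}

#' Overlap significance of two explicit gene sets
#'
#' @param A,B Character gene sets.
#' @param universe Universe size (count) or an explicit universe set, in
#'   which case `A` and `B` are intersected with it first. Defaults to
#'   20000 protein-coding-genome-sized background; always report it.
#' @return An `overlap_result`, see [hypergeom_overlap()].
#' @export
overlap_test <- function(A, B, universe = 20000L) {
  A <- unique(toupper(A)); B <- unique(toupper(B))
  if (is.character(universe)) {
    universe <- unique(toupper(universe))
    A <- intersect(A, universe); B <- intersect(B, universe)
    n_u <- length(universe)
  } else {
    n_u <- as.integer(universe)
  }
  hypergeom_overlap(length(A), length(B), length(intersect(A, B)), n_u,
                    A = A, B = B)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> |A|=%d |B|=%d overlap=%d universe=%d p=%.3g\n",
    x$n_A, x$n_B, x$n_overlap, x$n_universe, x$p_overlap))
  invisible(x)
}

#' Over-representation of a query gene set in GMT terms
#'
#' For each term, the one-sided Fisher/hypergeometric upper-tail p-value
#' of the observed overlap between the query and the term within the
#' universe, with Benjamini-Hochberg adjustment across all tested terms.
#' When the universe is an explicit set, query and terms are intersected
#' with it first. Rows are sorted by ascending p, ties broken by term
#' label.
#'
#' @param query Non-empty character gene set.
#' @param terms Named list of term member vectors (see [read_gmt()]).
#' @param universe Universe size or explicit set; defaults to 20000.
#' @return Data frame with columns `term`, `term_size`, `overlap`, `p`,
#'   `fdr`.
#' @export
enrich <- function(query, terms, universe = 20000L) {
  if (!length(query)) stop("empty query set")
  if (!length(terms) || is.null(names(terms)))
    stop("terms must be a non-empty named list")
  query <- unique(toupper(query))
  terms <- lapply(terms, function(t) unique(toupper(t)))
  if (is.character(universe)) {
    universe <- unique(toupper(universe))
    query <- intersect(query, universe)
    terms <- lapply(terms, intersect, universe)
    n_u <- length(universe)
  } else {
    n_u <- as.integer(universe)
  }
  n_q <- length(query)
  term_size <- lengths(terms)
  if (n_u < n_q || any(term_size > n_u))
    stop("universe smaller than the query or a term")
  overlap <- vapply(terms, function(t) length(intersect(t, query)), 0L)
  p <- phyper(overlap - 1, term_size, n_u - term_size, n_q,
              lower.tail = FALSE)
  out <- data.frame(term = names(terms), term_size = unname(term_size),
                    overlap = unname(overlap), p = unname(p),
                    fdr = unname(p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
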