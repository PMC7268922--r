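# Synthetic multi-study case/control expression collections with planted
# ground truth, emulating a set of independent GEO-style datasets.

#' Configuration for the multi-study expression simulator
#'
#' Describes a collection of independent case/control expression studies on
#' the log2 scale: per-gene true log2 fold changes (`true_lfc`), optional
#' between-study variance of the study-specific effect (`tau2`, the
#' random-effects component), a common within-arm per-sample standard
#' deviation (`sigma`), per-gene baseline log2 means, per-study arm sizes,
#' and a metadata pool (region labels, year range) from which study
#' metadata are drawn. Matrices are exported on the linear scale (`2^x`) so
#' that the pipeline's own log2 step is exercised.
#'
#' Defaults mirror a nine-study collection with the arm sizes, countries
#' and year span of the COPD expression datasets the pipeline was designed
#' around.
#'
#' @param n_studies Number of studies (>= 1).
#' @param n_genes Number of genes (>= 1).
#' @param n_case,n_control Per-study arm sizes; recycled to `n_studies`.
#' @param true_lfc Per-gene true log2 fold change (case minus control);
#'   recycled to `n_genes`.
#' @param tau2 Per-gene between-study variance of the study-specific
#'   effect; recycled to `n_genes`; all entries >= 0.
#' @param sigma Within-arm per-sample standard deviation on the log2
#'   scale (> 0).
#' @param baseline_mean Per-gene baseline log2 mean; recycled to `n_genes`.
#' @param dropout Probability that a given gene is unmeasured in a given
#'   study (independent per gene and study), giving genes a variable
#'   number of contributing studies.
#' @param regions Pool of region labels sampled with replacement.
#' @param years Candidate study years, sampled uniformly.
#' @param seed Integer RNG seed; identical seed and configuration give a
#'   bit-identical collection.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_studies = 9,
                              n_genes = 100,
                              n_case = c(18, 10, 30, 23, 22, 6, 10, 36, 16),
                              n_control = c(20, 6, 24, 9, 135, 6, 10, 27, 19),
                              true_lfc = 0,
                              tau2 = 0,
                              sigma = 0.5,
                              baseline_mean = 8,
                              dropout = 0,
                              regions = c("Spain", "United Kingdom",
                                          "United States", "Hungary",
                                          "Australia", "Netherlands"),
                              years = 2008:2016,
                              seed = 1L) {
  n_studies <- as.integer(n_studies)
  n_genes <- as.integer(n_genes)
  cfg <- list(
    n_studies = n_studies,
    n_genes = n_genes,
    n_case = as.integer(rep_len(n_case, n_studies)),
    n_control = as.integer(rep_len(n_control, n_studies)),
    true_lfc = rep_len(as.numeric(true_lfc), n_genes),
    tau2 = rep_len(as.numeric(tau2), n_genes),
    sigma = as.numeric(sigma),
    baseline_mean = rep_len(as.numeric(baseline_mean), n_genes),
    dropout = as.numeric(dropout),
    regions = as.character(regions),
    years = as.integer(years),
    seed = as.integer(seed)
  )
  num <- unlist(cfg[c("n_case", "n_control", "true_lfc", "tau2", "sigma",
                      "baseline_mean", "dropout", "seed")])
  if (any(!is.finite(num))) stop("non-finite values in simulation config")
  if (n_studies < 1L || n_genes < 1L) stop("n_studies and n_genes must be >= 1")
  if (any(cfg$n_case < 1L) || any(cfg$n_control < 1L))
    stop("all arm sizes must be >= 1")
  if (cfg$sigma <= 0) stop("sigma must be > 0")
  if (any(cfg$tau2 < 0)) stop("tau2 must be >= 0 elementwise")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (!length(cfg$regions)) stop("at least one region label required")
  structure(cfg, class = "simulation_config")
}

# One sub-seed per study so generate_study(cfg, i) is self-contained and
# agrees with the i-th element of generate_collection(cfg).
study_seeds <- function(config) {
  local_seed(config$seed,
             sample.int(2147483646L, config$n_studies, replace = FALSE))
}

#' Simulate a single case/control expression study
#'
#' Control samples are drawn `N(baseline_g, sigma^2)` on the log2 scale;
#' case samples around `baseline_g + true_lfc_g + delta_gs` where
#' `delta_gs ~ N(0, tau2_g)` is the study-level deviation shared by all
#' case samples of the study. Values are exported on the linear scale
#' (`2^x`, strictly positive) so downstream preprocessing performs the
#' log2 transform itself. Genes lost to dropout are absent from the
#' returned matrix.
#'
#' @param config A [simulation_config()].
#' @param study_index Which study to generate, in `1:n_studies`.
#' @return An [expression_study] with metadata drawn from the config pool.
#' @export
generate_study <- function(config, study_index) {
  stopifnot(inherits(config, "simulation_config"))
  study_index <- as.integer(study_index)
  if (study_index < 1L || study_index > config$n_studies)
    stop("study_index out of range")
  seed_i <- study_seeds(config)[study_index]
  nc <- config$n_case[study_index]
  nn <- config$n_control[study_index]
  g <- config$n_genes
  local_seed(seed_i, {
    region <- sample(config$regions, 1L)
    year <- if (length(config$years) == 1L) config$years
            else sample(config$years, 1L)
    delta <- rnorm(g, 0, sqrt(config$tau2))
    ctrl <- matrix(rnorm(g * nn, mean = config$baseline_mean,
                         sd = config$sigma), nrow = g)
    case <- matrix(rnorm(g * nc,
                         mean = config$baseline_mean + config$true_lfc + delta,
                         sd = config$sigma), nrow = g)
    present <- if (config$dropout > 0) runif(g) >= config$dropout
               else rep(TRUE, g)
    if (!any(present)) present[1L] <- TRUE   # a study never loses every gene
    x <- 2^cbind(case, ctrl)
    study_id <- sprintf("STUDY%02d", study_index)
    rownames(x) <- gene_labels(g)
    colnames(x) <- c(sprintf("%s_case%02d", study_id, seq_len(nc)),
                     sprintf("%s_ctrl%02d", study_id, seq_len(nn)))
    expression_study(
      study_id = study_id,
      matrix = x[present, , drop = FALSE],
      sample_groups = rep(c("case", "control"), c(nc, nn)),
      region = region,
      year = year
    )
  })
}

gene_labels <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a collection of studies with shared ground truth
#'
#' @param config A [simulation_config()].
#' @return A list of [expression_study] objects (class `study_collection`)
#'   carrying the planted per-gene truth as `attr(x, "truth")`, a data
#'   frame with columns `gene`, `true_lfc`, `tau2`.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  studies <- lapply(seq_len(config$n_studies),
                    function(i) generate_study(config, i))
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  structure(studies,
            class = c("study_collection", "list"),
            truth = data.frame(gene = gene_labels(config$n_genes),
                               true_lfc = config$true_lfc,
                               tau2 = config$tau2,
                               stringsAsFactors = FALSE))
}

#' Generate two gene sets with an exact intersection size
#'
#' Draws, from a synthetic universe of `n_universe` gene labels, two sets
#' `A` and `B` with `|A| = n_A`, `|B| = n_B` and exactly `n_overlap` genes
#' in common — the structure needed to exercise set partitioning and
#' overlap significance with known answers.
#'
#' @param n_universe,n_A,n_B,n_overlap Set sizes; must satisfy
#'   `n_overlap <= min(n_A, n_B)` and `n_A + n_B - n_overlap <= n_universe`.
#' @param seed Integer RNG seed.
#' @return List of class `gene_set_pair` with elements `A`, `B`,
#'   `universe` (character vectors).
#' @export
generate_genesets <- function(n_universe, n_A, n_B, n_overlap, seed = 1L) {
  sizes <- c(n_universe, n_A, n_B, n_overlap)
  if (any(!is.finite(sizes)) || any(sizes < 0) || any(sizes != round(sizes)))
    stop("set sizes must be non-negative integers")
  if (n_A < 1 || n_B < 1) stop("n_A and n_B must be >= 1")
  if (n_overlap > min(n_A, n_B))
    stop("n_overlap exceeds the smaller set size")
  if (n_A + n_B - n_overlap > n_universe)
    stop("universe too small for the requested sets")
  universe <- sprintf("U%05d", seq_len(n_universe))
  local_seed(seed, {
    pool <- sample(universe)
    common <- pool[seq_len(n_overlap)]
    a_only <- pool[n_overlap + seq_len(n_A - n_overlap)]
    b_only <- pool[n_A + seq_len(n_B - n_overlap)]
    structure(list(A = sort(c(common, a_only)),
                   B = sort(c(common, b_only)),
                   universe = universe),
              class = "gene_set_pair")
  })
}
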