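# Reading, writing and preprocessing of expression studies, gene lists and
# GMT collections.

#' Construct an expression study
#'
#' A single case/control study: a gene-by-sample expression matrix with
#' unique gene row names, a case/control label per sample, and study-level
#' metadata (region, year). Arm sizes are derived from the labels. Studies
#' with fewer than 10 samples in total are retained but flagged
#' (`size_compliant = FALSE`), matching the usual minimum-size inclusion
#' filter for cross-study pooling.
#'
#' @param study_id Study label.
#' @param matrix Numeric gene x sample matrix with gene row names.
#' @param sample_groups Character vector, one of `"case"`/`"control"` per
#'   column of `matrix`.
#' @param region Region/country label.
#' @param year Study year.
#' @return Object of class `expression_study`.
#' @export
expression_study <- function(study_id, matrix, sample_groups,
                             region = NA_character_, year = NA_integer_) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric matrix")
  if (is.null(rownames(matrix))) stop("matrix must have gene row names")
  if (anyDuplicated(rownames(matrix)))
    stop("gene ids must be unique within a study")
  sample_groups <- as.character(sample_groups)
  if (length(sample_groups) != ncol(matrix))
    stop("one group label per sample column required")
  if (!all(sample_groups %in% c("case", "control")))
    stop("sample groups must be 'case' or 'control'")
  n_case <- sum(sample_groups == "case")
  n_control <- sum(sample_groups == "control")
  if (n_case < 1L || n_control < 1L)
    stop("study needs at least one case and one control sample")
  structure(list(
    study_id = as.character(study_id),
    matrix = matrix,
    gene_ids = rownames(matrix),
    sample_groups = sample_groups,
    region = as.character(region),
    year = as.integer(year),
    n_case = n_case,
    n_control = n_control,
    size_compliant = (n_case + n_control) >= 10L,
    preprocessed = FALSE,
    log = character()
  ), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %s: %d genes, %d case / %d control (%s, %s)%s\n",
    x$study_id, nrow(x$matrix), x$n_case, x$n_control,
    x$region, x$year,
    if (x$size_compliant) "" else " [below 10-sample inclusion filter]"))
  invisible(x)
}

#' Read one study from matrix / phenotype / metadata files
#'
#' The matrix file is a TSV with gene ids in the first column and one
#' column per sample; the phenotype file has columns `sample_id`, `group`
#' (`case`/`control`); the metadata file has columns `study_id`, `region`,
#' `year`. Phenotype sample ids must match the matrix columns exactly
#' (any mismatch is a hard error). Genes carrying any missing value in the
#' study are dropped from that study and recorded in the study log, so a
#' gene's number of contributing studies may vary across the collection.
#' Duplicate gene rows keep the row with the highest mean.
#'
#' @param matrix_path,phenotype_path,metadata_path File paths.
#' @return An [expression_study].
#' @export
read_study <- function(matrix_path, phenotype_path, metadata_path) {
  for (p in c(matrix_path, phenotype_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- read.delim(matrix_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- toupper(as.character(raw[[1L]]))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  pheno <- read.delim(phenotype_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(pheno)))
    stop("phenotype file needs columns sample_id, group")
  if (!setequal(pheno$sample_id, colnames(m)) ||
      anyDuplicated(pheno$sample_id))
    stop("phenotype sample ids do not match matrix columns")
  groups <- pheno$group[match(colnames(m), pheno$sample_id)]
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  log_lines <- character()
  if (anyDuplicated(rownames(m))) {
    keep <- order(-rowMeans(m, na.rm = TRUE))
    m <- m[keep, , drop = FALSE]
    dup <- duplicated(rownames(m))
    log_lines <- c(log_lines, sprintf(
      "collapsed %d duplicate gene rows (kept highest mean)", sum(dup)))
    m <- m[!dup, , drop = FALSE]
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  incomplete <- !stats::complete.cases(m)
  if (any(incomplete)) {
    log_lines <- c(log_lines, sprintf(
      "dropped %d genes with missing values: %s", sum(incomplete),
      paste(head(rownames(m)[incomplete], 10L), collapse = ", ")))
    m <- m[!incomplete, , drop = FALSE]
  }
  study <- expression_study(
    study_id = as.character(meta$study_id[1L]),
    matrix = m,
    sample_groups = groups,
    region = meta$region[1L] %||% NA_character_,
    year = meta$year[1L] %||% NA_integer_
  )
  study$log <- log_lines
  if (!study$size_compliant)
    warning("study ", study$study_id,
            " has fewer than 10 samples; flagged non-compliant")
  study
}

#' Write a study to matrix / phenotype / metadata TSV files
#'
#' Inverse of [read_study()]; values round-trip to at least 6 decimals.
#'
#' @param study An [expression_study].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "expression_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, study$study_id)
  paths <- paste0(base, c("_matrix.tsv", "_phenotype.tsv", "_metadata.tsv"))
  mat <- data.frame(gene = study$gene_ids, study$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(mat, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  pheno <- data.frame(sample_id = colnames(study$matrix),
                      group = study$sample_groups)
  write.table(pheno, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(study_id = study$study_id, region = study$region,
                     year = study$year, n_case = study$n_case,
                     n_control = study$n_control)
  write.table(meta, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Normalize and log2-transform a study
#'
#' If the matrix looks linear-scale (maximum value above `log2_threshold`,
#' default 50 — log2 microarray/RNA intensities rarely exceed ~20), it is
#' transformed with `log2(x + 1)`; already-logged data are left alone, so
#' the operation is idempotent. Cross-sample normalization then equalizes
#' per-sample medians (`"median-scale"`: subtract each sample's median and
#' add the grand mean of medians), applies quantile normalization
#' (`"quantile"`, via limma), or does nothing (`"none"`). Each decision is
#' appended to the study log.
#'
#' @param study An [expression_study].
#' @param method Normalization method.
#' @param log2_threshold Linear-scale detection cutoff on the matrix
#'   maximum.
#' @param force_log2 Override auto-detection: `TRUE`/`FALSE` forces the
#'   log step on/off, `NA` (default) auto-detects.
#' @return The preprocessed [expression_study].
#' @export
preprocess <- function(study,
                       method = c("median-scale", "quantile", "none"),
                       log2_threshold = 50, force_log2 = NA) {
  stopifnot(inherits(study, "expression_study"))
  method <- match.arg(method)
  m <- study$matrix
  if (!all(is.finite(m))) stop("non-finite expression values; clean first")
  do_log <- if (is.na(force_log2)) max(m) > log2_threshold else force_log2
  if (do_log) {
    if (any(m < 0))
      stop("negative values: cannot log2-transform")
    m <- log2(m + 1)
    study$log <- c(study$log, sprintf(
      "log2(x+1) applied (max > %g judged linear-scale)", log2_threshold))
  } else {
    study$log <- c(study$log, "log step skipped (data judged log-scale)")
  }
  if (method == "median-scale") {
    med <- apply(m, 2L, median)
    m <- sweep(m, 2L, med) + mean(med)
    study$log <- c(study$log, "median-scale normalization")
  } else if (method == "quantile") {
    dn <- dimnames(m)
    m <- limma::normalizeQuantiles(m)
    dimnames(m) <- dn
    study$log <- c(study$log, "quantile normalization (limma)")
  }
  study$matrix <- m
  study$preprocessed <- TRUE
  study
}

#' Read a plain-text gene list
#'
#' One symbol per line; symbols are upper-cased, trimmed and de-duplicated.
#'
#' @param path File path.
#' @return Character vector (a set) of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- unique(toupper(x[nzchar(x)]))
  if (!length(x)) stop("empty gene list: ", path)
  x
}

#' @rdname read_gene_list
#' @param genes Character vector of symbols to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(unique(toupper(genes)), path)
  invisible(path)
}

#' Read / write GMT term collections
#'
#' Standard GMT dialect: one term per line, tab-separated as
#' `term<TAB>description<TAB>member1<TAB>member2...`. Members are
#' upper-cased and de-duplicated.
#'
#' @param path File path.
#' @return Named list of character vectors (term -> members), with term
#'   descriptions in `attr(x, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT rows (need term, description, members)")
  terms <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(terms) <- vapply(parts, `[[`, "", 1L)
  attr(terms, "descriptions") <-
    setNames(vapply(parts, `[[`, "", 2L), names(terms))
  terms
}

#' @rdname read_gmt
#' @param terms Named list of member vectors.
#' @param descriptions Optional named descriptions; defaults to term names.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  if (!length(terms) || is.null(names(terms)))
    stop("terms must be a non-empty named list")
  desc <- descriptions %||% attr(terms, "descriptions") %||%
    setNames(names(terms), names(terms))
  lines <- vapply(names(terms), function(t) {
    paste(c(t, desc[[t]] %||% t, unique(toupper(terms[[t]]))),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GEO series-matrix file (experimental)
#'
#' Best-effort parser for the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` block of a GEO series-matrix text file, plus
#' the `!Sample_geo_accession`, `!Sample_title` and
#' `!Sample_characteristics_ch1` header lines. It returns the raw pieces;
#' assembling an [expression_study] (choosing which characteristic encodes
#' case/control, collapsing probes to genes) is left to the caller. This
#' reader is experimental and makes no attempt to cover every GEO dialect.
#'
#' @param path Path to an uncompressed series-matrix text file.
#' @return List with `matrix` (numeric, probes x samples), `samples`
#'   (accessions) and `characteristics` (character matrix, one row per
#'   `!Sample_characteristics_ch1` line).
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  strip <- function(x) gsub('^"|"$', "", x)
  fields <- function(l) strip(strsplit(l, "\t", fixed = TRUE)[[1L]])
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series-matrix table block found")
  tab <- lapply(lines[(beg + 1L):(end - 1L)], fields)
  header <- tab[[1L]]
  body <- tab[-1L]
  m <- matrix(NA_real_, nrow = length(body), ncol = length(header) - 1L,
              dimnames = list(vapply(body, `[[`, "", 1L), header[-1L]))
  for (i in seq_along(body))
    m[i, ] <- suppressWarnings(as.numeric(body[[i]][-1L]))
  acc <- grep("^!Sample_geo_accession", lines, value = TRUE)
  samples <- if (length(acc)) fields(acc[1L])[-1L] else colnames(m)
  chr <- grep("^!Sample_characteristics_ch1", lines, value = TRUE)
  characteristics <- if (length(chr))
    do.call(rbind, lapply(chr, function(l) fields(l)[-1L]))
  else matrix(character(), nrow = 0L, ncol = length(samples))
  list(matrix = m, samples = samples, characteristics = characteristics)
}
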