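#' Expression cohort objects
#'
#' An expression cohort bundles a log2-scale expression matrix (genes in
#' rows, samples in columns) with a tumor/normal label per sample. All
#' downstream stages (differential expression, co-expression, subtyping)
#' consume this container.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene identifiers) and colnames (sample identifiers). Values are assumed
#'   to be on the log2 scale, as produced by standard microarray/RNA-seq
#'   normalisation.
#' @param condition Character vector, one of `"tumor"`/`"normal"` per sample;
#'   either named by sample id or in column order of `values`.
#' @param cohort_id Single string naming the cohort.
#' @return An object of class `expr_cohort`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expr_cohort(m, c("tumor", "tumor", "normal"), "toy")
#' @export
expr_cohort <- function(values, condition, cohort_id = "cohort") {
  assert_that(is.matrix(values) && is.numeric(values),
              "`values` must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "`values` must carry gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(values)),
              paste0("duplicate gene identifiers: ",
                     paste(unique(rownames(values)[duplicated(rownames(values))]),
                           collapse = ", ")))
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample identifiers")
  assert_that(all(is.finite(values)), "expression values must all be finite")
  if (is.null(names(condition))) {
    assert_that(length(condition) == ncol(values),
                "`condition` length must match sample count")
    names(condition) <- colnames(values)
  }
  missing_cond <- setdiff(colnames(values), names(condition))
  assert_that(length(missing_cond) == 0,
              paste0("samples missing a condition: ",
                     paste(missing_cond, collapse = ", ")))
  condition <- condition[colnames(values)]
  assert_that(all(condition %in% c("tumor", "normal")),
              "conditions must be 'tumor' or 'normal'")
  structure(
    list(cohort_id = as.character(cohort_id), values = values,
         condition = condition),
    class = "expr_cohort"
  )
}

#' @export
print.expr_cohort <- function(x, ...) {
  cat(sprintf("<expr_cohort '%s'> %d genes x %d samples (%d tumor, %d normal)\n",
              x$cohort_id, nrow(x$values), ncol(x$values),
              sum(x$condition == "tumor"), sum(x$condition == "normal")))
  invisible(x)
}

#' @export
dim.expr_cohort <- function(x) dim(x$values)

# matrix of one stratum; "all" keeps every sample
cohort_stratum <- function(cohort, stratum = c("tumor", "normal", "all")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") return(cohort$values)
  cohort$values[, cohort$condition == stratum, drop = FALSE]
}

#' Tidy an expression cohort into a long tibble
#'
#' @param x An `expr_cohort`.
#' @param ... Unused.
#' @return A tibble with columns `cohort_id`, `gene`, `sample`, `condition`,
#'   `expression`.
#' @export
tidy.expr_cohort <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "expression") |>
    dplyr::mutate(
      cohort_id = x$cohort_id,
      condition = unname(x$condition[.data$sample]),
      .before = "gene"
    )
}

#' Read and write expression cohorts as TSV
#'
#' The expression file is a TSV with a header of sample identifiers and gene
#' identifiers in the first column; the condition file is a two-column TSV
#' (`sample_id`, `condition`) assigning each sample to `tumor` or `normal`.
#' `write_expression()` emits files that `read_expression()` re-ingests
#' losslessly.
#'
#' @param path Expression matrix TSV path.
#' @param condition_path Sample condition TSV path.
#' @param cohort_id Cohort name attached to the returned object.
#' @return `read_expression()` returns an [expr_cohort()];
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, condition_path, cohort_id = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  genes <- raw[[1]]
  cols <- lapply(names(raw)[-1], function(nm) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !(raw[[nm]] %in% c("NA", "NaN")))
    if (length(bad)) {
      parse_error(sprintf(
        "non-numeric expression value '%s' at row %d (gene %s), column '%s'",
        raw[[nm]][bad[1]], bad[1], genes[bad[1]], nm))
    }
    v
  })
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(genes, names(raw)[-1])
  cond <- utils::read.table(condition_path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "")
  assert_that(all(c("sample_id", "condition") %in% names(cond)),
              "condition file needs columns sample_id, condition")
  expr_cohort(mat, setNames(cond$condition, cond$sample_id),
              cohort_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_expression
#' @param cohort An `expr_cohort` to serialise.
#' @export
write_expression <- function(cohort, path, condition_path) {
  df <- data.frame(gene = rownames(cohort$values), cohort$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cohort$condition),
               condition = unname(cohort$condition)),
    condition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' Microarray platforms measure several probes per gene; the gene-level
#' value per sample is the unweighted arithmetic mean of its probes'
#' (log2-scale) values. Probes mapping to no gene in `probe_table` are
#' dropped with a message reporting the count.
#'
#' @param probe_matrix Numeric matrix, probes x samples, rownames = probe ids.
#' @param probe_table Data frame with columns `probe_id`, `gene_id`
#'   (one row per probe; `probe_id` unique, `gene_id` non-empty or `NA` for
#'   unmapped probes).
#' @param condition Per-sample condition passed through to [expr_cohort()].
#' @param cohort_id Cohort name.
#' @return An [expr_cohort()] with one row per mapped gene.
#' @export
collapse_probes <- function(probe_matrix, probe_table, condition,
                            cohort_id = "cohort") {
  assert_that(!anyDuplicated(probe_table$probe_id), "probe_id must be unique")
  unmapped <- is.na(probe_table$gene_id) | probe_table$gene_id == ""
  map <- setNames(probe_table$gene_id[!unmapped], probe_table$probe_id[!unmapped])
  absent <- setdiff(rownames(probe_matrix), probe_table$probe_id)
  assert_that(length(absent) == 0,
              paste0("probes absent from probe table: ",
                     paste(absent, collapse = ", ")))
  keep <- rownames(probe_matrix) %in% names(map)
  if (any(!keep)) {
    inform(sprintf("dropping %d probe(s) with no gene mapping", sum(!keep)))
  }
  pm <- probe_matrix[keep, , drop = FALSE]
  gene_of <- map[rownames(pm)]
  genes <- unique(gene_of)
  counts <- table(gene_of)
  # rowsum orders groups by sort(); restore first-appearance order
  out <- rowsum(pm, gene_of)[genes, , drop = FALSE] / as.vector(counts[genes])
  expr_cohort(out, condition, cohort_id)
}

#' Read and write GMT gene-set collections
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      parse_error(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    if (parts[1] %in% names(sets)) {
      parse_error(sprintf("duplicate set name '%s' at GMT line %d", parts[1], i))
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      parse_error(sprintf("empty gene set '%s' at GMT line %d", parts[1], i))
    }
    sets[[parts[1]]] <- structure(genes, description = parts[2])
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute each).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a protein-protein interaction edge list
#'
#' Two-column TSV (with header) of undirected gene pairs. Self-loops are
#' rejected; duplicate edges (in either orientation) collapse to one.
#'
#' @param path File path.
#' @return `read_ppi()` returns a tibble of class `ppi_network` with columns
#'   `from`, `to` (lexicographically ordered within each row).
#' @export
read_ppi <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  assert_that(ncol(df) >= 2, "PPI file needs two columns")
  ppi_network(df[[1]], df[[2]])
}

#' @rdname read_ppi
#' @param from,to Character vectors of interacting gene identifiers.
#' @export
ppi_network <- function(from, to) {
  assert_that(length(from) == length(to), "edge endpoints must pair up")
  assert_that(all(from != to), "self-loops are not allowed in the PPI network")
  a <- pmin(from, to)
  b <- pmax(from, to)
  out <- dplyr::distinct(tibble::tibble(from = a, to = b))
  class(out) <- c("ppi_network", class(out))
  out
}

#' @rdname read_ppi
#' @param ppi A `ppi_network`.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(as.data.frame(ppi[c("from", "to")]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# named list: gene -> character vector of PPI partners (genes absent from the
# network get no entry, which downstream reads as "no PPI records")
ppi_partners <- function(ppi) {
  both <- tibble::tibble(gene = c(ppi$from, ppi$to),
                         partner = c(ppi$to, ppi$from))
  split(both$partner, both$gene)
}

#' Read and write a clinical table
#'
#' Fixed-header TSV: `sample_id`, `time_months`, `event`, `hpv`, `smoking`,
#' `tp53`. Missing covariates are the literal string `NA`. `time_months`
#' must be non-negative, `event` 0/1.
#'
#' @param path File path.
#' @return `read_clinical()` returns a tibble of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = "NA")
  need <- c("sample_id", "time_months", "event", "hpv", "smoking", "tp53")
  assert_that(all(need %in% names(df)),
              paste0("clinical table needs columns: ", paste(need, collapse = ", ")))
  clinical_table(tibble::tibble(
    sample_id = df$sample_id,
    time_months = as.numeric(df$time_months),
    event = as.integer(df$event),
    hpv = df$hpv,
    smoking = df$smoking,
    tp53 = as.integer(df$tp53)
  ))
}

#' @rdname read_clinical
#' @param df Data frame with the clinical columns listed above.
#' @export
clinical_table <- function(df) {
  df <- tibble::as_tibble(df)
  assert_that(!anyDuplicated(df$sample_id), "duplicate sample_id in clinical table")
  assert_that(all(df$time_months >= 0, na.rm = FALSE) && !anyNA(df$time_months),
              "time_months must be non-negative and non-missing")
  assert_that(all(df$event %in% c(0L, 1L)), "event must be 0 or 1")
  assert_that(all(df$hpv %in% c("positive", "negative") | is.na(df$hpv)),
              "hpv must be positive/negative/NA")
  assert_that(all(df$smoking %in% c("current", "non") | is.na(df$smoking)),
              "smoking must be current/non/NA")
  assert_that(all(df$tp53 %in% c(0L, 1L) | is.na(df$tp53)), "tp53 must be 0/1/NA")
  if (!inherits(df, "clinical_table")) class(df) <- c("clinical_table", class(df))
  df
}

#' @rdname read_clinical
#' @param clinical A `clinical_table`.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
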