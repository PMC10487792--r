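#' Welch's two-sample t test
#'
#' Two-sided unequal-variance t test (Welch-Satterthwaite degrees of
#' freedom), the per-gene test behind [identify_degs()]. Thin wrapper over
#' [stats::t.test()] that enforces the preconditions the pipeline relies on.
#'
#' @param tumor_values,normal_values Numeric vectors, each with at least two
#'   values; at least one group must have positive variance.
#' @return A list with elements `t`, `df` and `p` (two-sided).
#' @examples
#' welch_t(c(5, 6, 7), c(1, 2, 3)) # t = 4.899, p = 0.00805
#' @export
welch_t <- function(tumor_values, normal_values) {
  assert_that(length(tumor_values) >= 2 && length(normal_values) >= 2,
              "each group needs at least 2 values")
  if (sd(tumor_values) == 0 && sd(normal_values) == 0) {
    abort("zero variance in both groups", class = "sigforge_validation_error")
  }
  fit <- stats::t.test(tumor_values, normal_values, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Identify differentially expressed genes in one cohort
#'
#' Flags each gene as differentially expressed between tumor and normal
#' samples when both the fold-change and p-value criteria hold:
#' `|fold_change| >= fc_thresh` (inclusive, i.e. `|log2fc| >= log2(fc_thresh)`)
#' and `p < p_thresh` from a per-gene Welch t test. Fold change is
#' `2^(mean_tumor - mean_normal)` on the log2 scale (a ratio of geometric
#' means); positive `log2fc` means higher in tumor ("up-regulated"). Genes
#' where the test fails (e.g. zero variance in both groups) get `NA` p and
#' are never DEGs; a warning reports how many.
#'
#' @param cohort An [expr_cohort()] with at least two samples per condition.
#' @param fc_thresh Fold-change threshold on the linear scale (default 1.5).
#' @param p_thresh p-value threshold (default 0.05, unadjusted).
#' @return A tibble of class `deg_result` with columns `cohort_id`, `gene`,
#'   `log2fc`, `fold_change`, `p_value`, `is_deg`, `direction`
#'   (up/down/none).
#' @export
identify_degs <- function(cohort, fc_thresh = 1.5, p_thresh = 0.05) {
  stopifnot(inherits(cohort, "expr_cohort"))
  tum <- cohort_stratum(cohort, "tumor")
  nor <- cohort_stratum(cohort, "normal")
  assert_that(ncol(tum) >= 2 && ncol(nor) >= 2,
              "need >= 2 tumor and >= 2 normal samples")
  log2fc <- rowMeans(tum) - rowMeans(nor)
  p <- vapply(seq_len(nrow(tum)), function(i) {
    tryCatch(welch_t(tum[i, ], nor[i, ])$p, error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(p)) {
    warn(sprintf("%d gene(s) untestable (NA p-value); treated as non-DEG",
                 sum(is.na(p))))
  }
  res <- tibble::tibble(
    cohort_id = cohort$cohort_id,
    gene = rownames(cohort$values),
    log2fc = unname(log2fc),
    fold_change = 2^unname(log2fc),
    p_value = p
  ) |>
    dplyr::mutate(
      # inclusive FC boundary; small slack so a fold change of exactly the
      # threshold is not lost to floating-point rounding
      is_deg = !is.na(.data$p_value) & .data$p_value < p_thresh &
        abs(.data$log2fc) >= log2(fc_thresh) - 1e-10,
      direction = dplyr::case_when(
        .data$is_deg & .data$log2fc > 0 ~ "up",
        .data$is_deg ~ "down",
        TRUE ~ "none"
      )
    )
  class(res) <- c("deg_result", class(res))
  attr(res, "fc_thresh") <- fc_thresh
  attr(res, "p_thresh") <- p_thresh
  res
}

#' Intersect up-regulated genes across cohorts
#'
#' Returns the genes flagged `direction == "up"` in every supplied
#' differential-expression result — the cross-cohort reproducibility filter
#' that defines the signature candidate pool. An empty intersection is
#' returned (with a message), not an error.
#'
#' @param deg_results A list of `deg_result` tibbles from [identify_degs()].
#' @return Character vector of gene identifiers, ordered as in the first
#'   cohort.
#' @export
intersect_up <- function(deg_results) {
  if (inherits(deg_results, "deg_result")) deg_results <- list(deg_results)
  assert_that(length(deg_results) >= 1, "need at least one DEG result")
  ups <- lapply(deg_results, function(d) d$gene[d$direction == "up"])
  out <- Reduce(intersect, ups)
  if (length(out) == 0) inform("up-regulated intersection is empty")
  out
}

#' @export
#' @rdname identify_degs
#' @param x A `deg_result`.
#' @param ... Unused.
glance.deg_result <- function(x, ...) {
  tibble::tibble(
    cohort_id = x$cohort_id[1],
    n_genes = nrow(x),
    n_deg = sum(x$is_deg),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    fc_thresh = attr(x, "fc_thresh"),
    p_thresh = attr(x, "p_thresh")
  )
}
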