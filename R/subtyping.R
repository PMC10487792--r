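#' Cluster tumor samples on signature-gene expression
#'
#' Unsupervised subtype discovery: signature-gene rows are z-scored,
#' sample-sample dissimilarity is 1 minus the Spearman correlation of their
#' expression profiles over the signature genes, and average-linkage
#' agglomeration is cut at height `1 - cut_rho` (default: samples cluster
#' together above Spearman 0.7). Clusters smaller than `min_frac` of the
#' samples are merged into the cluster whose centroid correlates best with
#' theirs, so a hard correlation cut cannot shed scattered singletons.
#' Cluster ids are ordered by descending size.
#'
#' @param cohort An [expr_cohort()]; only its tumor samples are clustered.
#' @param signature Character vector of signature gene ids (constant-row
#'   genes are dropped with a warning).
#' @param cut_rho Spearman threshold for the dendrogram cut (default 0.7).
#' @param min_frac Minimum cluster size as a fraction of samples
#'   (default 0.05).
#' @return A tibble of class `subtype_result` with columns `sample`,
#'   `cluster`; attributes `n_clusters`, `cut_rho`, and `centroids` (cluster
#'   mean profiles on the z-scored matrix).
#' @export
cluster_samples <- function(cohort, signature, cut_rho = 0.7, min_frac = 0.05) {
  m <- cohort_stratum(cohort, "tumor")
  sig <- intersect(signature, rownames(m))
  assert_that(length(sig) >= 2, "need at least 2 signature genes in the cohort")
  assert_that(ncol(m) >= 2, "need at least 2 tumor samples")
  m <- m[sig, , drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant signature gene(s)", sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
    assert_that(nrow(m) >= 2, "fewer than 2 informative signature genes")
  }
  z <- t(scale(t(m)))  # per-gene z-score
  rho <- cor(z, method = "spearman")
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = "average")
  cut <- cutree(hc, h = 1 - cut_rho)
  # merge undersized clusters into the best-correlated retained centroid
  min_n <- max(1L, ceiling(min_frac * ncol(z)))
  sizes <- table(cut)
  keep <- names(sizes)[sizes >= min_n]
  if (length(keep) == 0) keep <- names(sizes)[which.max(sizes)]
  centroid <- function(ids) rowMeans(z[, cut %in% ids, drop = FALSE])
  cents <- vapply(keep, function(k) centroid(k), numeric(nrow(z)))
  for (small in setdiff(names(sizes), keep)) {
    members <- names(cut)[cut == as.integer(small)]
    sim <- cor(rowMeans(z[, members, drop = FALSE]), cents)
    cut[members] <- as.integer(keep[which.max(sim)])
  }
  sizes <- sort(table(cut), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- tibble::tibble(sample = colnames(z),
                        cluster = unname(relabel[as.character(cut)]))
  class(out) <- c("subtype_result", class(out))
  attr(out, "n_clusters") <- length(sizes)
  attr(out, "cut_rho") <- cut_rho
  attr(out, "centroids") <- vapply(
    split(out$sample, out$cluster),
    function(s) rowMeans(z[, s, drop = FALSE]), numeric(nrow(z)))
  out
}

# Haldane-Anscombe corrected odds ratio for a 2x2 table (a,b / c,d):
# add 0.5 to every cell when any is zero
odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Annotate subtypes with clinical covariate frequencies and odds ratios
#'
#' Per-cluster frequencies of HPV positivity, current smoking and TP53
#' mutation are computed over non-missing entries (a cluster with an
#' all-missing covariate gets `NA`). For each binary covariate, pairwise
#' cluster-versus-cluster odds ratios are computed from the 2x2 table with
#' the Haldane correction (0.5 added to every cell) when any cell is zero.
#'
#' @param subtypes A `subtype_result` from [cluster_samples()].
#' @param clinical A `clinical_table` covering the clustered samples
#'   (missing covariates allowed).
#' @return A list with tibbles `frequencies` (cluster, n, hpv_positive,
#'   smoking_current, tp53_mutant) and `odds_ratios` (covariate, cluster_a,
#'   cluster_b, odds_ratio).
#' @export
annotate_subtypes <- function(subtypes, clinical) {
  joined <- dplyr::inner_join(subtypes, clinical,
                              by = c(sample = "sample_id"))
  assert_that(nrow(joined) > 0, "clinical table covers none of the samples")
  bin <- function(x, positive) ifelse(is.na(x), NA, as.integer(x == positive))
  joined <- joined |>
    dplyr::mutate(hpv_positive = bin(.data$hpv, "positive"),
                  smoking_current = bin(.data$smoking, "current"),
                  tp53_mutant = as.integer(.data$tp53))
  freqs <- joined |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(c("hpv_positive", "smoking_current", "tp53_mutant"),
                    ~ mean(.x, na.rm = TRUE))
    ) |>
    dplyr::mutate(dplyr::across(-c("cluster", "n"), ~ ifelse(is.nan(.x), NA, .x)))
  clusters <- sort(unique(joined$cluster))
  if (length(clusters) < 2) {
    return(list(frequencies = freqs,
                odds_ratios = tibble::tibble(covariate = character(0),
                                             cluster_a = integer(0),
                                             cluster_b = integer(0),
                                             odds_ratio = numeric(0))))
  }
  ors <- purrr::map_dfr(c("hpv_positive", "smoking_current", "tp53_mutant"),
    function(cov) {
      purrr::map_dfr(utils::combn(clusters, 2, simplify = FALSE), function(pr) {
        xa <- joined[[cov]][joined$cluster == pr[1]]
        xb <- joined[[cov]][joined$cluster == pr[2]]
        a <- sum(xa == 1, na.rm = TRUE); b <- sum(xa == 0, na.rm = TRUE)
        c <- sum(xb == 1, na.rm = TRUE); d <- sum(xb == 0, na.rm = TRUE)
        tibble::tibble(covariate = cov, cluster_a = pr[1], cluster_b = pr[2],
                       odds_ratio = if ((a + b) == 0 || (c + d) == 0) NA_real_
                                    else odds_ratio(a, b, c, d))
      })
    })
  list(frequencies = freqs, odds_ratios = ors)
}

#' Per-gene fold change of each subtype versus pooled normals
#'
#' @param cohort The [expr_cohort()] the subtypes were derived from.
#' @param subtypes A `subtype_result`.
#' @param genes Genes to report (default: all cohort genes).
#' @return A tibble with columns `gene`, `cluster`, `log2fc`, `fold_change`.
#' @export
subtype_fold_changes <- function(cohort, subtypes,
                                 genes = rownames(cohort$values)) {
  nor <- cohort_stratum(cohort, "normal")
  assert_that(ncol(nor) >= 1, "cohort has no normal samples")
  base <- rowMeans(nor[genes, , drop = FALSE])
  purrr::map_dfr(split(subtypes$sample, subtypes$cluster), function(samps) {
    lfc <- rowMeans(cohort$values[genes, samps, drop = FALSE]) - base
    tibble::tibble(gene = genes, log2fc = unname(lfc),
                   fold_change = 2^unname(lfc))
  }, .id = "cluster") |>
    dplyr::mutate(cluster = as.integer(.data$cluster)) |>
    dplyr::relocate("gene")
}

#' @export
#' @rdname cluster_samples
#' @param x A `subtype_result`.
#' @param ... Unused.
glance.subtype_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_clusters = attr(x, "n_clusters"),
    cut_rho = attr(x, "cut_rho"),
    largest = max(table(x$cluster)),
    smallest = min(table(x$cluster))
  )
}
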