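#' Pipeline configuration
#'
#' All thresholds of the signature-discovery pipeline in one place. The
#' defaults are the canonical published values: fold change 1.5 with
#' unadjusted p < 0.05 for differential expression, Spearman 0.6 for the
#' gene dendrogram cut, Spearman 0.7 for the sample dendrogram cut,
#' co-expression thresholds 0.5 (with PPI partners) and 0.7 (fallback
#' without PPI records), enrichment gate p < 0.05 with at least 3 members,
#' and a 60-month survival horizon.
#'
#' @param fc_thresh Fold-change threshold (linear scale).
#' @param p_thresh DEG p-value threshold.
#' @param gene_cut_rho Spearman cut for gene grouping.
#' @param sample_cut_rho Spearman cut for sample subtyping.
#' @param nig_r,ncg_r Co-expression thresholds for the interactor counts.
#' @param enrich_p,min_members Enrichment eligibility gate.
#' @param min_frac Minimum subtype size as a fraction of samples.
#' @param horizon Survival horizon in months.
#' @param pcc_stratum Sample stratum for all correlations (`"tumor"`,
#'   `"normal"` or `"all"`).
#' @param ps_raw_sum Use raw (unscaled) perturbation-score components.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_thresh = 1.5, p_thresh = 0.05,
                            gene_cut_rho = 0.6, sample_cut_rho = 0.7,
                            nig_r = 0.5, ncg_r = 0.7,
                            enrich_p = 0.05, min_members = 3,
                            min_frac = 0.05, horizon = 60,
                            pcc_stratum = "tumor", ps_raw_sum = FALSE) {
  assert_that(fc_thresh >= 1, "fc_thresh must be >= 1")
  assert_that(p_thresh > 0 && p_thresh <= 1, "p_thresh must be in (0,1]")
  assert_that(gene_cut_rho <= 1 && sample_cut_rho <= 1,
              "correlation cuts cannot exceed 1")
  assert_that(nig_r >= 0 && nig_r <= 1 && ncg_r >= 0 && ncg_r <= 1,
              "co-expression thresholds must be in [0,1]")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full signature-discovery pipeline
#'
#' Orchestrates every stage: per-cohort differential expression, the
#' cross-cohort up-regulated intersection, the cluster-score matrix and
#' gene grouping, GOBP enrichment gating (hallmark/pathway enrichments are
#' reported but never gate), representative and perturbation scoring,
#' signature selection, subtype clustering of the validation cohort,
#' clinical annotation and pairwise survival comparison. Counts at each
#' stage are collected in the `log` element. Degenerate configurations
#' (e.g. an empty DEG intersection) return early with an empty signature
#' and a warning rather than failing.
#'
#' @param cohorts List of discovery [expr_cohort()]s.
#' @param validation The [expr_cohort()] to subtype.
#' @param go List with `dags` and `annotations` (as from [generate_go()] or
#'   [read_obo()] + [read_annotations()]).
#' @param ppi A `ppi_network`.
#' @param clinical A `clinical_table` for the validation tumors (optional:
#'   `NULL` skips the survival stage).
#' @param hallmarks Optional gene-set collection for reporting enrichment.
#' @param config A [pipeline_config()].
#' @return A list of class `sig_pipeline` with elements `deg_results`,
#'   `candidates`, `cs`, `grouping`, `enrichment_gobp`, `eligible`,
#'   `signature`, `signature_genes`, `subtypes`, `annotation`, `survival`,
#'   `enrichment_hallmarks`, `log`.
#' @export
run_pipeline <- function(cohorts, validation, go, ppi, clinical = NULL,
                         hallmarks = NULL, config = pipeline_config()) {
  log <- list()
  deg_results <- lapply(cohorts, identify_degs,
                        fc_thresh = config$fc_thresh,
                        p_thresh = config$p_thresh)
  log$deg_per_cohort <- vapply(deg_results, function(d) sum(d$is_deg), integer(1))
  candidates <- intersect_up(deg_results)
  log$n_candidates <- length(candidates)
  empty <- function(reason) {
    warn(paste0("pipeline stopped early: ", reason))
    structure(list(deg_results = deg_results, candidates = candidates,
                   cs = NULL, grouping = NULL, enrichment_gobp = NULL,
                   eligible = integer(0), signature = NULL,
                   signature_genes = character(0), subtypes = NULL,
                   annotation = NULL, survival = NULL,
                   enrichment_hallmarks = NULL, log = log),
              class = "sig_pipeline")
  }
  if (length(candidates) < 2) return(empty("fewer than 2 shared up-regulated genes"))

  cs <- cs_matrix(candidates, go$dags, go$annotations, cohorts,
                  stratum = config$pcc_stratum)
  grouping <- cluster_genes(cs, cut_rho = config$gene_cut_rho)
  log$n_groups <- attr(grouping, "n_groups")

  gobp_sets <- annotation_gene_sets(go$dags$BP, go$annotations$BP)
  universe <- names(go$annotations$BP)[lengths(go$annotations$BP) > 0]
  gate_grouping <- grouping[grouping$gene %in% universe, ]
  if (nrow(gate_grouping) == 0) return(empty("no candidate has GOBP annotations"))
  enrichment_gobp <- enrich_groups(gate_grouping, gobp_sets, universe)
  eligible <- eligible_groups(enrichment_gobp, config$enrich_p,
                              config$min_members)
  sizes <- table(grouping$group)
  eligible <- eligible[sizes[as.character(eligible)] >= 2]
  log$n_eligible_groups <- length(eligible)
  if (length(eligible) == 0) return(empty("no group passes the enrichment gate"))

  elig_grouping <- grouping[grouping$group %in% eligible, ]
  rs <- representative_scores(cs, elig_grouping)
  ps <- perturbation_scores(elig_grouping$gene, cohorts, ppi, deg_results,
                            nig_r = config$nig_r, ncg_r = config$ncg_r,
                            stratum = config$pcc_stratum,
                            raw_sum = config$ps_raw_sum)
  signature <- select_signature(rs, ps)
  sig_genes <- signature_genes(signature)
  log$n_signature <- length(sig_genes)

  enrichment_hallmarks <- NULL
  if (!is.null(hallmarks)) {
    hm_universe <- unique(unlist(hallmarks))
    hm_grouping <- grouping[grouping$gene %in% hm_universe, ]
    if (nrow(hm_grouping) > 0) {
      enrichment_hallmarks <- enrich_groups(hm_grouping, hallmarks, hm_universe)
    }
  }

  subtypes <- NULL; annotation <- NULL; surv <- NULL
  if (!is.null(validation) && length(sig_genes) >= 2) {
    subtypes <- cluster_samples(validation, sig_genes,
                                cut_rho = config$sample_cut_rho,
                                min_frac = config$min_frac)
    log$n_subtypes <- attr(subtypes, "n_clusters")
    if (!is.null(clinical)) {
      annotation <- annotate_subtypes(subtypes, clinical)
      surv <- survival_compare(subtypes, clinical, horizon = config$horizon)
    }
  }
  structure(
    list(deg_results = deg_results, candidates = candidates, cs = cs,
         grouping = grouping, enrichment_gobp = enrichment_gobp,
         eligible = eligible, signature = signature,
         signature_genes = sig_genes, subtypes = subtypes,
         annotation = annotation, survival = surv,
         enrichment_hallmarks = enrichment_hallmarks, log = log),
    class = "sig_pipeline")
}

#' @export
print.sig_pipeline <- function(x, ...) {
  cat("<sig_pipeline>\n")
  cat("  candidates (up in all cohorts):", length(x$candidates), "\n")
  if (!is.null(x$grouping)) {
    cat("  gene groups:", attr(x$grouping, "n_groups"),
        "| eligible:", length(x$eligible), "\n")
  }
  cat("  signature genes:", length(x$signature_genes), "\n")
  if (!is.null(x$subtypes)) {
    cat("  subtypes:", attr(x$subtypes, "n_clusters"), "\n")
  }
  invisible(x)
}

#' @export
#' @rdname run_pipeline
#' @param x A `sig_pipeline`.
#' @param ... Unused.
glance.sig_pipeline <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$candidates),
    n_groups = if (is.null(x$grouping)) NA_integer_ else attr(x$grouping, "n_groups"),
    n_eligible = length(x$eligible),
    n_signature = length(x$signature_genes),
    n_subtypes = if (is.null(x$subtypes)) NA_integer_ else attr(x$subtypes, "n_clusters")
  )
}
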