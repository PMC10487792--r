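#' Pearson correlation of two genes in a cohort stratum
#'
#' Correlation of expression across samples of one stratum (tumor by
#' default: co-expression is assessed in the disease context). Zero-variance
#' genes yield 0 with a warning rather than `NA`.
#'
#' @param cohort An [expr_cohort()].
#' @param gene_i,gene_j Gene identifiers present in the cohort.
#' @param stratum `"tumor"`, `"normal"` or `"all"`.
#' @return A numeric value in \[-1, 1\].
#' @export
pcc <- function(cohort, gene_i, gene_j, stratum = "tumor") {
  m <- cohort_stratum(cohort, stratum)
  assert_that(all(c(gene_i, gene_j) %in% rownames(m)),
              "gene not present in cohort")
  assert_that(ncol(m) >= 3, "need at least 3 samples in the stratum")
  x <- m[gene_i, ]; y <- m[gene_j, ]
  if (sd(x) == 0 || sd(y) == 0) {
    warn(sprintf("zero variance for %s/%s; correlation set to 0", gene_i, gene_j))
    return(0)
  }
  unname(cor(x, y))
}

# full gene x gene Pearson matrix over a stratum; zero-variance rows -> 0
pcc_matrix <- function(cohort, genes, stratum = "tumor") {
  m <- cohort_stratum(cohort, stratum)
  assert_that(all(genes %in% rownames(m)), "gene not present in cohort")
  sub <- t(m[genes, , drop = FALSE])
  sds <- apply(sub, 2, sd)
  r <- suppressWarnings(cor(sub))
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance gene(s); their correlations set to 0",
                 sum(sds == 0)))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Cluster score between two genes
#'
#' The functional-coherence score combining ontology similarity and
#' co-expression:
#' \deqn{CS_{ij} = \frac{RSS^{BP}_{ij} + RSS^{CC}_{ij}}{2}
#'   + \frac{1}{N}\sum_{n=1}^{N} PCC^{(n)}_{ij}}
#' where the RSS terms are gene-level relative specificity similarities
#' ([rss_gene()]) in the biological-process and cellular-component
#' namespaces and the PCC term averages the Pearson co-expression of the
#' pair over the `N` cohorts. Range \[-1, 2\].
#'
#' @param gene_i,gene_j Gene identifiers.
#' @param dags Named list of [go_dag()]s with elements `BP` and `CC`.
#' @param annotations Named list of annotation maps, elements `BP` and `CC`.
#' @param cohorts List of [expr_cohort()]s.
#' @param stratum Sample stratum for the correlations (default `"tumor"`).
#' @return A numeric value in \[-1, 2\].
#' @export
cluster_score <- function(gene_i, gene_j, dags, annotations, cohorts,
                          stratum = "tumor") {
  rss_bp <- rss_gene(dags$BP, annotations$BP, gene_i, gene_j)
  rss_cc <- rss_gene(dags$CC, annotations$CC, gene_i, gene_j)
  r <- vapply(cohorts, function(co) pcc(co, gene_i, gene_j, stratum), numeric(1))
  (rss_bp + rss_cc) / 2 + mean(r)
}

#' Cluster-score matrix for a set of genes
#'
#' Computes [cluster_score()] for every gene pair; the diagonal is fixed at
#' 2 (a gene's similarity to itself: both RSS terms 1 and correlation 1).
#'
#' @inheritParams cluster_score
#' @param genes Character vector of gene identifiers (all present in every
#'   cohort).
#' @return A symmetric numeric matrix of class `cs_matrix` with `genes` as
#'   dimnames, off-diagonal entries in \[-1, 2\] and diagonal 2.
#' @export
cs_matrix <- function(genes, dags, annotations, cohorts, stratum = "tumor") {
  n <- length(genes)
  assert_that(n >= 2, "need at least 2 genes")
  rss_part <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- (rss_gene(dags$BP, annotations$BP, genes[i], genes[j]) +
            rss_gene(dags$CC, annotations$CC, genes[i], genes[j])) / 2
    rss_part[i, j] <- v
    rss_part[j, i] <- v
  }
  pcc_part <- Reduce(`+`, lapply(cohorts, pcc_matrix, genes = genes,
                                 stratum = stratum)) / length(cohorts)
  cs <- rss_part + pcc_part
  diag(cs) <- 2
  class(cs) <- c("cs_matrix", class(cs))
  cs
}

#' Group genes by hierarchical clustering of cluster-score profiles
#'
#' The dissimilarity between two genes is 1 minus the Spearman correlation
#' of their cluster-score matrix rows, excluding the two self-entries of the
#' pair. Average-linkage agglomeration is cut at height `1 - cut_rho`, so
#' genes stay together when their score profiles correlate above `cut_rho`.
#'
#' @param cs A [cs_matrix()].
#' @param cut_rho Spearman correlation threshold for the dendrogram cut
#'   (default 0.6).
#' @return A tibble of class `cluster_grouping` with columns `gene`,
#'   `group` (integer ids ordered by group size, largest first), and
#'   attributes `n_groups` and `cut_rho`.
#' @export
cluster_genes <- function(cs, cut_rho = 0.6) {
  genes <- rownames(cs)
  n <- length(genes)
  assert_that(n >= 2, "need at least 2 genes")
  d <- matrix(0, n, n, dimnames = list(genes, genes))
  constant_seen <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    xi <- cs[i, keep]; xj <- cs[j, keep]
    if (length(keep) < 2 || sd(xi) == 0 || sd(xj) == 0) {
      constant_seen <- constant_seen || (length(keep) >= 2)
      rho <- 0
    } else {
      rho <- cor(xi, xj, method = "spearman")
    }
    d[i, j] <- d[j, i] <- 1 - rho
  }
  if (constant_seen) warn("constant cluster-score rows; dissimilarity set to 1")
  hc <- hclust(as.dist(d), method = "average")
  cut <- cutree(hc, h = 1 - cut_rho)
  # relabel ids by descending group size (ties by first appearance)
  sizes <- sort(table(cut), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- tibble::tibble(gene = genes, group = unname(relabel[as.character(cut)]))
  class(out) <- c("cluster_grouping", class(out))
  attr(out, "n_groups") <- length(sizes)
  attr(out, "cut_rho") <- cut_rho
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' `P(X >= k)` where `X` counts members of a gene set drawn when sampling
#' `|group|` genes without replacement from the universe.
#'
#' @param k Observed overlap between group and set.
#' @param group_size Number of genes drawn (the group size).
#' @param set_size Number of universe genes in the set.
#' @param universe_size Total universe size.
#' @return Upper-tail p-value in (0, 1\].
#' @export
hypergeom_test <- function(k, group_size, set_size, universe_size) {
  assert_that(universe_size >= 1, "empty universe")
  phyper(k - 1, set_size, universe_size - set_size, group_size,
         lower.tail = FALSE)
}

#' Gene-set enrichment of gene groups
#'
#' Tests every (group, set) pair with the upper-tail hypergeometric test
#' against a fixed universe. Raw p-values are reported (no multiplicity
#' adjustment): the downstream eligibility gate uses the unadjusted 0.05
#' threshold.
#'
#' @param grouping A `cluster_grouping` tibble (columns `gene`, `group`), or
#'   any data frame with those columns.
#' @param collection Named list of gene sets (as from [read_gmt()]).
#' @param universe Character vector of background genes; groups must be
#'   subsets of it. Defaults to all genes appearing in `collection`.
#' @return A tibble of class `enrichment_result` with columns `group`,
#'   `set`, `k` (group members in the set), `set_size`, `group_size`, `p`.
#' @export
enrich_groups <- function(grouping, collection,
                          universe = unique(unlist(collection))) {
  assert_that(length(universe) >= 1, "empty universe")
  assert_that(all(grouping$gene %in% universe),
              "every group must be a subset of the universe")
  sets_u <- lapply(collection, intersect, y = universe)
  by_group <- split(grouping$gene, grouping$group)
  out <- purrr::map_dfr(names(by_group), function(g) {
    members <- by_group[[g]]
    tibble::tibble(
      group = as.integer(g),
      set = names(collection),
      k = vapply(sets_u, function(s) length(intersect(members, s)), integer(1),
                 USE.NAMES = FALSE),
      set_size = unname(lengths(sets_u)),
      group_size = length(members)
    )
  })
  out$p <- unname(hypergeom_test(out$k, out$group_size, out$set_size,
                                 length(universe)))
  class(out) <- c("enrichment_result", class(out))
  attr(out, "universe_size") <- length(universe)
  out
}

#' Eligible groups under the enrichment gate
#'
#' A group is eligible when at least one tested set (GOBP terms in the
#' canonical pipeline) is enriched at `p < p_thresh` with at least
#' `min_members` of the group's genes in that set.
#'
#' @param enrichment An `enrichment_result` from [enrich_groups()].
#' @param p_thresh Enrichment p-value threshold (default 0.05).
#' @param min_members Minimum group members in the enriched set (default 3).
#' @return Sorted integer vector of eligible group ids.
#' @export
eligible_groups <- function(enrichment, p_thresh = 0.05, min_members = 3) {
  hit <- enrichment$p < p_thresh & enrichment$k >= min_members
  sort(unique(enrichment$group[hit]))
}

#' Representative scores within cluster groups
#'
#' For gene *i* in a group of `M` genes the representative score is
#' \deqn{RS_i = \frac{\sum_{j \ne i} CS_{ij}}{2M}} summing cluster scores
#' over the gene's co-members (the self pair, a constant 2, is excluded).
#' High RS marks the genes most functionally central to their group.
#'
#' @param cs A [cs_matrix()] covering all grouped genes.
#' @param grouping Data frame with columns `gene`, `group`; every group must
#'   have at least 2 members (RS is undefined for singletons).
#' @return A tibble with columns `gene`, `group`, `rs`.
#' @export
representative_scores <- function(cs, grouping) {
  assert_that(all(grouping$gene %in% rownames(cs)),
              "grouping genes missing from the cluster-score matrix")
  sizes <- table(grouping$group)
  assert_that(all(sizes >= 2),
              "representative score undefined for singleton groups")
  grouping |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(rs = {
      members <- .data$gene
      m <- length(members)
      vapply(members, function(g) {
        sum(cs[g, setdiff(members, g)]) / (2 * m)
      }, numeric(1), USE.NAMES = FALSE)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "group", "rs")
}

#' Co-expressed-interactor counts for the perturbation score
#'
#' `nig()` counts the PPI partners of a gene whose tumor-stratum Pearson
#' correlation with it reaches `r_thresh` in absolute value (default 0.5).
#' `ncg()` is the fallback for genes with no PPI records at all: the number
#' of all other cohort genes co-expressed at `|r| >= r_thresh` (default
#' 0.7); it is 0 by definition for genes that do have PPI records.
#'
#' @param gene Gene identifier.
#' @param cohort An [expr_cohort()].
#' @param ppi A `ppi_network` (see [ppi_network()]).
#' @param r_thresh Absolute-correlation threshold.
#' @param stratum Sample stratum for the correlations.
#' @return A non-negative integer count.
#' @export
nig <- function(gene, cohort, ppi, r_thresh = 0.5, stratum = "tumor") {
  partners <- ppi_partners(ppi)[[gene]] %||% character(0)
  partners <- intersect(partners, rownames(cohort$values))
  if (length(partners) == 0) return(0L)
  r <- vapply(partners, function(p) {
    suppressWarnings(pcc(cohort, gene, p, stratum))
  }, numeric(1))
  sum(abs(r) >= r_thresh)
}

#' @rdname nig
#' @export
ncg <- function(gene, cohort, ppi, r_thresh = 0.7, stratum = "tumor") {
  if (gene %in% names(ppi_partners(ppi))) return(0L)
  others <- setdiff(rownames(cohort$values), gene)
  if (length(others) == 0) return(0L)
  m <- cohort_stratum(cohort, stratum)
  x <- m[gene, ]
  if (sd(x) == 0) return(0L)
  r <- suppressWarnings(as.vector(cor(x, t(m[others, , drop = FALSE]))))
  r[is.na(r)] <- 0
  sum(abs(r) >= r_thresh)
}

#' Perturbation scores
#'
#' Summarises how strongly each candidate gene is dysregulated and how much
#' co-expressed interaction context it perturbs. Per cohort, four
#' components are combined: `NFC` (absolute log2 fold change, min-max
#' rescaled to \[0, 1\] across the scored genes), `NP` (`1 - p` from the
#' differential-expression test, so stronger significance scores higher),
#' `NIG` and `NCG` (the [nig()]/[ncg()] counts, each divided by its
#' per-cohort maximum). The four rescaled components are summed to a
#' per-cohort score; per-cohort scores are converted to ascending rank
#' fractions, averaged across cohorts, and min-max normalised so the final
#' score spans \[0, 1\]. With `raw_sum = TRUE` the per-cohort score is
#' instead the unscaled sum `|FC| + p + NIG + NCG` of the raw quantities.
#'
#' @param genes Character vector of genes to score.
#' @param cohorts List of [expr_cohort()]s.
#' @param ppi A `ppi_network`.
#' @param deg_results List of `deg_result` tibbles aligned with `cohorts`.
#' @param nig_r,ncg_r Correlation thresholds for [nig()] and [ncg()].
#' @param stratum Sample stratum for the correlations.
#' @param raw_sum Use the unscaled component sum per cohort (default FALSE).
#' @return A tibble with columns `gene`, `ps` (in \[0, 1\]) plus the
#'   per-cohort components `nfc`, `np`, `nig`, `ncg` nested in the
#'   `components` attribute.
#' @export
perturbation_scores <- function(genes, cohorts, ppi, deg_results,
                                nig_r = 0.5, ncg_r = 0.7, stratum = "tumor",
                                raw_sum = FALSE) {
  assert_that(length(cohorts) == length(deg_results),
              "one DEG result per cohort required")
  if (length(genes) == 1) {
    inform("single gene: perturbation score is 1 by convention")
    return(tibble::tibble(gene = genes, ps = 1))
  }
  comp <- purrr::map2_dfr(cohorts, deg_results, function(co, deg) {
    idx <- match(genes, deg$gene)
    assert_that(!anyNA(idx), "every gene must appear in every DEG result")
    p_raw <- deg$p_value[idx]
    p_raw[is.na(p_raw)] <- 1
    nig_n <- vapply(genes, nig, numeric(1),
                    cohort = co, ppi = ppi, r_thresh = nig_r, stratum = stratum)
    ncg_n <- vapply(genes, ncg, numeric(1),
                    cohort = co, ppi = ppi, r_thresh = ncg_r, stratum = stratum)
    tibble::tibble(
      cohort_id = co$cohort_id, gene = genes,
      nfc_raw = abs(deg$log2fc[idx]), p_raw = p_raw,
      nig = nig_n, ncg = ncg_n
    )
  })
  per_cohort <- comp |>
    dplyr::group_by(.data$cohort_id) |>
    dplyr::mutate(
      ps_cohort = if (raw_sum) {
        2^.data$nfc_raw + .data$p_raw + .data$nig + .data$ncg
      } else {
        rescale01(.data$nfc_raw, constant = 1) + (1 - .data$p_raw) +
          (if (max(.data$nig) > 0) .data$nig / max(.data$nig) else .data$nig * 0) +
          (if (max(.data$ncg) > 0) .data$ncg / max(.data$ncg) else .data$ncg * 0)
      },
      rank_frac = rank_fraction(.data$ps_cohort)
    ) |>
    dplyr::ungroup()
  out <- per_cohort |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ps = mean(.data$rank_frac)) |>
    dplyr::mutate(ps = rescale01(.data$ps, constant = 1)) |>
    dplyr::arrange(match(.data$gene, genes))
  attr(out, "components") <- per_cohort
  out
}

#' Per-group selection count
#'
#' How many genes to keep from a group of size `G` when the smallest group
#' among all eligible groups has `min_g` members:
#' \deqn{SC = \frac{G - min(G)}{min(G)} + min(G)} rounded half-up and capped
#' at `G`. The smallest group keeps all its members; larger groups grow the
#' quota sub-linearly.
#'
#' @param G Group size (integer, `>= min_g`).
#' @param min_g Minimum group size among eligible groups (integer `>= 1`).
#' @return An integer in `[min_g, G]`.
#' @examples
#' sc_count(5, 5)  # 5
#' sc_count(55, 5) # 15
#' @export
sc_count <- function(G, min_g) {
  assert_that(min_g >= 1, "min_g must be >= 1")
  assert_that(G >= min_g, "G must be at least min_g")
  min(G, round_half_up((G - min_g) / min_g + min_g))
}

#' Select the signature genes
#'
#' Within each eligible group, representative scores are min-max rescaled to
#' \[0, 1\] (they can be negative when co-expression is negative; a
#' degenerate all-equal group rescales to 1), combined with the perturbation
#' score as a geometric mean `sqrt(RS01 * PS)`, and the top [sc_count()]
#' genes are kept (ties broken lexicographically by gene id). The union of
#' the per-group selections is the signature.
#'
#' @param rs_scores Tibble from [representative_scores()] (columns `gene`,
#'   `group`, `rs`), restricted to eligible groups.
#' @param ps_scores Tibble from [perturbation_scores()] (columns `gene`, `ps`).
#' @param min_g Minimum group size used in [sc_count()]; defaults to the
#'   smallest group present in `rs_scores`.
#' @return A tibble of class `signature_set` with columns `group`, `gene`,
#'   `rs`, `ps`, `rs01`, `combined`, `rank`, `selected`; attribute `sc` maps
#'   group id to its selection count. Use [signature_genes()] for the union.
#' @export
select_signature <- function(rs_scores, ps_scores,
                             min_g = min(table(rs_scores$group))) {
  assert_that(all(rs_scores$gene %in% ps_scores$gene),
              "every scored gene needs a perturbation score")
  out <- rs_scores |>
    dplyr::left_join(ps_scores[c("gene", "ps")], by = "gene") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      rs01 = rescale01(.data$rs, constant = 1),
      combined = sqrt(.data$rs01 * .data$ps)
    ) |>
    dplyr::arrange(dplyr::desc(.data$combined), .data$gene, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      # groups below the reference minimum keep all members (quota capped
      # at the group size)
      selected = .data$rank <= sc_count(max(dplyr::n(), min_g), min_g) &
        .data$rank <= dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$rank)
  class(out) <- c("signature_set", class(out))
  attr(out, "min_g") <- min_g
  attr(out, "sc") <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(sc = sum(.data$selected)) |>
    tibble::deframe()
  out
}

#' @rdname select_signature
#' @param signature A `signature_set`.
#' @export
signature_genes <- function(signature) {
  unique(signature$gene[signature$selected])
}

#' @export
#' @rdname select_signature
#' @param x A `signature_set`.
#' @param ... Unused.
glance.signature_set <- function(x, ...) {
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$group),
    n_candidates = nrow(x),
    n_selected = sum(x$selected),
    min_g = attr(x, "min_g")
  )
}
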