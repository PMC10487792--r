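#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The defaults emulate the
#' design the pipeline targets: three discovery tumor/normal cohorts
#' sharing planted up-regulated genes organised in correlated functional
#' modules, a larger validation cohort whose tumors fall into three
#' molecular subtypes with distinct covariate frequencies, and exponential
#' survival with subtype-specific hazard ratios.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_cohorts Number of discovery cohorts (default 3).
#' @param genes_total Total genes simulated (default 2000).
#' @param n_modules,module_size Planted co-expression/function modules
#'   (default 10 modules of 10 genes).
#' @param n_up_deg Number of planted up-regulated genes; the first
#'   `n_up_deg` module genes are dysregulated (default: all module genes).
#' @param log2fc_mean,log2fc_sd Mean and per-gene jitter of the planted
#'   tumor-vs-normal shift on the log2 scale (default 1.5 / 0.25).
#' @param noise_sd Residual expression noise SD on the log2 scale
#'   (default 0.5).
#' @param tumor_n,normal_n Samples per discovery cohort (default 60 / 20).
#' @param within_module_corr Target pairwise Pearson correlation of module
#'   co-members, induced by a shared latent factor with loading
#'   `noise_sd * sqrt(rho / (1 - rho))` (default 0.6).
#' @param n_subtypes,subtype_props Number of tumor subtypes and their
#'   proportions (default 3; 0.40/0.35/0.25).
#' @param subtype_shift Log2 contrast of the subtype-marker modules: a
#'   module is up-shifted by this amount in the tumors of its own subtype
#'   and down-shifted by half of it in the other subtypes (default 2.5).
#' @param hazard_ratios Per-subtype hazard ratios, last subtype as the
#'   reference (default 1.39, 1.36, 1).
#' @param covariate_freqs Per-subtype frequencies for the clinical
#'   covariates, a list with elements `hpv`, `smoking`, `tp53`.
#' @param censor_rate Target fraction of censored observations under
#'   independent uniform censoring (default 0.3).
#' @param baseline_median_months Median survival of the reference subtype
#'   (default 30).
#' @param validation_tumor_n,validation_normal_n Validation cohort size
#'   (default 345 tumors / 44 normals).
#' @param discovery_subtype_atten Attenuation factor applied to the subtype
#'   contrast in the discovery cohorts (default 0.1): the validation cohort
#'   carries the full contrast for subtype discovery, while the discovery
#'   cohorts remain dominated by functional-module co-expression, which is
#'   what their gene grouping stage consumes.
#' @param ppi_p_in,ppi_p_out Within-module and background PPI edge
#'   probabilities (default 0.6 / 0.002).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cohorts = 3L,
                       genes_total = 2000L,
                       n_modules = 10L,
                       module_size = 10L,
                       n_up_deg = n_modules * module_size,
                       log2fc_mean = 1.5,
                       log2fc_sd = 0.25,
                       noise_sd = 0.5,
                       tumor_n = 60L,
                       normal_n = 20L,
                       within_module_corr = 0.6,
                       n_subtypes = 3L,
                       subtype_props = c(0.40, 0.35, 0.25),
                       subtype_shift = 2.5,
                       hazard_ratios = c(1.39, 1.36, 1),
                       covariate_freqs = list(
                         hpv = c(0.057, 0.022, 0.67),
                         smoking = c(0.43, 0.15, 0.12),
                         tp53 = c(0.72, 0.72, 0.54)),
                       censor_rate = 0.3,
                       baseline_median_months = 30,
                       validation_tumor_n = 345L,
                       validation_normal_n = 44L,
                       discovery_subtype_atten = 0.1,
                       ppi_p_in = 0.6,
                       ppi_p_out = 0.002) {
  cfg <- as.list(environment())
  assert_that(abs(sum(subtype_props) - 1) < 1e-8, "subtype_props must sum to 1")
  assert_that(length(subtype_props) == n_subtypes &&
                length(hazard_ratios) == n_subtypes,
              "per-subtype vectors must have n_subtypes entries")
  assert_that(n_modules * module_size <= genes_total,
              "module genes cannot exceed genes_total")
  assert_that(n_up_deg <= n_modules * module_size,
              "planted DEGs must belong to modules")
  assert_that(within_module_corr > 0 && within_module_corr < 1,
              "within_module_corr must be in (0,1)")
  assert_that(censor_rate >= 0 && censor_rate < 1, "censor_rate in [0,1)")
  assert_that(all(unlist(covariate_freqs) >= 0 & unlist(covariate_freqs) <= 1),
              "covariate frequencies must be in [0,1]")
  assert_that(all(lengths(covariate_freqs) == n_subtypes),
              "covariate frequencies must have n_subtypes entries")
  assert_that(all(hazard_ratios > 0), "hazard ratios must be positive")
  structure(cfg, class = "sim_config")
}

# deterministic sub-seeds so each generator is reproducible standalone
sub_seed <- function(config, offset) (config$seed %% 10^7) * 100 + offset

#' Plant the ground truth of a simulated study
#'
#' Draws the fixed latent structure every generator shares: gene
#' identifiers, module membership, which module genes are dysregulated,
#' which modules define each subtype, and the subtype of every tumor sample
#' (discovery and validation cohorts).
#'
#' @param config A [sim_config()].
#' @return A list of class `ground_truth` with elements `genes`,
#'   `module_of` (named integer vector over module genes), `true_up_degs`,
#'   `module_subtype` (module id -> subtype it marks), `subtype_of` (named
#'   integer vector over all tumor sample ids), `true_hr`, and the sample
#'   id layout per cohort.
#' @export
plant_truth <- function(config) {
  set.seed(sub_seed(config, 1))
  genes <- sprintf("g%04d", seq_len(config$genes_total))
  module_genes <- genes[seq_len(config$n_modules * config$module_size)]
  module_of <- setNames(rep(seq_len(config$n_modules), each = config$module_size),
                        module_genes)
  true_up_degs <- module_genes[seq_len(config$n_up_deg)]
  module_subtype <- setNames(
    rep(seq_len(config$n_subtypes), length.out = config$n_modules),
    seq_len(config$n_modules))
  cohort_ids <- sprintf("cohort%d", seq_len(config$n_cohorts))
  samples <- lapply(seq_len(config$n_cohorts), function(k) {
    list(tumor = sprintf("c%d_t%03d", k, seq_len(config$tumor_n)),
         normal = sprintf("c%d_n%03d", k, seq_len(config$normal_n)))
  })
  names(samples) <- cohort_ids
  samples$validation <- list(
    tumor = sprintf("va_t%03d", seq_len(config$validation_tumor_n)),
    normal = sprintf("va_n%03d", seq_len(config$validation_normal_n)))
  # proportional (largest-remainder) subtype quota within each cohort, then
  # shuffled: every cohort represents the subtype mix, so cross-cohort
  # fold changes are not distorted by sampling drift in the mix
  quota_draw <- function(n) {
    base <- floor(n * config$subtype_props)
    rem <- n - sum(base)
    frac <- n * config$subtype_props - base
    if (rem > 0) {
      top <- order(frac, decreasing = TRUE)[seq_len(rem)]
      base[top] <- base[top] + 1L
    }
    sample(rep(seq_len(config$n_subtypes), base))
  }
  subtype_of <- unlist(lapply(samples, function(s) {
    setNames(quota_draw(length(s$tumor)), s$tumor)
  }))
  names(subtype_of) <- unlist(lapply(samples, `[[`, "tumor"), use.names = FALSE)
  # Per-gene, per-subtype loading of the subtype contrast. The structural
  # part follows the module layout (up in the module's own subtype, half
  # down elsewhere) with a graded per-gene weight; a per-gene jitter,
  # centred against the subtype proportions so the marginal tumor-vs-normal
  # shift is untouched, spreads the loadings continuously. Real marker
  # genes differ in effect size, and a continuous spread keeps rank-based
  # sample correlations close to their Pearson counterparts.
  w <- runif(length(module_genes), 0.5, 1.5)
  struct <- outer(seq_along(module_genes), seq_len(config$n_subtypes),
                  function(g, s) {
                    own <- module_subtype[module_of[module_genes[g]]] == s
                    ifelse(own, 1, -0.5)
                  }) * w
  jitter <- matrix(rnorm(length(struct), sd = 0.4), nrow(struct))
  subtype_loading <- struct + jitter
  # centre against the subtype mix so loadings carry contrast only and the
  # marginal tumor-vs-normal shift stays exactly at the configured value
  subtype_loading <- subtype_loading - drop(subtype_loading %*% config$subtype_props)
  dimnames(subtype_loading) <- list(module_genes, NULL)
  structure(
    list(genes = genes, module_of = module_of, true_up_degs = true_up_degs,
         module_subtype = module_subtype, subtype_of = subtype_of,
         subtype_loading = subtype_loading,
         true_hr = config$hazard_ratios, samples = samples),
    class = "ground_truth")
}

# shared latent-factor expression matrix for one cohort
simulate_cohort_matrix <- function(config, truth, tumor_ids, normal_ids,
                                   cohort_id, subtype_amp) {
  genes <- truth$genes
  n_genes <- length(genes)
  all_ids <- c(tumor_ids, normal_ids)
  n <- length(all_ids)
  mu <- rnorm(n_genes, mean = 7, sd = 1)
  mat <- matrix(rnorm(n_genes * n, sd = config$noise_sd), n_genes, n,
                dimnames = list(genes, all_ids))
  mat <- mat + mu
  lambda <- config$noise_sd *
    sqrt(config$within_module_corr / (1 - config$within_module_corr))
  for (m in seq_len(config$n_modules)) {
    members <- names(truth$module_of)[truth$module_of == m]
    f <- rnorm(n)
    mat[members, ] <- mat[members, , drop = FALSE] +
      lambda * matrix(f, length(members), n, byrow = TRUE)
  }
  if (length(truth$true_up_degs) && config$log2fc_mean != 0) {
    delta <- rnorm(length(truth$true_up_degs), config$log2fc_mean,
                   config$log2fc_sd)
    mat[truth$true_up_degs, tumor_ids] <-
      mat[truth$true_up_degs, tumor_ids, drop = FALSE] + delta
  }
  if (subtype_amp != 0) {
    members <- rownames(truth$subtype_loading)
    for (s in seq_len(config$n_subtypes)) {
      hit <- tumor_ids[truth$subtype_of[tumor_ids] == s]
      if (length(hit)) {
        mat[members, hit] <- mat[members, hit, drop = FALSE] +
          subtype_amp * truth$subtype_loading[, s]
      }
    }
  }
  expr_cohort(mat, setNames(rep(c("tumor", "normal"),
                                c(length(tumor_ids), length(normal_ids))),
                            all_ids),
              cohort_id)
}

#' Generate the discovery cohorts
#'
#' Each cohort is drawn from the latent-factor model: gene baselines
#' N(7, 1), residual noise `N(0, noise_sd)`, a shared per-module factor
#' giving expected within-module correlation
#' `lambda^2 / (lambda^2 + noise_sd^2) = within_module_corr`, a planted
#' tumor shift on dysregulated genes, and subtype-specific shifts on the
#' modules marking each tumor's subtype.
#'
#' @param config A [sim_config()].
#' @param truth A [plant_truth()] result.
#' @return A list of [expr_cohort()]s, one per discovery cohort.
#' @export
generate_cohorts <- function(config, truth = plant_truth(config)) {
  set.seed(sub_seed(config, 2))
  lapply(seq_len(config$n_cohorts), function(k) {
    ids <- truth$samples[[sprintf("cohort%d", k)]]
    simulate_cohort_matrix(config, truth, ids$tumor, ids$normal,
                           sprintf("cohort%d", k),
                           config$subtype_shift * config$discovery_subtype_atten)
  })
}

#' @rdname generate_cohorts
#' @export
generate_validation_cohort <- function(config, truth = plant_truth(config)) {
  set.seed(sub_seed(config, 3))
  ids <- truth$samples$validation
  simulate_cohort_matrix(config, truth, ids$tumor, ids$normal, "validation",
                         config$subtype_shift)
}

# deterministic toy ontology skeleton: root -> l1 -> l2 -> l3 -> l4
build_toy_dag <- function(prefix, fanout, namespace) {
  terms <- paste0(prefix, ":ROOT")
  edges <- tibble::tibble(term = character(0), parent = character(0),
                          relation = character(0))
  level_terms <- list(terms)
  rel_cycle <- c("is_a", "is_a", "part_of", "is_a", "regulates")
  idx <- 0L
  for (lvl in seq_along(fanout)) {
    new <- character(0)
    for (p in level_terms[[lvl]]) {
      for (k in seq_len(fanout[lvl])) {
        idx <- idx + 1L
        t <- sprintf("%s:%07d", prefix, idx)
        new <- c(new, t)
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          term = t, parent = p,
          relation = rel_cycle[(idx %% length(rel_cycle)) + 1L]))
      }
    }
    terms <- c(terms, new)
    level_terms[[lvl + 1L]] <- new
  }
  list(dag = go_dag(terms, edges, namespace), levels = level_terms)
}

#' Generate the toy ontology and gene annotations
#'
#' Builds one rooted DAG per namespace (BP depth 4, CC depth 3) using all
#' five relation types, then annotates genes so that each planted module's
#' genes share a specific deep BP term (and a shared CC term), while
#' background genes get scattered annotations. Module co-members are
#' therefore far more similar under [rss_gene()] than random pairs, which
#' is what makes the cluster score informative on synthetic data.
#'
#' @inheritParams generate_cohorts
#' @return A list with `dags` (list `BP`, `CC` of [go_dag()]) and
#'   `annotations` (list `BP`, `CC` of gene -> term id vectors).
#' @export
generate_go <- function(config, truth = plant_truth(config)) {
  assert_that(config$n_modules >= 1, "need at least one module")
  set.seed(sub_seed(config, 4))
  bp <- build_toy_dag("SBP", c(4, 3, 2, 2), "BP")
  cc <- build_toy_dag("SCC", c(3, 2, 2), "CC")
  bp_deep <- bp$levels[[5]]   # depth-4 terms
  cc_deep <- cc$levels[[4]]   # depth-3 terms
  bp_mod <- sample(bp_deep, config$n_modules,
                   replace = config$n_modules > length(bp_deep))
  cc_mod <- sample(cc_deep, config$n_modules,
                   replace = config$n_modules > length(cc_deep))
  ann_bp <- list()
  ann_cc <- list()
  bp_pool <- unlist(bp$levels[3:5])
  cc_pool <- unlist(cc$levels[2:4])
  for (g in truth$genes) {
    m <- truth$module_of[g]
    if (!is.na(m)) {
      ann_bp[[g]] <- unique(c(bp_mod[m], sample(bp_pool, 1)))
      ann_cc[[g]] <- cc_mod[m]
    } else {
      ann_bp[[g]] <- sample(bp_pool, sample(1:3, 1))
      ann_cc[[g]] <- sample(cc_pool, sample(1:2, 1))
    }
  }
  list(dags = list(BP = bp$dag, CC = cc$dag),
       annotations = list(BP = ann_bp, CC = ann_cc))
}

# linear index (1..choose(n,2), ordered by i then j) -> unordered pair i < j
index_to_pair <- function(idx, n) {
  cum <- cumsum((n - 1):1)        # pairs with first element <= i
  i <- findInterval(idx - 1L, cum) + 1L
  j <- i + (idx - c(0, cum)[i])
  cbind(i, j)
}

#' Generate the protein-protein interaction network
#'
#' Module co-members interact with probability `ppi_p_in`; all other pairs
#' with the much smaller background probability `ppi_p_out`, so planted
#' modules are dense subgraphs of an otherwise sparse network.
#'
#' @inheritParams generate_cohorts
#' @return A `ppi_network` tibble (see [ppi_network()]).
#' @export
generate_ppi <- function(config, truth = plant_truth(config)) {
  set.seed(sub_seed(config, 5))
  edges_from <- character(0)
  edges_to <- character(0)
  for (m in seq_len(config$n_modules)) {
    members <- names(truth$module_of)[truth$module_of == m]
    prs <- utils::combn(members, 2)
    keep <- runif(ncol(prs)) < config$ppi_p_in
    edges_from <- c(edges_from, prs[1, keep])
    edges_to <- c(edges_to, prs[2, keep])
  }
  n <- length(truth$genes)
  n_pairs <- choose(n, 2)
  n_bg <- rbinom(1, n_pairs, config$ppi_p_out)
  if (n_bg > 0) {
    idx <- sample(n_pairs, n_bg)
    pr <- index_to_pair(idx, n)
    edges_from <- c(edges_from, truth$genes[pr[, 1]])
    edges_to <- c(edges_to, truth$genes[pr[, 2]])
  }
  ppi_network(edges_from, edges_to)
}

# largest uniform-censoring bound solving the target censoring fraction for
# an exponential mixture; Inf when censor_rate = 0
censor_bound <- function(rates, props, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  p_cens <- function(u) {
    sum(props * (1 - exp(-rates * u)) / (rates * u)) - censor_rate
  }
  uniroot(p_cens, c(1e-6, 1e6))$root
}

#' Generate the clinical table for the validation tumors
#'
#' Covariates are Bernoulli draws with the per-subtype frequencies of the
#' configuration; survival is exponential with rate
#' `log(2) / baseline_median_months * HR(subtype)` under independent
#' uniform censoring calibrated to the target censoring fraction.
#'
#' @inheritParams generate_cohorts
#' @return A `clinical_table` tibble covering the validation tumor samples.
#' @export
generate_clinical <- function(config, truth = plant_truth(config)) {
  set.seed(sub_seed(config, 6))
  ids <- truth$samples$validation$tumor
  st <- truth$subtype_of[ids]
  lambda_ref <- log(2) / config$baseline_median_months
  rates <- lambda_ref * config$hazard_ratios[st]
  t_event <- rexp(length(ids), rate = rates)
  u <- censor_bound(lambda_ref * config$hazard_ratios, config$subtype_props,
                    config$censor_rate)
  c_time <- if (is.finite(u)) runif(length(ids), 0, u) else rep(Inf, length(ids))
  event <- as.integer(t_event <= c_time)
  time <- pmin(t_event, c_time)
  draw <- function(freqs) rbinom(length(ids), 1, freqs[st])
  clinical_table(tibble::tibble(
    sample_id = ids,
    time_months = time,
    event = event,
    hpv = ifelse(draw(config$covariate_freqs$hpv) == 1, "positive", "negative"),
    smoking = ifelse(draw(config$covariate_freqs$smoking) == 1, "current", "non"),
    tp53 = draw(config$covariate_freqs$tp53)
  ))
}

#' Generate a hallmark-style gene-set collection
#'
#' Small synthetic pathway sets for the reporting arm of the enrichment
#' stage: one set per module (its genes plus background noise genes) and a
#' few purely random sets.
#'
#' @inheritParams generate_cohorts
#' @return Named list of gene sets (GMT-compatible, see [write_gmt()]).
#' @export
generate_hallmarks <- function(config, truth = plant_truth(config)) {
  set.seed(sub_seed(config, 7))
  background <- setdiff(truth$genes, names(truth$module_of))
  sets <- list()
  for (m in seq_len(config$n_modules)) {
    members <- names(truth$module_of)[truth$module_of == m]
    sets[[sprintf("HALLMARK_M%02d", m)]] <- structure(
      c(members, sample(background, 20)),
      description = sprintf("module %d genes plus background", m))
  }
  for (k in 1:3) {
    sets[[sprintf("HALLMARK_RANDOM%d", k)]] <- structure(
      sample(truth$genes, 30), description = "random background set")
  }
  sets
}

#' Simulate a complete synthetic study
#'
#' Runs every generator off one configuration: discovery cohorts,
#' validation cohort, ontology and annotations, PPI network, clinical
#' table, hallmark sets, and the ground-truth manifest all downstream
#' recovery tests key off. Deterministic: the same config (including its
#' seed) yields identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with elements `config`, `truth`,
#'   `cohorts`, `validation`, `go`, `ppi`, `clinical`, `hallmarks`.
#' @export
simulate_study <- function(config = sim_config()) {
  truth <- plant_truth(config)
  structure(
    list(config = config,
         truth = truth,
         cohorts = generate_cohorts(config, truth),
         validation = generate_validation_cohort(config, truth),
         go = generate_go(config, truth),
         ppi = generate_ppi(config, truth),
         clinical = generate_clinical(config, truth),
         hallmarks = generate_hallmarks(config, truth)),
    class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Emits the full file set the readers in this package ingest (expression +
#' condition TSVs per cohort, OBO ontology, annotation TSVs, PPI TSV,
#' clinical TSV, hallmark GMT) plus `ground_truth.json`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (co in c(study$cohorts, list(study$validation))) {
    write_expression(co, file.path(dir, paste0(co$cohort_id, "_expr.tsv")),
                     file.path(dir, paste0(co$cohort_id, "_condition.tsv")))
  }
  write_obo(study$go$dags, file.path(dir, "ontology.obo"))
  write_annotations(study$go$annotations$BP, file.path(dir, "annotations_bp.tsv"))
  write_annotations(study$go$annotations$CC, file.path(dir, "annotations_cc.tsv"))
  write_ppi(study$ppi, file.path(dir, "ppi.tsv"))
  write_clinical(study$clinical, file.path(dir, "clinical.tsv"))
  write_gmt(study$hallmarks, file.path(dir, "hallmarks.gmt"))
  truth <- study$truth
  jsonlite::write_json(
    list(genes = truth$genes,
         module_of = as.list(truth$module_of),
         true_up_degs = truth$true_up_degs,
         module_subtype = as.list(truth$module_subtype),
         subtype_of = as.list(truth$subtype_of),
         true_hr = truth$true_hr),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
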