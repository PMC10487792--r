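test_that("pairwise correlation honours identity, antisymmetry and zero variance", {
  x <- c(1, 2, 4, 3, 5, 7, 6, 8)
  m <- rbind(a = x, b = -x, c = rep(2, 8), d = rnorm(8))
  colnames(m) <- sprintf("s%d", 1:8)
  co <- expr_cohort(m, rep("tumor", 8), "c")
  expect_equal(pcc(co, "a", "a"), 1)
  expect_equal(pcc(co, "a", "b"), -1)
  expect_warning(r0 <- pcc(co, "a", "c"), "zero variance")
  expect_equal(r0, 0)
})

test_that("cluster score composes similarity and co-expression as stated", {
  dags <- toy_dags()
  ann <- list(BP = list(g1 = "a1", g2 = "a1", g5 = character(0), g6 = character(0)),
              CC = list(g1 = "x1", g2 = "x1", g5 = character(0), g6 = character(0)))
  x <- c(1, 2, 3, 4)
  m <- rbind(g1 = x, g2 = 2 * x + 1,        # PCC exactly 1
             g5 = c(1, -1, 1, -1),          # orthogonal pair: PCC 0
             g6 = c(1, 1, -1, -1))
  colnames(m) <- sprintf("s%d", 1:4)
  co <- expr_cohort(m, rep("tumor", 4), "c")
  # identical annotations in both namespaces + perfect correlation -> 2
  expect_equal(cluster_score("g1", "g2", dags, ann, list(co)), 2)
  # no annotations and zero correlation -> 0
  expect_equal(cluster_score("g5", "g6", dags, ann, list(co)), 0)
})

test_that("cluster scores equal an independently composed oracle on random pairs", {
  set.seed(12)
  spec_bp <- random_dag_edges(15)
  spec_cc <- random_dag_edges(10)
  dags <- list(BP = go_dag(spec_bp$terms, spec_bp$edges, "BP"),
               CC = go_dag(spec_cc$terms, spec_cc$edges, "CC"))
  genes <- sprintf("G%02d", 1:8)
  ann <- list(
    BP = setNames(lapply(genes, function(g) sample(spec_bp$terms, sample(1:3, 1))), genes),
    CC = setNames(lapply(genes, function(g) sample(spec_cc$terms, sample(1:2, 1))), genes))
  cohorts <- lapply(1:2, function(k) {
    m <- matrix(rnorm(8 * 10, 6), 8, 10, dimnames = list(genes, sprintf("s%d", 1:10)))
    expr_cohort(m, rep("tumor", 10), paste0("c", k))
  })
  for (rep in 1:20) {
    pr <- sample(genes, 2)
    expected <- (oracle_rss_gene(spec_bp$edges, spec_bp$root,
                                 ann$BP[[pr[1]]], ann$BP[[pr[2]]]) +
                 oracle_rss_gene(spec_cc$edges, spec_cc$root,
                                 ann$CC[[pr[1]]], ann$CC[[pr[2]]])) / 2 +
      mean(vapply(cohorts, function(co) {
        cor(co$values[pr[1], ], co$values[pr[2], ])
      }, numeric(1)))
    expect_equal(cluster_score(pr[1], pr[2], dags, ann, cohorts), expected)
  }
  # full matrix: symmetric, bounded, diagonal pinned at 2
  cs <- cs_matrix(genes, dags, ann, cohorts)
  expect_true(all(abs(cs - t(cs)) < 1e-12))
  expect_true(all(diag(cs) == 2))
  off <- cs[upper.tri(cs)]
  expect_true(all(off >= -1 - 1e-12 & off <= 2 + 1e-12))
})

test_that("gene grouping separates blocks and matches the naive linkage oracle", {
  genes <- sprintf("g%02d", 1:10)
  cs <- matrix(0.1, 10, 10, dimnames = list(genes, genes))
  cs[1:5, 1:5] <- 1.8
  cs[6:10, 6:10] <- 1.8
  diag(cs) <- 2
  class(cs) <- c("cs_matrix", class(cs))
  grp <- cluster_genes(cs, cut_rho = 0.6)
  expect_equal(attr(grp, "n_groups"), 2)
  expect_equal(dplyr::n_distinct(grp$group[1:5]), 1)
  expect_equal(dplyr::n_distinct(grp$group[6:10]), 1)
  # degenerate cut keeps everything together
  grp_all <- cluster_genes(cs, cut_rho = -1)
  expect_equal(attr(grp_all, "n_groups"), 1)
})

test_that("gene grouping equals brute-force average linkage on random instances", {
  set.seed(19)
  for (rep in 1:4) {
    n <- sample(12:18, 1)
    genes <- sprintf("g%02d", seq_len(n))
    base <- matrix(rnorm(n * n), n)
    cs <- (base + t(base)) / 2
    cs <- pmin(pmax(cs, -1), 2)
    dimnames(cs) <- list(genes, genes)
    diag(cs) <- 2
    class(cs) <- c("cs_matrix", class(cs))
    cut_rho <- 0.6
    grp <- cluster_genes(cs, cut_rho)
    # rebuild the pairwise dissimilarity exactly as documented, then cluster
    # it with the O(n^3) agglomeration oracle
    d <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      keep <- setdiff(1:n, c(i, j))
      d[i, j] <- d[j, i] <- 1 - cor(cs[i, keep], cs[j, keep], method = "spearman")
    }
    oracle <- oracle_avg_linkage_cut(d, 1 - cut_rho)
    expect_equal(adjusted_rand_index(grp$group, oracle), 1)
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # closed-form anchor: all five drawn genes inside a five-gene set
  expect_equal(hypergeom_test(5, 5, 5, 20), 1 / choose(20, 5))
  universe <- sprintf("u%02d", 1:18)
  grouping <- tibble::tibble(gene = universe[1:5], group = 1L)
  collection <- list(S1 = universe[3:7], S2 = universe[10:18], S3 = universe[1:2])
  enr <- enrich_groups(grouping, collection, universe)
  for (i in seq_len(nrow(enr))) {
    expect_equal(
      enr$p[i],
      oracle_hyper_enum(enr$k[i], 5, collection[[enr$set[i]]], universe),
      tolerance = 1e-12)
  }
  # drawing the whole universe makes every overlap certain
  full <- enrich_groups(tibble::tibble(gene = universe, group = 1L),
                        collection, universe)
  expect_true(all(full$p == 1))
  expect_error(enrich_groups(grouping, collection, character(0)), "universe")
})

test_that("the eligibility gate requires a small p AND enough members", {
  enr <- tibble::tibble(group = c(1L, 1L, 2L, 3L),
                        set = c("A", "B", "A", "B"),
                        k = c(5L, 2L, 2L, 4L),
                        set_size = 5L, group_size = 6L,
                        p = c(0.001, 0.2, 0.003, 0.04))
  expect_equal(eligible_groups(enr), c(1L, 3L))
  expect_equal(eligible_groups(enr, min_members = 5), 1L)
})

test_that("representative scores follow the within-group sum", {
  genes <- c("a", "b")
  cs <- matrix(2, 2, 2, dimnames = list(genes, genes))
  class(cs) <- c("cs_matrix", class(cs))
  rs <- representative_scores(cs, tibble::tibble(gene = genes, group = 1L))
  expect_equal(rs$rs, c(0.5, 0.5))  # 2 / (2 * M), M = 2
  # all-zero off-diagonals give zero scores
  cs0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(cs0) <- 2
  rs0 <- representative_scores(cs0, tibble::tibble(gene = letters[1:3], group = 1L))
  expect_equal(rs0$rs, rep(0, 3))
  expect_error(
    representative_scores(cs, tibble::tibble(gene = "a", group = 1L)),
    "singleton")
  # random instance equals the explicit-loop oracle
  set.seed(4)
  g8 <- sprintf("g%d", 1:8)
  m <- matrix(runif(64, -1, 2), 8, 8, dimnames = list(g8, g8))
  m <- (m + t(m)) / 2; diag(m) <- 2
  class(m) <- c("cs_matrix", class(m))
  grouping <- tibble::tibble(gene = g8, group = rep(1:2, each = 4))
  rs8 <- representative_scores(m, grouping)
  for (i in 1:8) {
    members <- g8[grouping$group == grouping$group[i]]
    expected <- sum(m[g8[i], setdiff(members, g8[i])]) / (2 * length(members))
    expect_equal(rs8$rs[rs8$gene == g8[i]], expected)
  }
})

test_that("interactor counts follow the published worked example and a loop oracle", {
  set.seed(1234)
  n_partner <- 37
  partners <- sprintf("p%02d", seq_len(n_partner))
  samples <- sprintf("s%02d", 1:40)
  x <- rnorm(40)
  m <- rbind(matrix(rnorm(40 * n_partner), n_partner,
                    dimnames = list(partners, samples)),
             X = x)
  # exactly one partner strongly co-expressed with X
  m["p01", ] <- x + rnorm(40, sd = 0.1)
  co <- expr_cohort(m, rep("tumor", 40), "c")
  stopifnot(sum(abs(cor(t(m))["X", partners]) >= 0.5) == 1)
  net <- ppi_network(rep("X", n_partner), partners)
  expect_equal(nig("X", co, net), 1)
  # no PPI record: nig is an empty sum, ncg switches on
  lonely <- expr_cohort(rbind(m, L = x + rnorm(40, sd = 0.05)),
                        rep("tumor", 40), "c")
  expect_equal(nig("L", lonely, net), 0L)
  r_all <- cor(t(lonely$values))["L", setdiff(rownames(lonely$values), "L")]
  expect_equal(ncg("L", lonely, net), sum(abs(r_all) >= 0.7))
  expect_equal(ncg("X", co, net), 0L)  # has PPI records
  # random toy instance vs an explicit loop for both counts
  for (g in c("p05", "p10")) {
    prt <- intersect(c("X"), rownames(co$values))
    expect_equal(nig(g, co, net),
                 sum(vapply(prt, function(q) abs(cor(m[g, ], m[q, ])) >= 0.5,
                            logical(1))))
  }
})

test_that("perturbation scores span [0,1] with ranked extremes and match the oracle", {
  set.seed(77)
  genes <- sprintf("g%02d", 1:12)
  cohorts <- lapply(1:2, function(k) {
    m <- matrix(rnorm(12 * 12, 6), 12, dimnames = list(genes, sprintf("s%d", 1:12)))
    expr_cohort(m, rep(c("tumor", "normal"), each = 6), paste0("c", k))
  })
  net <- ppi_network(c("g01", "g01", "g02"), c("g02", "g03", "g04"))
  degs <- lapply(cohorts, identify_degs, fc_thresh = 1.01, p_thresh = 0.99)
  ps <- perturbation_scores(genes, cohorts, net, degs)
  expect_true(all(ps$ps >= 0 & ps$ps <= 1))
  expect_equal(ps$gene, genes)
  # independent explicit-loop oracle over the same components
  comp <- attr(ps, "components")
  nfc <- matrix(comp$nfc_raw, 12); p <- matrix(comp$p_raw, 12)
  nig_m <- matrix(comp$nig, 12); ncg_m <- matrix(comp$ncg, 12)
  expect_equal(ps$ps, oracle_ps(nfc, p, nig_m, ncg_m))
})

test_that("a gene topping every component scores 1; the bottom gene scores 0", {
  genes <- c("top", "mid", "low")
  deg <- tibble::tibble(cohort_id = "c", gene = genes,
                        log2fc = c(3, 1, 0.1), fold_change = 2^c(3, 1, 0.1),
                        p_value = c(1e-9, 0.02, 0.9),
                        is_deg = c(TRUE, TRUE, FALSE),
                        direction = c("up", "up", "none"))
  set.seed(9)
  x <- rnorm(12)
  m <- rbind(top = x, mid = rnorm(12), low = rnorm(12),
             q1 = x + rnorm(12, sd = 0.05), q2 = rnorm(12))
  colnames(m) <- sprintf("s%d", 1:12)
  co <- expr_cohort(m, rep("tumor", 12), "c")
  net <- ppi_network(c("top", "low"), c("q1", "q2"))
  stopifnot(abs(cor(m["low", ], m["q2", ])) < 0.5)
  ps <- perturbation_scores(genes, list(co), net, list(deg))
  expect_equal(ps$ps[ps$gene == "top"], 1)
  expect_equal(ps$ps[ps$gene == "low"], 0)
})

test_that("improving one component never lowers a gene's perturbation score", {
  base <- list(nfc = c(1, 2, 0.5, 1.5), p = c(0.2, 0.01, 0.5, 0.1),
               nig = c(0, 2, 1, 0), ncg = c(0, 0, 0, 0))
  score_of <- function(cmp, gene) {
    oracle_ps(matrix(cmp$nfc), matrix(cmp$p), matrix(cmp$nig),
              matrix(cmp$ncg))[gene]
  }
  for (field in c("nfc", "nig")) {
    bumped <- base
    bumped[[field]][3] <- bumped[[field]][3] + 2
    expect_gte(score_of(bumped, 3), score_of(base, 3))
  }
  bumped <- base; bumped$p[3] <- 1e-6
  expect_gte(score_of(bumped, 3), score_of(base, 3))
})

test_that("selection counts implement the sub-linear quota with half-up rounding", {
  expect_equal(sc_count(5, 5), 5)
  expect_equal(sc_count(55, 5), 15)
  expect_equal(sc_count(9, 5), 6)    # (9-5)/5 + 5 = 5.8 -> 6
  expect_equal(sc_count(12, 5), 6)   # 6.4 -> 6
  expect_equal(sc_count(13, 5), 7)   # 6.6 -> 7
  expect_equal(sc_count(6, 6), 6)
  expect_error(sc_count(4, 5), "at least")
})

test_that("signature selection keeps whole minimum groups and ranks by combined score", {
  rs <- tibble::tibble(gene = sprintf("g%d", 1:7),
                       group = c(rep(1L, 5), 2L, 2L),
                       rs = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.9, 0.1))
  ps <- tibble::tibble(gene = rs$gene, ps = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.9, 0.4))
  sig <- select_signature(rs, ps, min_g = 5)
  # a group exactly at min_g keeps all members regardless of scores
  expect_true(all(sig$selected[sig$group == 1]))
  # 2-member group with min_g 5 is capped at its size
  expect_true(all(sig$selected[sig$group == 2]))
  # ordering: 6-gene group with min_g 5 keeps a quota of 5, dropping the
  # weakest combined score; rank 1 goes to the strongest
  six <- select_signature(
    tibble::tibble(gene = letters[1:6], group = 1L,
                   rs = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1)),
    tibble::tibble(gene = letters[1:6], ps = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.05)),
    min_g = 5)
  expect_equal(six$gene[six$rank == 1], "a")
  expect_equal(sum(six$selected), 5)
  expect_setequal(signature_genes(six), letters[1:5])
})

test_that("pipeline recovers planted modules and selects mostly planted genes", {
  pipe <- default_pipeline()
  study <- default_study()
  truth <- study$truth
  expect_gte(mean(pipe$signature_genes %in% truth$true_up_degs), 0.7)
  # eligible-group structure matches the planted modules
  elig <- pipe$grouping[pipe$grouping$group %in% pipe$eligible, ]
  planted <- elig$gene %in% names(truth$module_of)
  expect_gt(mean(planted), 0.9)
  modules <- truth$module_of[elig$gene[planted]]
  ari <- adjusted_rand_index(elig$group[planted], modules)
  expect_gte(ari, 0.8)
})
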