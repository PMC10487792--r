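small_cfg <- function(seed = 2, ...) {
  sim_config(seed = seed, genes_total = 250, n_modules = 4, module_size = 6,
             tumor_n = 25, normal_n = 15, validation_tumor_n = 60,
             validation_normal_n = 10, ...)
}

test_that("the generator is deterministic for a fixed seed", {
  a <- simulate_study(small_cfg())
  b <- simulate_study(small_cfg())
  expect_identical(a$cohorts[[1]]$values, b$cohorts[[1]]$values)
  expect_identical(a$validation$values, b$validation$values)
  expect_identical(a$truth$subtype_of, b$truth$subtype_of)
  expect_identical(as.data.frame(a$ppi), as.data.frame(b$ppi))
  expect_identical(as.data.frame(a$clinical), as.data.frame(b$clinical))
  c2 <- simulate_study(small_cfg(seed = 3))
  expect_false(identical(a$cohorts[[1]]$values, c2$cohorts[[1]]$values))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(subtype_props = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(n_modules = 100, module_size = 100, genes_total = 200),
               "exceed")
  expect_error(sim_config(n_up_deg = 101), "modules")
  expect_error(sim_config(within_module_corr = 1.2), "0,1")
  expect_error(sim_config(hazard_ratios = c(1, -1, 1)), "positive")
  expect_error(sim_config(censor_rate = 1), "censor")
})

test_that("module co-members share deep terms: within-module gene similarity dominates", {
  deltas <- vapply(1:20, function(s) {
    cfg <- small_cfg(seed = s)
    truth <- plant_truth(cfg)
    go <- generate_go(cfg, truth)
    mods <- names(truth$module_of)
    set.seed(s)
    within <- mean(replicate(30, {
      m <- sample(unique(truth$module_of), 1)
      pr <- sample(names(truth$module_of)[truth$module_of == m], 2)
      rss_gene(go$dags$BP, go$annotations$BP, pr[1], pr[2])
    }))
    between <- mean(replicate(30, {
      ms <- sample(unique(truth$module_of), 2)
      g1 <- sample(names(truth$module_of)[truth$module_of == ms[1]], 1)
      g2 <- sample(names(truth$module_of)[truth$module_of == ms[2]], 1)
      rss_gene(go$dags$BP, go$annotations$BP, g1, g2)
    }))
    within - between
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.95)
  expect_gt(mean(deltas), 0.2)
})

test_that("module genes share a term whose self-similarity is exact", {
  cfg <- small_cfg()
  truth <- plant_truth(cfg)
  go <- generate_go(cfg, truth)
  members <- names(truth$module_of)[truth$module_of == 1]
  shared <- Reduce(intersect, go$annotations$BP[members])
  expect_gte(length(shared), 1)
  expect_equal(rss_term(go$dags$BP, shared[1], shared[1]), 1)
  expect_gte(go_depth(go$dags$BP, shared[1]), 3)
})

test_that("latent-factor co-expression matches its closed form", {
  # expected pairwise r = lambda^2 / (lambda^2 + sigma^2) = within_module_corr
  target <- 0.6
  rs <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, genes_total = 60, n_modules = 2, module_size = 8,
                      tumor_n = 40, normal_n = 10, within_module_corr = target,
                      log2fc_mean = 0, subtype_shift = 0,
                      validation_tumor_n = 10, validation_normal_n = 5)
    truth <- plant_truth(cfg)
    co <- generate_cohorts(cfg, truth)[[1]]
    members <- names(truth$module_of)[truth$module_of == 1]
    r <- cor(t(co$values[members, ]))
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_lt(abs(mean(rs) - target), 0.05)
})

test_that("the planted tumor shift is recovered within CLT tolerance", {
  # 200 replicate cohorts at n = 30/30, sd 0.5: the mean realized shift of
  # planted genes stays within 3 standard errors of the planted 1.5
  diffs <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, genes_total = 40, n_modules = 1, module_size = 5,
                      tumor_n = 30, normal_n = 30, subtype_shift = 0,
                      log2fc_sd = 0, validation_tumor_n = 10,
                      validation_normal_n = 5)
    truth <- plant_truth(cfg)
    co <- generate_cohorts(cfg, truth)[[1]]
    g <- truth$true_up_degs[1]
    mean(co$values[g, co$condition == "tumor"]) -
      mean(co$values[g, co$condition == "normal"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.5), 3 * se)
})

test_that("a zero-signal configuration triggers the DEG filter at its false-positive rate", {
  cfg <- sim_config(seed = 5, genes_total = 500, n_modules = 1, module_size = 5,
                    log2fc_mean = 0, subtype_shift = 0, tumor_n = 30,
                    normal_n = 20, validation_tumor_n = 10,
                    validation_normal_n = 5)
  deg <- identify_degs(generate_cohorts(cfg)[[1]])
  # the joint |FC| >= 1.5 & p < 0.05 rule is far stricter than p alone here
  expect_lt(mean(deg$is_deg), 0.01)
})

test_that("PPI edges concentrate within modules; a zero background keeps them pure", {
  cfg <- small_cfg(seed = 6, ppi_p_out = 0)
  truth <- plant_truth(cfg)
  net <- generate_ppi(cfg, truth)
  mod <- truth$module_of
  expect_true(all(!is.na(mod[net$from]) & !is.na(mod[net$to])))
  expect_true(all(mod[net$from] == mod[net$to]))
  net2 <- generate_ppi(small_cfg(seed = 6))
  within2 <- !is.na(mod[net2$from]) & !is.na(mod[net2$to]) &
    mod[net2$from] == mod[net2$to]
  # within-module density p_in = 0.6 versus background 0.002
  expect_gt(sum(within2), 0.4 * 4 * choose(6, 2))
  expect_gt(mean(within2), 0.1)
})

test_that("clinical covariate frequencies and censoring track the configuration", {
  cfg <- sim_config(seed = 12)
  truth <- plant_truth(cfg)
  cl <- generate_clinical(cfg, truth)
  st <- truth$subtype_of[cl$sample_id]
  for (s in 1:3) {
    expect_lt(abs(mean(cl$hpv[st == s] == "positive") -
                    cfg$covariate_freqs$hpv[s]), 0.1)
  }
  expect_lt(abs(mean(cl$event == 0) - cfg$censor_rate), 0.1)
  expect_true(all(cl$time_months >= 0))
})

test_that("null hazard ratios keep the log-rank test at its nominal size", {
  cfg <- sim_config(seed = 1, hazard_ratios = c(1, 1, 1),
                    validation_tumor_n = 150)
  rejections <- vapply(1:300, function(s) {
    cfg_s <- cfg; cfg_s$seed <- s + 1000
    truth <- plant_truth(cfg_s)
    cl <- generate_clinical(cfg_s, truth)
    st <- truth$subtype_of[cl$sample_id]
    a <- cl[st == 1, ]; b <- cl[st == 3, ]
    logrank(a$time_months, a$event, b$time_months, b$event, horizon = Inf)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("log-rank power against HR 1.5 matches the Schoenfeld approximation", {
  # 150 per group, censor rate 0.3; oracle: power = Phi(sqrt(d/4)|log HR| - z)
  set.seed(404)
  n <- 150; hr <- 1.5
  lam <- log(2) / 30
  u <- uniroot(function(u) {
    mean(c((1 - exp(-lam * u)) / (lam * u),
           (1 - exp(-lam * hr * u)) / (lam * hr * u))) - 0.3
  }, c(1e-3, 1e5))$root
  sims <- replicate(300, {
    ta <- rexp(n, lam); tb <- rexp(n, lam * hr)
    ca <- runif(n, 0, u); cb <- runif(n, 0, u)
    d <- sum(ta <= ca) + sum(tb <= cb)
    p <- logrank(pmin(ta, ca), as.integer(ta <= ca),
                 pmin(tb, cb), as.integer(tb <= cb), horizon = Inf)$p
    c(reject = p < 0.05, d = d)
  })
  power_hat <- mean(sims["reject", ])
  d_bar <- mean(sims["d", ])
  power_theory <- pnorm(sqrt(d_bar / 4) * abs(log(hr)) - qnorm(0.975))
  expect_lt(abs(power_hat - power_theory),
            2.58 * sqrt(power_theory * (1 - power_theory) / 300) + 0.02)
})

test_that("a written study re-reads losslessly and carries its manifest", {
  dir <- withr::local_tempdir()
  study <- simulate_study(small_cfg(seed = 8))
  write_study(study, dir)
  co <- read_expression(file.path(dir, "cohort1_expr.tsv"),
                        file.path(dir, "cohort1_condition.tsv"), "cohort1")
  expect_equal(co$values, study$cohorts[[1]]$values)
  expect_equal(co$condition, study$cohorts[[1]]$condition)
  net <- read_ppi(file.path(dir, "ppi.tsv"))
  expect_equal(as.data.frame(net), as.data.frame(study$ppi))
  cl <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(cl$event, study$clinical$event)
  expect_equal(cl$time_months, study$clinical$time_months, tolerance = 1e-9)
  dags <- read_obo(file.path(dir, "ontology.obo"))
  expect_equal(dags$BP$depth, study$go$dags$BP$depth)
  manifest <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                  simplifyVector = TRUE)
  expect_setequal(manifest$true_up_degs, study$truth$true_up_degs)
  ann <- read_annotations(file.path(dir, "annotations_bp.tsv"))
  expect_equal(ann[order(names(ann))],
               study$go$annotations$BP[order(names(study$go$annotations$BP))])
})
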