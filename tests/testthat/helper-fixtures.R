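# shared expensive fixtures, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- simulate_study(sim_config(seed = 1))
  }
  .fixture_cache$study
}

default_pipeline <- function() {
  if (is.null(.fixture_cache$pipe)) {
    s <- default_study()
    .fixture_cache$pipe <- suppressWarnings(
      run_pipeline(s$cohorts, s$validation, s$go, s$ppi, s$clinical,
                   s$hallmarks))
  }
  .fixture_cache$pipe
}

# a small deterministic cohort: n_genes x (n_tum + n_nor), genes gA01..,
# tumors first
toy_cohort <- function(n_genes = 6, n_tum = 8, n_nor = 6, seed = 42,
                       cohort_id = "toy") {
  set.seed(seed)
  genes <- sprintf("gA%02d", seq_len(n_genes))
  samples <- c(sprintf("t%02d", seq_len(n_tum)), sprintf("n%02d", seq_len(n_nor)))
  m <- matrix(rnorm(n_genes * length(samples), 6, 1), n_genes,
              dimnames = list(genes, samples))
  expr_cohort(m, rep(c("tumor", "normal"), c(n_tum, n_nor)), cohort_id)
}

# tiny two-namespace ontology: root -> a,b ; a -> a1,a2 ; b -> b1
toy_dags <- function() {
  bp <- go_dag(c("R", "a", "b", "a1", "a2", "b1"),
               data.frame(term = c("a", "b", "a1", "a2", "b1"),
                          parent = c("R", "R", "a", "a", "b"),
                          relation = c("is_a", "is_a", "is_a", "part_of", "is_a")),
               "BP")
  cc <- go_dag(c("R", "x", "x1"),
               data.frame(term = c("x", "x1"), parent = c("R", "x"),
                          relation = c("is_a", "is_a")),
               "CC")
  list(BP = bp, CC = cc)
}
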