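# Independent oracles used to cross-check the implementation. These are
# deliberately naive (explicit enumeration / brute force) and share no code
# with the package internals they verify.

# ancestors (incl. self) of a term by explicit edge-following on an edge table
oracle_ancestors <- function(edges, term) {
  anc <- term
  repeat {
    parents <- unique(edges$parent[edges$term %in% anc])
    new <- setdiff(parents, anc)
    if (length(new) == 0) return(anc)
    anc <- c(anc, new)
  }
}

# all parent-paths from term to root, as a list of path lengths
oracle_path_lengths <- function(edges, from, to) {
  if (from == to) return(0L)
  out <- integer(0)
  for (p in edges$parent[edges$term == from]) {
    sub <- oracle_path_lengths(edges, p, to)
    out <- c(out, sub + 1L)
  }
  out
}

oracle_depth <- function(edges, term, root) {
  lens <- oracle_path_lengths(edges, term, root)
  if (length(lens) == 0) stop("term does not reach root")
  max(lens)
}

oracle_dist <- function(edges, term, anc) {
  min(oracle_path_lengths(edges, term, anc))
}

oracle_lca_set <- function(edges, a, b, root) {
  common <- intersect(oracle_ancestors(edges, a), oracle_ancestors(edges, b))
  depths <- vapply(common, oracle_depth, integer(1), edges = edges, root = root)
  common[depths == max(depths)]
}

oracle_rss_term <- function(edges, a, b, root) {
  if (a == b) return(1)
  common <- intersect(oracle_ancestors(edges, a), oracle_ancestors(edges, b))
  vals <- vapply(common, function(c0) {
    dep <- oracle_depth(edges, c0, root)
    dep / (dep + oracle_dist(edges, a, c0) + oracle_dist(edges, b, c0))
  }, numeric(1))
  max(vals)
}

oracle_rss_gene <- function(edges, root, terms_i, terms_j) {
  if (length(terms_i) == 0 || length(terms_j) == 0) return(0)
  m <- outer(terms_i, terms_j,
             Vectorize(function(a, b) oracle_rss_term(edges, a, b, root)))
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# random DAG over n terms: term i may have parents among terms < i
random_dag_edges <- function(n, p_extra = 0.3) {
  terms <- sprintf("T%02d", seq_len(n))
  rows <- lapply(2:n, function(i) {
    primary <- sample(i - 1, 1)
    extra <- which(runif(i - 1) < p_extra / 2)
    parents <- unique(c(primary, extra))
    data.frame(term = terms[i], parent = terms[parents],
               relation = sample(c("is_a", "part_of", "regulates"),
                                 length(parents), replace = TRUE))
  })
  list(terms = terms, edges = do.call(rbind, rows), root = terms[1])
}

# brute-force upper-tail hypergeometric by enumerating every possible group
oracle_hyper_enum <- function(k, group_size, set_genes, universe) {
  draws <- utils::combn(universe, group_size, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set_genes)) >= k,
              logical(1)))
}

# naive O(n^3) average-linkage agglomeration with a merge-height cutoff
oracle_avg_linkage_cut <- function(d, h) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best_d) { best_d <- avg; best <- c(i, j) }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- integer(n)
  for (i in seq_along(clusters)) membership[clusters[[i]]] <- i
  membership
}

# explicit-loop perturbation-score pipeline (rescale, sum, rank, average,
# normalise), independent of the dplyr implementation
oracle_ps <- function(nfc, p, nig_m, ncg_m) {
  n_genes <- nrow(nfc); n_cohorts <- ncol(nfc)
  rescale <- function(x) {
    if (max(x) == min(x)) return(rep(1, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  rank_mat <- matrix(0, n_genes, n_cohorts)
  for (k in seq_len(n_cohorts)) {
    nig_s <- if (max(nig_m[, k]) > 0) nig_m[, k] / max(nig_m[, k]) else rep(0, n_genes)
    ncg_s <- if (max(ncg_m[, k]) > 0) ncg_m[, k] / max(ncg_m[, k]) else rep(0, n_genes)
    ps_k <- rescale(nfc[, k]) + (1 - p[, k]) + nig_s + ncg_s
    rank_mat[, k] <- rank(ps_k, ties.method = "average") / n_genes
  }
  rescale(rowMeans(rank_mat))
}
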