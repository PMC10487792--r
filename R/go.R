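GO_RELATIONS <- c("is_a", "part_of", "regulates",
                  "negatively_regulates", "positively_regulates")

#' Gene Ontology DAG objects
#'
#' A rooted directed acyclic graph of ontology terms for one namespace
#' (biological process `BP` or cellular component `CC`). All five relation
#' types (`is_a`, `part_of`, `regulates`, `negatively_regulates`,
#' `positively_regulates`) are traversed identically as parent links when
#' computing depth, ancestors and similarity.
#'
#' @param terms Character vector of term identifiers.
#' @param parent_edges Data frame with columns `term`, `parent`, `relation`.
#' @param namespace `"BP"` or `"CC"`.
#' @return An object of class `go_dag` with precomputed term depths
#'   (longest parent-path to the root; root depth 0).
#' @export
go_dag <- function(terms, parent_edges, namespace = c("BP", "CC")) {
  namespace <- match.arg(namespace)
  terms <- as.character(terms)
  assert_that(!anyDuplicated(terms), "duplicate term identifiers")
  pe <- tibble::tibble(term = as.character(parent_edges$term),
                       parent = as.character(parent_edges$parent),
                       relation = as.character(parent_edges$relation))
  assert_that(all(pe$relation %in% GO_RELATIONS),
              paste0("relations restricted to: ", paste(GO_RELATIONS, collapse = ", ")))
  assert_that(all(c(pe$term, pe$parent) %in% terms),
              "parent edges reference unknown terms")
  parents <- split(pe$parent, factor(pe$term, levels = terms))
  roots <- terms[lengths(parents) == 0]
  assert_that(length(roots) == 1,
              "DAG must have exactly one root (term with no parents)")
  # Kahn topological order (parents before children); also proves acyclicity
  indeg <- setNames(lengths(parents), terms)
  children <- split(pe$term, factor(pe$parent, levels = terms))
  queue <- roots
  topo <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  assert_that(length(topo) == length(terms), "parent edges contain a cycle")
  depth <- setNames(rep(0L, length(terms)), terms)
  for (t in topo) {
    ps <- parents[[t]]
    if (length(ps)) depth[t] <- max(depth[ps]) + 1L
  }
  structure(
    list(namespace = namespace, terms = terms, parents = parents,
         children = children, root = roots, depth = depth,
         edges = pe, cache = new.env(parent = emptyenv())),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag %s> %d terms, %d edges, root '%s', max depth %d\n",
              x$namespace, length(x$terms), nrow(x$edges), x$root,
              max(x$depth)))
  invisible(x)
}

#' Term depth, ancestors and lowest common ancestors
#'
#' `go_depth()` is the length of the longest parent-edge path from a term to
#' the root (root depth 0), the conventional specificity measure on an
#' ontology DAG. `go_ancestors()` returns every ancestor with the shortest
#' parent-path distance to it (a term is its own ancestor at distance 0).
#' `lca_set()` returns the common ancestors of maximal depth.
#'
#' @param dag A [go_dag()].
#' @param term,a,b Term identifiers present in `dag`.
#' @return `go_depth()` an integer; `go_ancestors()` a named integer vector
#'   of distances; `lca_set()` a character vector of terms.
#' @export
go_depth <- function(dag, term) {
  assert_that(term %in% dag$terms, paste0("unknown term: ", term))
  unname(dag$depth[term])
}

#' @rdname go_depth
#' @export
go_ancestors <- function(dag, term) {
  assert_that(term %in% dag$terms, paste0("unknown term: ", term))
  key <- paste0("anc.", term)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  # BFS up the parent edges: shortest distance to each ancestor
  dist <- setNames(0L, term)
  frontier <- term
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  assign(key, dist, envir = dag$cache)
  dist
}

#' @rdname go_depth
#' @export
lca_set <- function(dag, a, b) {
  anc_a <- go_ancestors(dag, a)
  anc_b <- go_ancestors(dag, b)
  common <- intersect(names(anc_a), names(anc_b))
  depths <- dag$depth[common]
  common[depths == max(depths)]
}

#' Relative specificity similarity between two ontology terms
#'
#' A similarity in \[0, 1\] that rewards a deep (specific) shared ancestor
#' and penalises the distance of each term from it:
#' \deqn{RSS(a,b) = \max_{c \in anc(a) \cap anc(b)}
#'   \frac{depth(c)}{depth(c) + d(a,c) + d(b,c)}}
#' with `depth` the longest path to the root and `d` the shortest
#' parent-path length. Identical terms score 1; terms whose only common
#' ancestor is the root score 0.
#'
#' @inheritParams go_depth
#' @return A numeric value in \[0, 1\].
#' @export
rss_term <- function(dag, a, b) {
  assert_that(a %in% dag$terms, paste0("unknown term: ", a))
  assert_that(b %in% dag$terms, paste0("unknown term: ", b))
  if (a == b) return(1)
  key <- if (a < b) paste0("rss.", a, "|", b) else paste0("rss.", b, "|", a)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  anc_a <- go_ancestors(dag, a)
  anc_b <- go_ancestors(dag, b)
  common <- intersect(names(anc_a), names(anc_b))
  dep <- as.numeric(dag$depth[common])
  val <- max(dep / (dep + as.numeric(anc_a[common]) + as.numeric(anc_b[common])))
  assign(key, val, envir = dag$cache)
  val
}

#' Gene-level ontology similarity (best-match average)
#'
#' Aggregates term-level [rss_term()] values over two genes' annotation
#' sets: for each term of one gene take its best match among the other
#' gene's terms, average these maxima per gene, then average the two
#' directions (making the measure symmetric). A gene with no annotations in
#' the namespace scores 0 against everything.
#'
#' @param dag A [go_dag()].
#' @param annotation Named list mapping gene id to a character vector of
#'   term ids in `dag`'s namespace.
#' @param gene_i,gene_j Gene identifiers (need not appear in `annotation`;
#'   absent means unannotated).
#' @return A numeric value in \[0, 1\].
#' @export
rss_gene <- function(dag, annotation, gene_i, gene_j) {
  ti <- annotation[[gene_i]] %||% character(0)
  tj <- annotation[[gene_j]] %||% character(0)
  if (length(ti) == 0 || length(tj) == 0) return(0)
  m <- matrix(0, length(ti), length(tj))
  for (p in seq_along(ti)) for (q in seq_along(tj)) {
    m[p, q] <- rss_term(dag, ti[p], tj[q])
  }
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

OBO_NAMESPACES <- c(biological_process = "BP", cellular_component = "CC")

#' Read and write ontologies in OBO 1.2 format
#'
#' A minimal OBO parser covering `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` and `relationship` tags (the five relation types of
#' [go_dag()]). Obsolete terms are skipped. Terms are split by namespace and
#' one [go_dag()] is built per namespace present.
#'
#' @param path File path.
#' @return `read_obo()` returns a named list of [go_dag()] objects keyed by
#'   namespace (`BP`, `CC`), with a `names_table` attribute mapping term id
#'   to name.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  in_term <- FALSE
  cur <- NULL
  recs <- list()
  flush <- function(cur) if (!is.null(cur) && !isTRUE(cur$obsolete)) recs[[length(recs) + 1L]] <<- cur
  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[i])
    line <- trimws(line)
    if (line == "[Term]") {
      flush(cur)
      cur <- list(edges = list())
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || line == "") next
    kv <- regmatches(line, regexec("^([a-z_]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) parse_error(sprintf("malformed OBO line %d: '%s'", i, lines[i]))
    key <- kv[2]; val <- trimws(kv[3])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "is_a") cur$edges[[length(cur$edges) + 1L]] <- c("is_a", val)
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2) parse_error(sprintf("malformed relationship at OBO line %d", i))
      if (parts[1] %in% GO_RELATIONS) {
        cur$edges[[length(cur$edges) + 1L]] <- c(parts[1], parts[2])
      }
    }
  }
  flush(cur)
  assert_that(length(recs) > 0, "no [Term] stanzas found")
  ns_of <- vapply(recs, function(r) r$namespace %||% "biological_process", character(1))
  ids <- vapply(recs, function(r) r$id %||% parse_error("term without id"), character(1))
  names_tab <- tibble::tibble(
    term = ids,
    name = vapply(recs, function(r) r$name %||% "", character(1)),
    namespace = ns_of)
  out <- list()
  for (ns in intersect(names(OBO_NAMESPACES), unique(ns_of))) {
    idx <- ns_of == ns
    terms <- ids[idx]
    edge_rows <- purrr::map2_dfr(recs[idx], terms, function(r, id) {
      if (length(r$edges) == 0) return(tibble::tibble())
      em <- do.call(rbind, r$edges)
      tibble::tibble(term = id, parent = em[, 2], relation = em[, 1])
    })
    out[[OBO_NAMESPACES[[ns]]]] <- go_dag(terms, edge_rows, OBO_NAMESPACES[[ns]])
  }
  attr(out, "names_table") <- names_tab
  out
}

#' @rdname read_obo
#' @param dags Named list of [go_dag()] objects (as returned by `read_obo()`).
#' @export
write_obo <- function(dags, path) {
  names_tab <- attr(dags, "names_table")
  ns_long <- setNames(names(OBO_NAMESPACES), OBO_NAMESPACES)
  out <- c("format-version: 1.2", "")
  for (ns in names(dags)) {
    dag <- dags[[ns]]
    for (t in dag$terms) {
      nm <- ""
      if (!is.null(names_tab)) {
        hit <- names_tab$name[names_tab$term == t]
        if (length(hit)) nm <- hit[1]
      }
      stanza <- c("[Term]", paste0("id: ", t),
                  if (nzchar(nm)) paste0("name: ", nm),
                  paste0("namespace: ", ns_long[[ns]]))
      e <- dag$edges[dag$edges$term == t, , drop = FALSE]
      for (k in seq_len(nrow(e))) {
        stanza <- c(stanza, if (e$relation[k] == "is_a") {
          paste0("is_a: ", e$parent[k])
        } else {
          paste0("relationship: ", e$relation[k], " ", e$parent[k])
        })
      }
      out <- c(out, stanza, "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Build term-wise gene sets from an annotation map
#'
#' Inverts a gene -> terms map into term -> genes sets, propagating each
#' annotation to all ancestor terms (the true-path rule: a gene annotated
#' to a term is implicitly annotated to everything the term specialises).
#' The root term, which would contain every annotated gene, is dropped.
#'
#' @param dag A [go_dag()].
#' @param annotation Named list gene -> term ids.
#' @param propagate Propagate annotations to ancestors (default TRUE).
#' @return Named list term id -> character vector of genes, usable as the
#'   collection argument of [enrich_groups()].
#' @export
annotation_gene_sets <- function(dag, annotation, propagate = TRUE) {
  genes <- names(annotation)
  pairs_gene <- character(0)
  pairs_term <- character(0)
  for (g in genes) {
    terms <- intersect(annotation[[g]], dag$terms)
    if (length(terms) == 0) next
    if (propagate) {
      terms <- unique(unlist(lapply(terms, function(t) names(go_ancestors(dag, t)))))
    }
    pairs_gene <- c(pairs_gene, rep(g, length(terms)))
    pairs_term <- c(pairs_term, terms)
  }
  sets <- lapply(split(pairs_gene, pairs_term), unique)
  sets[setdiff(names(sets), dag$root)]
}

#' Read and write gene-to-term annotation maps
#'
#' Two-column TSV (`gene`, `term`), one row per gene-term pair, per
#' namespace file.
#'
#' @param path File path.
#' @return `read_annotations()` returns a named list gene -> character
#'   vector of term ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  assert_that(all(c("gene", "term") %in% names(df)),
              "annotation file needs columns gene, term")
  lapply(split(df$term, df$gene), unique)
}

#' @rdname read_annotations
#' @param annotation Named list gene -> term ids.
#' @export
write_annotations <- function(annotation, path) {
  df <- tibble::tibble(
    gene = rep(names(annotation), lengths(annotation)),
    term = unlist(annotation, use.names = FALSE))
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
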