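# Ontology-term enrichment for CGI sets and Wang semantic similarity.
#
# The ontology is a rooted DAG with typed edges (is_a, part_of). CGIs carry
# terms through their assigned genes; enrichment contrasts a target CGI set
# against the background CGI universe with one-sided Fisher tests, BH
# correction, a minimum background-count filter, and a semantic-similarity
# collapse of redundant significant terms.

#' Construct an ontology term graph
#'
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (each relation one of `"is_a"`, `"part_of"`).
#' @param terms Optional character vector of all term ids (defaults to the
#'   ids appearing in `edges`).
#' @return An object of class `term_graph` with components `terms`,
#'   `edges` and `roots`. Construction fails on cyclic edge sets.
#' @export
term_graph <- function(edges, terms = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && !all(c("child", "parent", "relation") %in% names(edges)))
    stop_bad("edges need columns child, parent, relation")
  if (nrow(edges) > 0 && !all(edges$relation %in% c("is_a", "part_of")))
    stop_bad("relation must be 'is_a' or 'part_of'")
  terms <- sort(unique(c(terms, edges$child, edges$parent)))
  if (length(terms) == 0L) stop_bad("term graph has no terms")
  # Kahn-style check for acyclicity: repeatedly peel terms with no
  # remaining outgoing (child -> parent) edge; a stuck non-empty residue
  # means a cycle.
  remaining <- edges
  pending <- terms
  while (length(pending) > 0L) {
    sinks <- setdiff(pending, remaining$child)
    if (length(sinks) == 0L) stop_bad("ontology edges contain a cycle")
    pending <- setdiff(pending, sinks)
    remaining <- remaining[!(remaining$parent %in% sinks), , drop = FALSE]
  }
  roots <- setdiff(terms, edges$child)
  structure(list(terms = terms, edges = edges, roots = roots),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("Ontology term graph: %d terms, %d edges, root(s): %s\n",
              length(x$terms), nrow(x$edges), paste(x$roots, collapse = ", ")))
  invisible(x)
}

parents_of <- function(graph, term) {
  e <- graph$edges
  e$parent[e$child == term]
}

#' All ancestors of a term (excluding itself)
#'
#' @param graph A [term_graph()].
#' @param term Term id.
#' @return Character vector of ancestor term ids (set semantics: each
#'   ancestor once, regardless of the number of paths).
#' @export
term_ancestors <- function(graph, term) {
  if (!term %in% graph$terms) stop_bad("unknown term: ", term)
  seen <- character(0)
  frontier <- parents_of(graph, term)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, parents_of, graph = graph))), seen)
  }
  seen
}

#' Close gene-term assignments under the parent relation
#'
#' Extends each gene's direct term set with all ancestor terms up to the
#' root(s), with set semantics (idempotent).
#'
#' @param assignments Named list: gene id -> character vector of direct
#'   term ids.
#' @param graph A [term_graph()].
#' @return Named list: gene id -> full term set.
#' @export
propagate_ancestors <- function(assignments, graph) {
  unknown <- setdiff(unique(unlist(assignments)), graph$terms)
  if (length(unknown)) stop_bad("unknown term id(s): ", paste(unknown, collapse = ", "))
  anc_cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    res <- term_ancestors(graph, t)
    anc_cache[[t]] <- res
    res
  }
  lapply(assignments, function(ts) {
    sort(unique(c(ts, unlist(lapply(ts, anc)))))
  })
}

#' Term enrichment of a target CGI set against a background
#'
#' A CGI carries a term if any of its assigned genes carries it (after
#' ancestor propagation). For every term, the 2x2 table (target vs rest) x
#' (has term vs not) is tested with a one-sided Fisher's exact test for
#' enrichment; terms carried by fewer than `min_background` background
#' CGIs are excluded before testing; p-values are BH-adjusted across the
#' tested terms.
#'
#' @param target_cgis Character vector of target CGI ids (subset of
#'   `background_cgis`).
#' @param background_cgis Character vector: the CGI universe.
#' @param cgi_to_genes Named list: CGI id -> assigned gene ids.
#' @param gene_to_terms Named list: gene id -> term ids (propagate with
#'   [propagate_ancestors()] first for ancestor-closed counts).
#' @param min_background Minimum background CGI count per term (default 10;
#'   terms below it are excluded, boundary exclusive: `k < 10` drops).
#' @param fdr Significance threshold on the adjusted p (default 0.05).
#' @return A `term_enrichment` data.frame: `term, k_target, n_target,
#'   k_background, n_background, odds_ratio, fold_enrichment, p_value,
#'   q_value, significant`, ordered by q then p then term id.
#' @export
enrich_terms <- function(target_cgis, background_cgis, cgi_to_genes,
                         gene_to_terms, min_background = 10, fdr = 0.05) {
  if (length(background_cgis) == 0L) stop_bad("empty background")
  if (!all(target_cgis %in% background_cgis))
    stop_bad("target CGIs must be a subset of the background")
  cgi_terms <- lapply(background_cgis, function(cg) {
    genes <- cgi_to_genes[[cg]]
    sort(unique(unlist(gene_to_terms[genes])))
  })
  names(cgi_terms) <- background_cgis
  n_bg <- length(background_cgis)
  n_tg <- length(target_cgis)
  is_target <- background_cgis %in% target_cgis
  term_tab_bg <- table(unlist(cgi_terms))
  term_tab_tg <- table(unlist(cgi_terms[is_target]))
  terms <- names(term_tab_bg)[term_tab_bg >= min_background]
  if (length(terms) == 0L)
    return(structure(data.frame(), class = c("term_enrichment", "data.frame")))
  k_bg <- as.integer(term_tab_bg[terms])
  k_tg <- as.integer(ifelse(is.na(term_tab_tg[terms]), 0L, term_tab_tg[terms]))
  a <- k_tg; b <- n_tg - k_tg
  c_ <- k_bg - k_tg; d <- (n_bg - n_tg) - c_
  p <- fisher_p_2x2(a, b, c_, d, alternative = "greater")
  q <- benjamini_hochberg(p)
  orat <- odds_ratio_2x2(a, b, c_, d)
  fold <- (k_tg / n_tg) / (k_bg / n_bg)
  out <- data.frame(term = terms, k_target = k_tg, n_target = n_tg,
                    k_background = k_bg, n_background = n_bg,
                    odds_ratio = orat, fold_enrichment = fold,
                    p_value = p, q_value = q, significant = q < fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_enrichment", "data.frame")
  out
}

#' Wang semantic similarity between two ontology terms
#'
#' Implements the graph-based Wang measure: each term's ancestor graph is
#' scored with S-values (1 for the term itself; an ancestor's S-value is
#' the maximum over paths of the product of edge contribution factors),
#' and the similarity is the summed S-values of the common ancestors
#' (including the terms themselves when shared) from both sides, divided
#' by the two terms' total semantic values.
#'
#' @param term_a,term_b Term ids.
#' @param graph A [term_graph()].
#' @param weights Named contribution factors per relation; defaults to the
#'   method's original parameterisation `c(is_a = 0.8, part_of = 0.6)`.
#' @return Similarity in \[0, 1\]; 1 iff the terms are identical (for
#'   weights < 1).
#' @export
wang_similarity <- function(term_a, term_b, graph,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- wang_svalues(term_a, graph, weights)
  sb <- wang_svalues(term_b, graph, weights)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

wang_svalues <- function(term, graph, weights) {
  if (!term %in% graph$terms) stop_bad("unknown term: ", term)
  sv <- setNames(1, term)
  # relax upwards until fixpoint; products are monotone decreasing on a DAG
  repeat {
    changed <- FALSE
    for (t in names(sv)) {
      e <- graph$edges[graph$edges$child == t, , drop = FALSE]
      if (nrow(e) == 0L) next
      w <- unname(weights[e$relation]) * sv[[t]]
      for (j in seq_len(nrow(e))) {
        p <- e$parent[j]
        if (is.null(sv[p]) || is.na(sv[p]) || sv[p] < w[j]) {
          sv[p] <- w[j]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sv
}

#' Collapse semantically similar enriched terms
#'
#' Greedy redundancy filter in the style of ontology "simplify" steps:
#' walk the results in ascending q-value order (ties broken by term id);
#' keep the current term and discard every not-yet-kept term whose Wang
#' similarity to it exceeds `threshold`. Within each group of mutually
#' similar terms, exactly the lowest-q member is retained.
#'
#' @param results A `term_enrichment` data.frame (from [enrich_terms()]).
#' @param graph The [term_graph()] the terms come from.
#' @param threshold Similarity threshold (strict: `> 0.7` collapses).
#' @param weights Edge contribution factors, as in [wang_similarity()].
#' @return `results` with an added logical column `kept_after_collapse`.
#' @export
collapse_similar_terms <- function(results, graph, threshold = 0.7,
                                   weights = c(is_a = 0.8, part_of = 0.6)) {
  if (nrow(results) == 0L) {
    results$kept_after_collapse <- logical(0)
    return(results)
  }
  ord <- order(results$q_value, results$p_value, results$term)
  kept <- logical(nrow(results))
  discarded <- logical(nrow(results))
  for (i in ord) {
    if (discarded[i]) next
    kept[i] <- TRUE
    for (j in ord) {
      if (j == i || kept[j] || discarded[j]) next
      if (wang_similarity(results$term[i], results$term[j], graph, weights) > threshold)
        discarded[j] <- TRUE
    }
  }
  results$kept_after_collapse <- kept
  results
}
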