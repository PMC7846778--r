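# small fixed DAG used throughout: root -> {mid1, mid2}; leaves under mids
chain_graph <- function() {
  term_graph(edges = data.frame(
    child = c("mid", "leaf"),
    parent = c("root", "mid"),
    relation = c("is_a", "is_a"), stringsAsFactors = FALSE))
}

test_that("term graphs validate structure and reject cycles", {
  g <- chain_graph()
  expect_equal(g$roots, "root")
  expect_error(term_graph(data.frame(child = c("a", "b"), parent = c("b", "a"),
                                     relation = "is_a")), "cycle")
  expect_error(term_graph(data.frame(child = "a", parent = "b", relation = "near")),
               "is_a")
})

test_that("ancestor propagation closes assignments up to the root", {
  g <- chain_graph()
  expect_equal(propagate_ancestors(list(g1 = "root"), g)$g1, "root")
  expect_equal(propagate_ancestors(list(g1 = "leaf"), g)$g1,
               c("leaf", "mid", "root"))

  # diamond: each ancestor once (set semantics), and idempotence
  dia <- term_graph(data.frame(child = c("b", "c", "d", "d"),
                               parent = c("a", "a", "b", "c"),
                               relation = "is_a"))
  once <- propagate_ancestors(list(g = "d"), dia)
  expect_equal(once$g, c("a", "b", "c", "d"))
  expect_identical(propagate_ancestors(once, dia), once)

  expect_error(propagate_ancestors(list(g = "ghost"), g), "unknown term")
})

test_that("term enrichment filters small-background terms and matches the Fisher oracle", {
  # 100 CGIs, one gene each; term A on 30 background CGIs, strongly targeted;
  # term B on 9 background CGIs (must be excluded); root on everyone
  cgis <- sprintf("cgi%03d", 1:100)
  genes <- sprintf("g%03d", 1:100)
  cgi2gene <- setNames(as.list(genes), cgis)
  g2t <- setNames(rep(list("root"), 100), genes)
  for (i in 1:30) g2t[[i]] <- c(g2t[[i]], "termA")
  for (i in 91:99) g2t[[i]] <- c(g2t[[i]], "termB")
  target <- cgis[c(1:18, 95:96)]  # 18 of 20 carry termA
  res <- enrich_terms(target, cgis, cgi2gene, g2t, min_background = 10)
  expect_false("termB" %in% res$term)       # background 9 < 10: excluded
  ra <- res[res$term == "termA", ]
  expect_equal(ra$k_target, 18)
  expect_equal(ra$k_background, 30)
  expect_equal(ra$p_value, oracle_fisher_2x2(18, 2, 12, 68, "greater"),
               tolerance = 1e-12)
  expect_true(ra$significant)

  # a term carried by every CGI: odds ratio region of 1, p = 1
  rr <- res[res$term == "root", ]
  expect_equal(rr$p_value, 1)
  expect_equal(rr$fold_enrichment, 1)

  expect_error(enrich_terms("x", character(), cgi2gene, g2t), "empty background")
  expect_error(enrich_terms("zzz", cgis, cgi2gene, g2t), "subset")
})

test_that("a planted ontology enrichment is recovered at FDR 0.05", {
  sim <- simulate_ontology(n_terms = 40, depth = 3, n_genes = 300, seed = 9)
  g2t <- propagate_ancestors(sim$gene_to_terms, sim$graph)
  genes <- names(sim$gene_to_terms)
  cgis <- sprintf("cgi_%04d", seq_along(genes))
  cgi2gene <- setNames(as.list(genes), cgis)
  target <- cgis[match(sim$truth$planted_genes, genes)]
  res <- enrich_terms(target, cgis, cgi2gene, g2t)
  planted <- res[res$term == sim$truth$planted_term, ]
  expect_equal(nrow(planted), 1)
  expect_lt(planted$q_value, 0.05)
})

test_that("Wang similarity: self-identity, hand-computed value, symmetry, range", {
  two_leaves <- term_graph(data.frame(child = c("x", "y"),
                                      parent = c("root", "root"),
                                      relation = c("is_a", "is_a")))
  expect_equal(wang_similarity("x", "x", two_leaves), 1)
  # S-values: each leaf {self: 1, root: 0.8}, SV = 1.8; shared: root only
  expect_equal(wang_similarity("x", "y", two_leaves), (0.8 + 0.8) / (1.8 + 1.8))
  expect_equal(wang_similarity("x", "y", two_leaves), wang_similarity("y", "x", two_leaves))

  # part_of edges use their own weight
  po <- term_graph(data.frame(child = c("x", "y"), parent = c("root", "root"),
                              relation = c("part_of", "part_of")))
  expect_equal(wang_similarity("x", "y", po), (0.6 + 0.6) / (1.6 + 1.6))

  # multiple paths: the max-product path defines the S-value
  dia <- term_graph(data.frame(child = c("b", "c", "d", "d"),
                               parent = c("a", "a", "b", "c"),
                               relation = c("is_a", "part_of", "is_a", "is_a")))
  sv <- cgimeth:::wang_svalues("d", dia, c(is_a = 0.8, part_of = 0.6))
  expect_equal(unname(sv["a"]), 0.8 * 0.8)  # via b, not 0.8 * 0.6 via c

  set.seed(skip_free_seed)
  for (i in 1:10) {
    sim <- simulate_ontology(n_terms = 15, depth = 3, n_genes = 5, seed = i)
    ts <- sample(sim$graph$terms, 2)
    s_ab <- wang_similarity(ts[1], ts[2], sim$graph)
    expect_equal(s_ab, wang_similarity(ts[2], ts[1], sim$graph))
    expect_gte(s_ab, 0); expect_lte(s_ab, 1)
    if (ts[1] != ts[2]) expect_lt(s_ab, 1)
  }
  expect_error(wang_similarity("nope", "x", two_leaves), "unknown term")
})

test_that("similarity collapse keeps exactly the lowest-q term per similar group", {
  # x, y, z share both parents (p1, p2) and a grandparent chain, so all
  # pairwise Wang similarities exceed 0.7; far2 sits on an unrelated branch
  g <- term_graph(data.frame(
    child = c("q", "p1", "p2", "x", "x", "y", "y", "z", "z", "far1", "far2"),
    parent = c("root", "q", "q", "p1", "p2", "p1", "p2", "p1", "p2",
               "root", "far1"),
    relation = "is_a"))
  expect_gt(wang_similarity("x", "y", g), 0.7)
  expect_gt(wang_similarity("x", "z", g), 0.7)
  expect_lt(wang_similarity("x", "far2", g), 0.7)

  # three mutually similar terms: exactly the lowest-q one survives
  res <- data.frame(term = c("x", "y", "z", "far2"),
                    q_value = c(0.01, 0.02, 0.015, 0.03),
                    p_value = c(0.001, 0.002, 0.0015, 0.003),
                    stringsAsFactors = FALSE)
  out <- collapse_similar_terms(res, g)
  expect_equal(out$term[out$kept_after_collapse], c("x", "far2"))

  # pair of similar terms: lowest q wins
  res_pair <- data.frame(term = c("x", "y"), q_value = c(0.02, 0.01),
                         p_value = c(0.002, 0.001))
  out_pair <- collapse_similar_terms(res_pair, g)
  expect_equal(out_pair$term[out_pair$kept_after_collapse], "y")

  # all pairwise similarities below threshold: everything kept
  res2 <- data.frame(term = c("x", "far2"), q_value = c(0.01, 0.02),
                     p_value = c(0.001, 0.002))
  out2 <- collapse_similar_terms(res2, g)
  expect_true(all(out2$kept_after_collapse))

  # deterministic tie-break by term id at equal q
  res3 <- data.frame(term = c("y", "x"), q_value = c(0.01, 0.01),
                     p_value = c(0.001, 0.001))
  out3 <- collapse_similar_terms(res3, g)
  expect_equal(out3$term[out3$kept_after_collapse], "x")
})
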