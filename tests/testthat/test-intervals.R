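test_that("overlapping and book-ended intervals merge into sorted disjoint unions", {
  x <- genomic_intervals(c("chr1", "chr1"), c(100, 150), c(200, 250))
  m <- merge_intervals(x)
  expect_equal(m[, c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 100, end = 250))

  be <- genomic_intervals(c("chr1", "chr1"), c(100, 200), c(200, 300))
  expect_equal(merge_intervals(be)$end, 300)

  empty <- genomic_intervals(character(), numeric(), numeric())
  expect_equal(nrow(merge_intervals(empty)), 0)

  expect_error(genomic_intervals("chr1", 200, 200), "malformed")
})

test_that("merge_intervals is idempotent and matches the base-set union oracle", {
  set.seed(skip_free_seed)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    s <- sample(0:80, n, replace = TRUE)
    x <- genomic_intervals(sample(c("chr1", "chr2"), n, replace = TRUE),
                           s, s + sample(1:30, n, replace = TRUE))
    m <- merge_intervals(x)
    expect_identical(m[, 1:3], merge_intervals(m)[, 1:3])
    o <- oracle_merge(x)
    expect_equal(m$start, o$start)
    expect_equal(m$end, o$end)
    expect_equal(m$chrom, o$chrom)
  }
})

test_that("interval filtering enforces chromosome whitelist and blacklist overlap", {
  cgis <- genomic_intervals(c("chr1", "chrX", "chr2"), c(0, 10, 100),
                            c(50, 60, 200), name = c("a", "b", "c"))
  auto <- sprintf("chr%d", 1:22)
  expect_equal(filter_intervals(cgis, allowed_chroms = auto)$name, c("a", "c"))

  bl <- genomic_intervals("chr2", 199, 300)  # 1 bp overlap with c
  expect_equal(filter_intervals(cgis, blacklist = bl)$name, c("a", "b"))
  bl2 <- genomic_intervals("chr2", 200, 300)  # book-ended, no overlap
  expect_equal(filter_intervals(cgis, blacklist = bl2)$name, c("a", "b", "c"))

  expect_identical(filter_intervals(cgis,
                                    blacklist = genomic_intervals(character(), numeric(), numeric())),
                   cgis)
})

test_that("CGI annotation applies TSS > gene body > intergenic precedence", {
  genes <- gene_models(gene_id = c("g1", "g2"), chrom = c("chr1", "chr1"),
                       tss = c(1000, 5000), tx_start = c(1000, 3000),
                       tx_end = c(2000, 6000))
  cgis <- genomic_intervals(rep("chr1", 3), c(900, 3500, 8000),
                            c(1100, 3600, 8200), name = c("at_tss", "in_body", "nowhere"))
  ann <- annotate_cgis(cgis, genes)
  expect_equal(ann$category, c("TSS", "gene_body", "intergenic"))
  expect_equal(ann$assigned_genes[1:2], c("g1", "g2"))

  # a CGI overlapping g1's TSS and g2's body is TSS (precedence)
  both <- genomic_intervals("chr1", 950, 3500, name = "both")
  expect_equal(annotate_cgis(both, genes)$category, "TSS")

  # category counts invariant to input ordering
  perm <- cgis[c(3, 1, 2), ]
  expect_equal(sort(table(annotate_cgis(perm, genes)$category)),
               sort(table(ann$category)))
  expect_error(annotate_cgis(cgis, genes[0, ]), "non-empty")
})

test_that("CGI-to-gene mapping follows TSS, transcript, then closest-TSS with ties", {
  genes <- gene_models(gene_id = c("g1", "g2", "g3"),
                       chrom = c("chr1", "chr1", "chr1"),
                       tss = c(1000, 1050, 9000),
                       tx_start = c(1000, 900, 9000),
                       tx_end = c(2000, 1500, 9500))
  two_tss <- genomic_intervals("chr1", 990, 1060, name = "two_tss")
  expect_equal(map_cgis_to_genes(two_tss, genes)$two_tss, c("g1", "g2"))

  in_tx <- genomic_intervals("chr1", 1600, 1700, name = "in_tx")
  expect_equal(map_cgis_to_genes(in_tx, genes)$in_tx, "g1")

  # intergenic CGI equidistant from g3's TSS (9000) and g1's TSS (1000):
  # edges at 4900 and 5100 -> distances 3900+1 to the left edge... use exact
  eq <- genomic_intervals("chr1", 4950, 5051, name = "eq")
  # distance to g1 tss: 4950 - 1000 = 3950; to g3: 9000 - 5050 = 3950
  expect_equal(map_cgis_to_genes(eq, genes[c(1, 3), ])$eq, c("g1", "g3"))

  lost <- genomic_intervals("chr9", 0, 100, name = "lost")
  m <- map_cgis_to_genes(lost, genes)
  expect_length(m$lost, 0)
  expect_equal(attr(m, "unmapped"), "lost")
})

test_that("peak overlap enrichment matches the hypergeometric tail oracle", {
  # background of 100 CGIs; peaks overlap the first 8 of 10 targets and 10 of the rest
  bg <- genomic_intervals(rep("chr1", 100), seq(0, by = 1000, length.out = 100),
                          seq(500, by = 1000, length.out = 100))
  target <- bg[1:10, ]
  ov_idx <- c(1:8, 11:20)
  peaks <- genomic_intervals(rep("chr1", length(ov_idx)), bg$start[ov_idx] + 10,
                             bg$start[ov_idx] + 20)
  res <- overlap_enrichment(target, peaks, bg, sided = "greater")
  expect_equal(res$table["overlap", "target"], 8)
  expect_equal(res$fold_enrichment, (8 / 10) / (18 / 100))
  expect_equal(res$p_value, oracle_fisher_2x2(8, 2, 10, 80, "greater"), tolerance = 1e-12)

  # degenerate: target equals background
  res2 <- overlap_enrichment(bg, peaks, bg)
  expect_equal(res2$fold_enrichment, 1)
  expect_equal(res2$p_value, 1)

  expect_error(overlap_enrichment(genomic_intervals("chr2", 0, 10), peaks, bg),
               "subset")
})

test_that("fragment counting increments every overlapped region", {
  regions <- genomic_intervals(c("chr1", "chr1"), c(0, 100), c(100, 200),
                               name = c("r1", "r2"))
  spanning <- genomic_intervals("chr1", 90, 110)
  expect_equal(unname(count_overlaps(spanning, regions)), c(1, 1))
  expect_equal(unname(count_overlaps(regions[0, ], regions)), c(0, 0))
  exact <- genomic_intervals("chr1", 0, 100)
  expect_equal(count_overlaps(exact, regions)[["r1"]], 1)
})

test_that("midpoint-centred windows are contiguous with documented centring", {
  region <- genomic_intervals("chr1", 900, 1100, name = "cgi")  # midpoint 1000
  w1 <- make_windows(region, 250, 1)
  expect_equal(c(w1$start, w1$end), c(875, 1125))
  w2 <- make_windows(region, 250, 2)
  expect_equal(w2$start, c(750, 1000))
  expect_equal(w2$end, c(1000, 1250))
  w3 <- make_windows(region, 250, 3)
  expect_equal(w3$start[2], 875)  # middle window centred on the midpoint
  expect_true(all(diff(w3$start) == 250))

  near0 <- genomic_intervals("chr1", 0, 100, name = "edge")  # midpoint 50
  wt <- make_windows(near0, 250, 1)
  expect_equal(wt$start, 0)  # truncated at chromosome start
  expect_equal(wt$end, 175)
})
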