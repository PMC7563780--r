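test_that("adjusted TMB matches hand arithmetic", {
  panel <- tiny_panel(genes = c(paste0("G", 1:20), "BRAF", "TP53", "PTEN"),
                      target_size_mb = 1.3,
                      tumor_genes = c("BRAF", "TP53", "PTEN"),
                      genome_size_mb = 3101.79)
  # 13 somatic, 3 in tumor genes: 10/1.3 + 3/3101.79
  v <- rbind(var_row("A", rep(paste0("G", 1:10))),
             var_row("A", c("BRAF", "TP53", "PTEN")))
  res <- compute_tmb(v, panel, "A")
  expect_equal(res$n_somatic, 13L)
  expect_equal(res$n_tumorgene, 3L)
  expect_equal(res$tmb, 10 / 1.3 + 3 / 3101.79, tolerance = 1e-12)

  # all variants in tumor genes are down-weighted to the genome rate
  panel2 <- tiny_panel(genes = c("BRAF", "TP53"), target_size_mb = 2.0,
                       tumor_genes = c("BRAF", "TP53"),
                       genome_size_mb = 3000)
  v2 <- var_row("A", rep(c("BRAF", "TP53"), c(3, 2)))
  res2 <- compute_tmb(v2, panel2, "A")
  expect_equal(res2$tmb, 5 / 3000, tolerance = 1e-12)

  expect_equal(compute_tmb(empty_variants(), panel)$tmb, 0)
})

test_that("TMB increments are exactly the per-megabase rates", {
  panel <- tiny_panel()
  v <- var_row("A", "FILLER1")
  base <- compute_tmb(v, panel)$tmb
  plus_nontumor <- compute_tmb(rbind(v, var_row("A", "FILLER2")), panel)$tmb
  plus_tumor <- compute_tmb(rbind(v, var_row("A", "BRAF")), panel)$tmb
  expect_equal(plus_nontumor - base, 1 / panel$target_size_mb,
               tolerance = 1e-12)
  expect_equal(plus_tumor - base, 1 / panel$genome_size_mb,
               tolerance = 1e-12)
})

test_that("with no known tumor genes the TMB reduces to the naive panel rate", {
  panel <- panel_definition(c("A1", "A2", "A3"), target_size_mb = 1.7,
                            tumor_genes = character(0))
  v <- var_row("A", c("A1", "A2", "A3", "A1"))
  expect_equal(compute_tmb(v, panel)$tmb, 4 / 1.7, tolerance = 1e-12)
})

test_that("doubling the target size halves the panel term exactly", {
  genes <- c("BRAF", paste0("G", 1:6))
  p1 <- tiny_panel(genes = genes, tumor_genes = "BRAF",
                   target_size_mb = 1.1)
  p2 <- tiny_panel(genes = genes, tumor_genes = "BRAF",
                   target_size_mb = 2.2)
  v <- var_row("A", c(paste0("G", 1:5), "BRAF"))
  expect_equal(compute_tmb(v, p2)$panel_term,
               compute_tmb(v, p1)$panel_term / 2, tolerance = 1e-12)
  expect_equal(compute_tmb(v, p2)$genome_term,
               compute_tmb(v, p1)$genome_term, tolerance = 1e-12)
})

test_that("burden summaries handle single-patient and constant groups", {
  cl <- rbind(clin_row("A", subtype = "uveal"),
              clin_row("B", subtype = "cutaneous"),
              clin_row("C", subtype = "cutaneous"))
  v <- rbind(var_row("A", "FILLER1", driver = FALSE),
             var_row("A", "FILLER2", driver = FALSE),
             var_row("B", "FILLER1", driver = FALSE),
             var_row("B", "FILLER2", driver = FALSE),
             var_row("C", "FILLER1", driver = FALSE),
             var_row("C", "FILLER2", driver = FALSE))
  coh <- tiny_cohort(cl, v)
  s <- summarize_burden(coh, "tmb")
  uv <- s[s$subtype == "uveal", ]
  expect_equal(uv$n, 1)
  expect_equal(uv$q1, uv$median)
  expect_equal(uv$q3, uv$median)
  expect_equal(uv$min, uv$max)
  # identical burden everywhere -> every group median equal
  expect_equal(unique(s$median), 2 / coh$panel$target_size_mb)
  expect_error(summarize_burden(tiny_cohort(clin_row("A")[0, ])),
               "empty cohort")
})
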