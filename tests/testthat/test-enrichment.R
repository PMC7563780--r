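test_that("the uveal MYC table gives the known one-sided exact p", {
  # a=8 altered uveal, b=0, c=12 altered elsewhere, d=62
  coh <- make_paper_fixture()
  enr <- gene_enrichment(coh)
  myc <- enr[enr$gene == "MYC" & enr$group == "uveal", ]
  expect_equal(c(myc$a, myc$b, myc$c, myc$d), c(8, 0, 12, 62))
  expect_equal(signif(myc$p_one_sided, 2), 3.5e-6)
  expect_equal(myc$direction, "enriched")
  expect_true(myc$significant)
})

test_that("degenerate tables give p = 1 and are never flagged", {
  cl <- rbind(clin_row("A", subtype = "uveal"), clin_row("B"),
              clin_row("C"))
  # BRAF altered in everyone; PTEN in no one
  v <- var_row(c("A", "B", "C"), "BRAF")
  enr <- gene_enrichment(tiny_cohort(cl, v))
  braf <- enr[enr$gene == "BRAF", ]
  expect_true(all(braf$p_one_sided == 1))
  pten <- enr[enr$gene == "PTEN", ]
  expect_true(all(pten$p_one_sided == 1))
  expect_false(any(pten$significant))
  expect_error(gene_enrichment(tiny_cohort(clin_row("A"))),
               "two subtypes")
})

test_that("exact tests equal brute-force margin-fixed enumeration (n <= 30)", {
  set.seed(42)
  for (i in 1:60) {
    t <- random_table()
    a <- t[["a"]]; b <- t[["b"]]; c <- t[["c"]]; d <- t[["d"]]
    oracle <- oracle_fisher(a, b, c, d)
    expect_equal(melcohort:::fisher_p(a, b, c, d, "greater"),
                 oracle$greater, tolerance = 1e-10)
    expect_equal(melcohort:::fisher_p(a, b, c, d, "two.sided"),
                 oracle$two.sided, tolerance = 1e-10)
  }
})

test_that("swapping group and rest maps the enrichment p to the opposite tail", {
  tables <- list(c(5, 3, 2, 10), c(8, 0, 12, 62), c(1, 7, 6, 6))
  for (t in tables) {
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    expect_equal(melcohort:::fisher_p(a, b, c, d, "greater"),
                 melcohort:::fisher_p(c, d, a, b, "less"),
                 tolerance = 1e-12)
    expect_equal(melcohort:::fisher_p(a, b, c, d, "two.sided"),
                 melcohort:::fisher_p(c, d, a, b, "two.sided"),
                 tolerance = 1e-12)
  }
})

test_that("moving an altered patient into the group never increases the enrichment p", {
  # margins fixed: (a, b, c, d) -> (a+1, b-1, c-1, d+1)
  for (t in list(c(2, 6, 4, 8), c(0, 5, 5, 10), c(3, 3, 3, 3))) {
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    p0 <- melcohort:::fisher_p(a, b, c, d, "greater")
    p1 <- melcohort:::fisher_p(a + 1, b - 1, c - 1, d + 1, "greater")
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("Mann-Whitney exact branch matches enumeration and handles ties", {
  # canonical small example: complete separation of 3 vs 3
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact")
  # identical samples -> p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(7)
  for (i in 1:30) {
    x <- sample(1:5, sample(2:6, 1), replace = TRUE)  # heavy ties
    y <- sample(1:5, sample(2:6, 1), replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_two_sided(x, y),
                 tolerance = 1e-10, info = paste("case", i))
  }
})

test_that("large groups fall back to the tie-corrected normal approximation", {
  set.seed(3)
  x <- rpois(20, 6); y <- rpois(15, 9)
  mw <- mann_whitney(x, y)
  expect_equal(mw$method, "normal_approx")
  expect_equal(mw$p_value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = FALSE)$p.value,
               tolerance = 1e-12)
})

test_that("burden comparisons run against the cutaneous reference", {
  coh <- make_paper_fixture()
  bt <- compare_burden(coh, "tmb")
  expect_setequal(bt$subtype, c("acral", "mucosal", "uveal", "occult"))
  expect_true(all(bt$p_value >= 0 & bt$p_value <= 1))
  expect_true(all(bt$n_ref == 42))
  expect_error(compare_burden(coh, "tmb", reference_subtype = "nodular"),
               "no patients")
})

test_that("simulated mucosal-vs-cutaneous CNV excess is usually detected", {
  # mucosal melanoma simulates a median of 33 CNVs vs 8 in cutaneous;
  # the Mann-Whitney comparison should reject at 0.05 in most replicates
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(simulation_config(n_patients = 82, seed = 500 + r))
    bt <- compare_burden(coh, "n_cnv")
    p <- bt$p_value[bt$subtype == "mucosal"]
    if (length(p) == 1 && !is.na(p) && p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits, n_rep / 2)
})
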