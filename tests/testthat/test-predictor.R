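test_that("rules fire on unions, combinations and the pretreatment clause", {
  cl <- rbind(clin_row("A"), clin_row("B"), clin_row("C", pretreated = TRUE),
              clin_row("D"))
  cn <- rbind(cnv_row("A", "PTEN"),                    # union hit
              cnv_row("B", "CDKN2A"))                  # single gene only
  coh <- tiny_cohort(cl, cnvs = cn)

  union3 <- resistance_rule(c("EGFR", "PTEN", "TP53"))
  expect_true(apply_rule(union3, coh)[["A"]])
  expect_false(apply_rule(union3, coh)[["B"]])
  expect_false(apply_rule(union3, coh)[["D"]])  # no alterations

  combo <- resistance_rule(c("EGFR", "PTEN", "TP53", "CDKN2A"),
                           combination_k = 2)
  expect_false(apply_rule(combo, coh)[["B"]])  # one gene < k = 2
  coh2 <- tiny_cohort(cl, var_row("B", "TP53"), cn)
  expect_true(apply_rule(combo, coh2)[["B"]])

  with_pre <- resistance_rule(c("EGFR", "PTEN", "TP53"),
                              require_pretreatment = TRUE)
  expect_true(apply_rule(with_pre, coh)[["C"]])
  expect_error(resistance_rule(character(0)), "gene_set")
  expect_error(resistance_rule(c("A", "B"), combination_k = 3),
               "combination_k")
})

test_that("the four reference-rule variants reproduce their printed performance", {
  coh <- make_paper_fixture()
  rules <- default_rules()

  p <- evaluate_rule(coh, rules$pretreat_or_gene)
  expect_equal(c(p$a, p$b, p$c, p$d), c(28, 6, 17, 24))
  expect_equal(100 * p$sensitivity, 62.2, tolerance = 0.05)
  expect_equal(100 * p$specificity, 80.0, tolerance = 0.05)
  expect_equal(p$relative_risk, 1.99, tolerance = 0.005)

  p <- evaluate_rule(coh, rules$reduced)
  expect_equal(c(p$a, p$b, p$c, p$d), c(19, 4, 26, 26))
  expect_equal(p$relative_risk, 1.65, tolerance = 0.005)
  expect_equal(100 * p$ppv, 82.6, tolerance = 0.05)

  p <- evaluate_rule(coh, rules$plus_cdkn2a)
  expect_equal(c(p$a, p$b, p$c, p$d), c(33, 10, 12, 20))
  expect_equal(100 * p$sensitivity, 73.3, tolerance = 0.05)
  expect_equal(100 * p$specificity, 66.7, tolerance = 0.05)
  expect_equal(p$relative_risk, 2.05, tolerance = 0.005)

  p <- evaluate_rule(coh, rules$combination)
  expect_equal(c(p$a, p$b, p$c, p$d), c(9, 0, 36, 30))
  expect_equal(p$specificity, 1.0)
  expect_equal(100 * p$sensitivity, 20.0, tolerance = 0.05)
  expect_equal(p$relative_risk, 1.83, tolerance = 0.005)
})

test_that("performance denominators cover exactly the ICI-treated patients", {
  coh <- make_paper_fixture()
  p <- evaluate_rule(coh, default_rules()$reduced)
  expect_equal(p$n, 75)
  expect_equal(p$a + p$c, 45)  # PD
  expect_equal(p$b + p$d, 30)  # SD + PR
})

test_that("complementing the outcome transposes the 2x2 structure", {
  coh <- make_paper_fixture()
  rule <- default_rules()$pretreat_or_gene
  pd <- evaluate_rule(coh, rule, positive_outcome = "PD")
  # relabel so that disease control becomes the positive outcome
  sd_pr <- local({
    cl <- coh$clinical
    cl$recist_response[cl$recist_response %in% c("SD", "PR")] <- "PD2"
    cl$recist_response[cl$recist_response == "PD"] <- "PD3"
    cl$recist_response[cl$recist_response == "PD2"] <- "PD"
    cl$recist_response[cl$recist_response == "PD3"] <- "SD"
    evaluate_rule(melanoma_cohort(cl, coh$variants, coh$cnvs, coh$panel),
                  rule, positive_outcome = "PD")
  })
  expect_equal(c(sd_pr$a, sd_pr$b, sd_pr$c, sd_pr$d),
               c(pd$b, pd$a, pd$d, pd$c))
  expect_equal(sd_pr$sensitivity, 1 - pd$specificity)
  expect_equal(sd_pr$specificity, 1 - pd$sensitivity)
})

test_that("relative risk satisfies its defining algebra and undefined cases are flagged", {
  coh <- make_paper_fixture()
  for (rule in default_rules()) {
    p <- evaluate_rule(coh, rule)
    if (!p$rr_undefined)
      expect_equal(p$relative_risk * (p$c / (p$c + p$d)),
                   p$a / (p$a + p$b), tolerance = 1e-12)
  }
  # a rule that fires for every patient leaves the negative stratum empty
  cl <- rbind(clin_row("A"), clin_row("B", response = "PR"))
  cn <- rbind(cnv_row("A", "PTEN"), cnv_row("B", "PTEN"))
  p <- evaluate_rule(tiny_cohort(cl, cnvs = cn),
                     resistance_rule("PTEN"))
  expect_equal(p$specificity, 0)
  expect_true(p$rr_undefined)
  expect_true(is.na(p$relative_risk))
  expect_error(evaluate_rule(tiny_cohort(clin_row("A", regimen = "none",
                                                  response = "not_applicable")),
                             resistance_rule("PTEN")),
               "no ICI-treated")
})

test_that("predictor Fisher p matches brute-force enumeration", {
  coh <- make_paper_fixture()
  for (rule in default_rules()) {
    p <- evaluate_rule(coh, rule)
    oracle <- oracle_fisher(p$a, p$b, p$c, p$d)
    expect_equal(p$fisher_p, oracle$two.sided, tolerance = 1e-9)
    expect_equal(p$fisher_p_one_sided, oracle$greater, tolerance = 1e-9)
  }
})

test_that("response frequencies report the reference-cohort fractions", {
  coh <- make_paper_fixture()
  rf <- response_frequencies(coh, c("EGFR", "TP53", "PTEN", "ABSENT"))
  expect_equal(rf$pd_total, rep(45L, 4))
  expect_equal(rf$dc_total, rep(30L, 4))
  egfr <- rf[rf$gene == "EGFR", ]
  expect_equal(c(egfr$pd_n, egfr$dc_n), c(6L, 0L))
  expect_equal(100 * egfr$pd_freq, 13.3, tolerance = 0.05)
  tp53 <- rf[rf$gene == "TP53", ]
  expect_equal(c(tp53$pd_n, tp53$dc_n), c(6L, 1L))
  expect_equal(100 * tp53$dc_freq, 3.3, tolerance = 0.05)
  pten <- rf[rf$gene == "PTEN", ]
  expect_equal(c(pten$pd_n, pten$dc_n), c(11L, 3L))
  absent <- rf[rf$gene == "ABSENT", ]
  expect_equal(c(absent$pd_n, absent$dc_n), c(0L, 0L))
})
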