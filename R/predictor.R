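# Rule-based predictor of resistance to immune checkpoint inhibition.
#
# A resistance rule fires for a patient when at least `combination_k`
# distinct genes of its gene set carry a driver alteration (SNV or CNV), or
# -- if the rule includes the pretreatment clause -- when the patient
# received BRAF/MEK inhibition before ICI. Rule performance is evaluated
# on the ICI-treated patients only, against RECIST progressive disease
# (PD) versus disease control (SD + PR), as a 2x2 diagnostic table with
# sensitivity, specificity, predictive values, the relative risk of PD and
# Fisher's exact p.

#' Define a resistance rule
#'
#' @param gene_set genes whose driver alterations can fire the rule
#'   (alteration in any `combination_k` distinct members fires it).
#' @param combination_k minimum number of distinct altered genes from
#'   `gene_set` required; 1 gives plain union semantics.
#' @param require_pretreatment if `TRUE`, BRAF/MEKi pretreatment fires the
#'   rule regardless of the gene clause (logical OR).
#' @param name optional label used in reports.
#' @return object of class `resistance_rule`.
#' @export
resistance_rule <- function(gene_set, combination_k = 1L,
                            require_pretreatment = FALSE,
                            name = NULL) {
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0L && !require_pretreatment)
    stop("a rule needs a non-empty gene_set or the pretreatment clause",
         call. = FALSE)
  combination_k <- as.integer(combination_k)
  if (combination_k < 1L || combination_k > max(1L, length(gene_set)))
    stop("combination_k must be in 1..|gene_set|", call. = FALSE)
  if (is.null(name))
    name <- paste0(paste(gene_set, collapse = "+"),
                   if (combination_k > 1L) sprintf(" (>=%d)", combination_k),
                   if (require_pretreatment) " | pretreated")
  structure(list(gene_set = gene_set, combination_k = combination_k,
                 require_pretreatment = require_pretreatment, name = name),
            class = "resistance_rule")
}

#' The four predictor variants evaluated on melanoma ICI cohorts
#'
#' `reduced`: alteration in any of EGFR/PTEN/TP53. `pretreat_or_gene`: the
#' same union OR BRAF/MEKi pretreatment. `plus_cdkn2a`: adds CDKN2A to the
#' union (pretreatment clause kept). `combination`: at least two distinct
#' altered genes among EGFR/PTEN/TP53/CDKN2A, no pretreatment clause.
#'
#' @return named list of [resistance_rule()] objects.
#' @export
default_rules <- function() {
  g3 <- c("EGFR", "PTEN", "TP53")
  g4 <- c(g3, "CDKN2A")
  list(
    reduced = resistance_rule(g3, name = "reduced"),
    pretreat_or_gene = resistance_rule(g3, require_pretreatment = TRUE,
                                       name = "pretreat_or_gene"),
    plus_cdkn2a = resistance_rule(g4, require_pretreatment = TRUE,
                                  name = "plus_cdkn2a"),
    combination = resistance_rule(g4, combination_k = 2L,
                                  name = "combination"))
}

#' Apply a rule to every patient of a cohort
#'
#' @param rule a [resistance_rule()].
#' @param cohort a [melanoma_cohort()].
#' @return named logical vector over all clinical sample ids.
#' @export
apply_rule <- function(rule, cohort) {
  stopifnot(inherits(rule, "resistance_rule"),
            inherits(cohort, "melanoma_cohort"))
  m <- alteration_matrix(cohort, include_cnv = TRUE, drivers_only = TRUE)
  genes <- intersect(rule$gene_set, colnames(m))
  n_hit <- if (length(genes))
    rowSums(m[, genes, drop = FALSE]) else rep(0L, nrow(m))
  fired <- n_hit >= rule$combination_k
  if (rule$require_pretreatment) {
    pre <- cohort$clinical$braf_meki_pretreated[
      match(rownames(m), cohort$clinical$sample_id)]
    fired <- fired | pre
  }
  stats::setNames(fired, rownames(m))
}

#' Evaluate a resistance rule on the ICI-treated patients
#'
#' Builds the 2x2 table over exactly the ICI-treated patients
#' (a = rule-positive with the positive outcome, b = rule-positive
#' without, c = rule-negative with, d = rule-negative without) and derives
#' sensitivity `a/(a+c)`, specificity `d/(b+d)`, PPV `a/(a+b)`, NPV
#' `d/(c+d)`, relative risk `[a/(a+b)] / [c/(c+d)]` and Fisher's exact p
#' (two-sided, with the one-sided enrichment tail alongside). The relative
#' risk is flagged undefined (not silently NaN) when either rule stratum is
#' empty or no rule-negative patient shows the positive outcome.
#'
#' @param cohort a [melanoma_cohort()].
#' @param rule a [resistance_rule()].
#' @param positive_outcome RECIST category treated as the event
#'   (default `"PD"`; the complement within ICI-treated patients is
#'   disease control).
#' @return object of class `predictor_performance`.
#' @export
evaluate_rule <- function(cohort, rule, positive_outcome = "PD") {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  cl <- cohort$clinical
  ici <- cl$ici_regimen != "none"
  if (!any(ici))
    stop("no ICI-treated patients in cohort", call. = FALSE)
  fired <- apply_rule(rule, cohort)[cl$sample_id]
  pos <- cl$recist_response == positive_outcome
  f <- fired[ici]; p <- pos[ici]
  a <- sum(f & p); b <- sum(f & !p); c <- sum(!f & p); d <- sum(!f & !p)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  rr_undefined <- (a + b) == 0 || (c + d) == 0 || c == 0
  rr <- if (rr_undefined) NA_real_ else (a / (a + b)) / (c / (c + d))
  structure(list(
    rule = rule$name, positive_outcome = positive_outcome,
    n = a + b + c + d,
    a = a, b = b, c = c, d = d,
    sensitivity = rate(a, a + c), specificity = rate(d, b + d),
    ppv = rate(a, a + b), npv = rate(d, c + d),
    relative_risk = rr, rr_undefined = rr_undefined,
    fisher_p = fisher_p(a, b, c, d, "two.sided"),
    fisher_p_one_sided = fisher_p(a, b, c, d, "greater")),
    class = "predictor_performance")
}

#' @export
print.predictor_performance <- function(x, ...) {
  cat(sprintf("rule '%s' on %d ICI-treated patients (outcome %s)\n",
              x$rule, x$n, x$positive_outcome))
  cat(sprintf("  table [a b; c d] = [%d %d; %d %d]\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  sensitivity %s%%  specificity %s%%  PPV %s%%  NPV %s%%\n",
              fmt_pct(x$sensitivity), fmt_pct(x$specificity),
              fmt_pct(x$ppv), fmt_pct(x$npv)))
  cat(sprintf("  relative risk %s  Fisher p (two-sided) %.4g\n",
              if (x$rr_undefined) "undefined"
              else format(round_half_up(x$relative_risk, 2), nsmall = 2),
              x$fisher_p))
  invisible(x)
}

# presentation-only rounding: round-half-up, never used in computation
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  floor(x * pow + 0.5) / pow
}

fmt_pct <- function(x) {
  if (is.na(x)) return("NA")
  format(round_half_up(100 * x, 1), nsmall = 1)
}

#' Alteration frequency of genes in PD versus disease-control patients
#'
#' For each requested gene, the fraction of ICI-treated patients carrying
#' a driver alteration, split by RECIST outcome (PD versus SD+PR).
#' Numerators and denominators are retained.
#'
#' @param cohort a [melanoma_cohort()].
#' @param genes character vector of gene symbols (genes absent from the
#'   panel report zero numerators).
#' @return data.frame with columns `gene`, `pd_n`, `pd_total`, `pd_freq`,
#'   `dc_n`, `dc_total`, `dc_freq`.
#' @export
response_frequencies <- function(cohort, genes) {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  cl <- cohort$clinical
  ici <- cl$ici_regimen != "none"
  if (!any(ici)) stop("no ICI-treated patients in cohort", call. = FALSE)
  m <- alteration_matrix(cohort, include_cnv = TRUE, drivers_only = TRUE)
  m <- m[cl$sample_id[ici], , drop = FALSE]
  pd <- cl$recist_response[ici] == "PD"
  rows <- lapply(genes, function(g) {
    alt <- if (g %in% colnames(m)) m[, g] else rep(FALSE, nrow(m))
    data.frame(gene = g,
               pd_n = sum(alt & pd), pd_total = sum(pd),
               pd_freq = sum(alt & pd) / sum(pd),
               dc_n = sum(alt & !pd), dc_total = sum(!pd),
               dc_freq = sum(alt & !pd) / sum(!pd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
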