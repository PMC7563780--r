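# Stochastic cohort simulator.
#
# Emulates the statistical structure the cohort analyses assume:
# subtype-conditional driver alteration frequencies, per-subtype TMB
# (log-normal, parameterised by its median) and CNV-count (negative
# binomial, median-matched) distributions, BRAF/MEKi pretreatment
# conditional on BRAF status, and a two-point conditional response model
# P(PD | resistance-rule status) for ICI-treated patients. It does not
# emulate per-base sequencing data, allele frequencies or FFPE artifacts;
# what it supports is parameter-recovery testing of every analysis stage.

#' Simulation configuration
#'
#' Defaults encode the study conditions of the reference cohort: subtype
#' proportions 42/14/9/8/9 over 82; per-subtype driver alteration
#' frequencies taken from the reference cohort's oncoplot structure;
#' per-subtype TMB medians 9.4 / 1.5 / 3.2 / 2.8 / 7.5 mut/Mb and CNV-count
#' medians 8 / 12.5 / 33 / 8 / 16; P(PD | rule-positive) = 28/34 and
#' P(PD | rule-negative) = 17/41 for the union+pretreatment rule; ICI
#' probability 75/82 with a 60:15 combined:anti-PD-1 split; pretreatment
#' probability 18/23 for BRAF-mutated patients and 0 otherwise.
#'
#' @param n_patients cohort size.
#' @param seed mandatory RNG seed; identical seeds give byte-identical
#'   cohorts.
#' @param subtype_props named probabilities over the five subtypes.
#' @param gene_probs genes-by-subtype matrix of alteration probabilities;
#'   rows GNAQ/GNA11 are drawn mutually exclusively within uveal.
#' @param tmb_median,tmb_sdlog per-subtype log-normal TMB parameters
#'   (median in mut/Mb; `sdlog` on the log scale).
#' @param cnv_median,cnv_size per-subtype negative-binomial CNV-count
#'   parameters (median matched numerically; `size` is the dispersion).
#' @param p_ici probability of ICI treatment; `p_anti_pd1` conditional
#'   share of anti-PD-1 monotherapy among treated.
#' @param p_pretreat_braf probability of BRAF/MEKi pretreatment given a
#'   BRAF driver variant.
#' @param p_pd_pos,p_pd_neg P(PD) given resistance-rule status (the
#'   union+pretreatment rule); non-PD responses split SD:PR as `p_sd_dc`.
#' @param target_size_mb,genome_size_mb panel geometry.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 82L,
                              seed,
                              subtype_props = c(cutaneous = 42, acral = 14,
                                                mucosal = 9, uveal = 8,
                                                occult = 9) / 82,
                              gene_probs = default_gene_probs(),
                              tmb_median = c(cutaneous = 9.4, acral = 1.5,
                                             mucosal = 3.2, uveal = 2.8,
                                             occult = 7.5),
                              tmb_sdlog = 0.65,
                              cnv_median = c(cutaneous = 8, acral = 12.5,
                                             mucosal = 33, uveal = 8,
                                             occult = 16),
                              cnv_size = 2.5,
                              p_ici = 75 / 82,
                              p_anti_pd1 = 15 / 75,
                              p_pretreat_braf = 18 / 23,
                              p_pd_pos = 28 / 34,
                              p_pd_neg = 17 / 41,
                              p_sd_dc = 12 / 30,
                              target_size_mb = 1.3,
                              genome_size_mb = 3101.79) {
  if (missing(seed) || is.null(seed))
    stop("configuration error: a seed is mandatory", call. = FALSE)
  if (abs(sum(subtype_props) - 1) > 1e-8)
    stop("configuration error: subtype_props must sum to 1", call. = FALSE)
  probs <- c(gene_probs, p_ici, p_anti_pd1, p_pretreat_braf, p_pd_pos,
             p_pd_neg, p_sd_dc)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 subtype_props = subtype_props, gene_probs = gene_probs,
                 tmb_median = tmb_median, tmb_sdlog = tmb_sdlog,
                 cnv_median = cnv_median, cnv_size = cnv_size,
                 p_ici = p_ici, p_anti_pd1 = p_anti_pd1,
                 p_pretreat_braf = p_pretreat_braf,
                 p_pd_pos = p_pd_pos, p_pd_neg = p_pd_neg,
                 p_sd_dc = p_sd_dc,
                 target_size_mb = target_size_mb,
                 genome_size_mb = genome_size_mb),
            class = "simulation_config")
}

#' Default subtype-conditional driver alteration probabilities
#'
#' Frequencies mirror the reference cohort: BRAF/NRAS dominate cutaneous
#' and occult melanoma, acral melanoma carries KIT/PDGFRA/CDK4/RICTOR
#' amplifications, mucosal melanoma CCND2/CHEK2 copy number changes, and
#' uveal melanoma GNAQ/GNA11 (mutually exclusive) with universal MYC
#' amplification.
#'
#' @return genes-by-subtype numeric matrix.
#' @export
default_gene_probs <- function() {
  g <- rbind(
    #            cutaneous acral mucosal uveal occult
    BRAF   = c(0.40, 0.14, 0.00, 0.00, 0.44),
    NRAS   = c(0.38, 0.07, 0.11, 0.00, 0.22),
    NF1    = c(0.12, 0.00, 0.00, 0.00, 0.00),
    KRAS   = c(0.00, 0.07, 0.11, 0.00, 0.00),
    HRAS   = c(0.02, 0.00, 0.00, 0.00, 0.00),
    EGFR   = c(0.10, 0.04, 0.05, 0.04, 0.05),
    PTEN   = c(0.17, 0.21, 0.11, 0.12, 0.11),
    TP53   = c(0.10, 0.07, 0.11, 0.00, 0.05),
    CDKN2A = c(0.24, 0.29, 0.22, 0.12, 0.22),
    MYC    = c(0.14, 0.14, 0.22, 1.00, 0.22),
    GNAQ   = c(0.00, 0.00, 0.00, 0.45, 0.00),
    GNA11  = c(0.00, 0.00, 0.00, 0.45, 0.00),
    KIT    = c(0.02, 0.29, 0.11, 0.00, 0.00),
    PDGFRA = c(0.02, 0.29, 0.00, 0.00, 0.00),
    CDK4   = c(0.02, 0.14, 0.11, 0.00, 0.00),
    RICTOR = c(0.05, 0.21, 0.11, 0.00, 0.11),
    CCND2  = c(0.02, 0.07, 0.55, 0.00, 0.00),
    CHEK2  = c(0.00, 0.00, 0.33, 0.00, 0.00))
  colnames(g) <- c("cutaneous", "acral", "mucosal", "uveal", "occult")
  g
}

# genes realised as driver SNVs (with a canonical protein change) vs
# driver CNVs (with a direction)
SIM_SNV_GENES <- c(BRAF = "V600E", NRAS = "Q61K", NF1 = "Q1174fs",
                   KRAS = "G12D", HRAS = "Q61R", TP53 = "R175H",
                   GNAQ = "Q209P", GNA11 = "Q209L")
SIM_CNV_DIR <- c(EGFR = "amplification", PTEN = "deletion",
                 CDKN2A = "deletion", MYC = "amplification",
                 KIT = "amplification", PDGFRA = "amplification",
                 CDK4 = "amplification", RICTOR = "amplification",
                 CCND2 = "amplification", CHEK2 = "deletion")

# mu of a negative binomial with given size whose median is closest to m
nbinom_mu_for_median <- function(m, size) {
  mus <- seq(0.2, 4 * m + 5, by = 0.05)
  med <- stats::qnbinom(0.5, size = size, mu = mus)
  mus[which.min(abs(med - m))]
}

#' Simulate a melanoma cohort
#'
#' Draws per-patient subtypes, driver alterations, burden and treatment
#' response from a [simulation_config()]. Driver SNV genes contribute to
#' the somatic variant count; passenger variants in the remaining panel
#' genes are added so that the computed adjusted TMB matches the drawn
#' per-patient TMB. RECIST response is drawn conditionally on the
#' union+pretreatment resistance-rule status, so the configured
#' P(PD | rule) is recovered in expectation.
#'
#' @param config a [simulation_config()].
#' @return a [melanoma_cohort()].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  panel <- fixture_panel()
  fillers <- fixture_filler_genes()

  subtype <- sample(names(config$subtype_props), n, replace = TRUE,
                    prob = config$subtype_props)
  ids <- sprintf("S%05d", seq_len(n))

  gp <- config$gene_probs
  genes <- rownames(gp)
  # alteration indicator matrix, mutually exclusive GNAQ/GNA11
  alt <- matrix(FALSE, n, length(genes), dimnames = list(ids, genes))
  excl <- c("GNAQ", "GNA11") %in% genes
  for (g in genes) {
    if (all(excl) && g %in% c("GNAQ", "GNA11")) next
    alt[, g] <- stats::runif(n) < gp[g, subtype]
  }
  if (all(excl)) {
    u <- stats::runif(n)
    p1 <- gp["GNAQ", subtype]; p2 <- gp["GNA11", subtype]
    alt[, "GNAQ"] <- u < p1
    alt[, "GNA11"] <- u >= p1 & u < p1 + p2
  }

  col_or_false <- function(g) if (g %in% genes) alt[, g] else rep(FALSE, n)
  braf_mut <- col_or_false("BRAF")
  pretreated <- braf_mut & stats::runif(n) < config$p_pretreat_braf
  ici <- stats::runif(n) < config$p_ici
  regimen <- ifelse(!ici, "none",
                    ifelse(stats::runif(n) < config$p_anti_pd1,
                           "anti_pd1", "combined"))

  # rule status under the union+pretreatment predictor
  rule_pos <- col_or_false("EGFR") | col_or_false("PTEN") |
    col_or_false("TP53") | pretreated
  p_pd <- ifelse(rule_pos, config$p_pd_pos, config$p_pd_neg)
  is_pd <- stats::runif(n) < p_pd
  is_sd <- stats::runif(n) < config$p_sd_dc
  response <- ifelse(!ici, "not_applicable",
                     ifelse(is_pd, "PD", ifelse(is_sd, "SD", "PR")))

  clinical <- data.frame(sample_id = ids, subtype = subtype,
                         ici_regimen = regimen, recist_response = response,
                         braf_meki_pretreated = pretreated,
                         stringsAsFactors = FALSE)

  # --- driver alteration tables ----------------------------------------
  snv_genes <- intersect(names(SIM_SNV_GENES), genes)
  cnv_genes <- intersect(names(SIM_CNV_DIR), genes)
  w <- which(alt[, snv_genes, drop = FALSE], arr.ind = TRUE)
  drv_variants <- if (nrow(w)) data.frame(
    sample_id = ids[w[, 1]], gene = snv_genes[w[, 2]],
    variant_class = ifelse(snv_genes[w[, 2]] == "NF1", "frameshift",
                           "missense"),
    protein_change = unname(SIM_SNV_GENES[snv_genes[w[, 2]]]),
    is_driver = TRUE,
    is_hotspot = !(snv_genes[w[, 2]] %in% c("NF1", "TP53")),
    stringsAsFactors = FALSE) else empty_variant_table()
  wc <- which(alt[, cnv_genes, drop = FALSE], arr.ind = TRUE)
  drv_cnvs <- if (nrow(wc)) data.frame(
    sample_id = ids[wc[, 1]], gene = cnv_genes[wc[, 2]],
    direction = unname(SIM_CNV_DIR[cnv_genes[wc[, 2]]]),
    is_driver = TRUE, stringsAsFactors = FALSE) else empty_cnv_table()

  # --- burden: TMB-matched passenger variants --------------------------
  tmb_target <- stats::rlnorm(n,
                              meanlog = log(config$tmb_median[subtype]),
                              sdlog = config$tmb_sdlog)
  k_tumor <- vapply(seq_len(n), function(i)
    sum(alt[i, snv_genes]), numeric(1))
  n_pass <- pmax(0, round((tmb_target - k_tumor / config$genome_size_mb) *
                            config$target_size_mb))
  total_pass <- sum(n_pass)
  if (total_pass > 0) {
    pv_sample <- rep(ids, times = n_pass)
    pv_gene <- sample(fillers, total_pass, replace = TRUE)
    pv_syn <- stats::runif(total_pass) < 0.25
    pass_variants <- data.frame(
      sample_id = pv_sample, gene = pv_gene,
      variant_class = ifelse(pv_syn, "synonymous", "missense"),
      protein_change = ifelse(pv_syn, "L100L", "A100V"),
      is_driver = FALSE, is_hotspot = FALSE, stringsAsFactors = FALSE)
  } else {
    pass_variants <- empty_variant_table()
  }

  # --- CNV counts: negative binomial, median-matched -------------------
  mu_by_subtype <- vapply(config$cnv_median, nbinom_mu_for_median,
                          numeric(1), size = config$cnv_size)
  n_cnv_total <- stats::rnbinom(n, size = config$cnv_size,
                                mu = mu_by_subtype[subtype])
  n_drv_cnv <- vapply(seq_len(n), function(i)
    sum(alt[i, cnv_genes]), numeric(1))
  n_pass_cnv <- pmin(pmax(0, n_cnv_total - n_drv_cnv), length(fillers))
  total_pc <- sum(n_pass_cnv)
  if (total_pc > 0) {
    pc_sample <- rep(seq_len(n), times = n_pass_cnv)
    pc_gene <- unlist(lapply(seq_len(n), function(i) {
      if (n_pass_cnv[i] == 0) return(character())
      sample(fillers, n_pass_cnv[i])
    }))
    pass_cnvs <- data.frame(
      sample_id = ids[pc_sample], gene = pc_gene,
      direction = sample(CNV_DIRECTIONS, total_pc, replace = TRUE),
      is_driver = FALSE, stringsAsFactors = FALSE)
  } else {
    pass_cnvs <- empty_cnv_table()
  }

  variants <- rbind(drv_variants, pass_variants)
  cnvs <- rbind(drv_cnvs, pass_cnvs)
  variants <- variants[order(variants$sample_id, variants$gene,
                             variants$protein_change), ]
  cnvs <- cnvs[order(cnvs$sample_id, cnvs$gene), ]
  rownames(variants) <- rownames(cnvs) <- NULL

  melanoma_cohort(clinical, variants, cnvs,
                  panel_definition(panel$genes, config$target_size_mb,
                                   panel$tumor_genes,
                                   config$genome_size_mb))
}
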