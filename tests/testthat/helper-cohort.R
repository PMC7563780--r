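# Small in-code fixtures and independent oracles shared across tests.

tiny_panel <- function(genes = c("BRAF", "NRAS", "NF1", "TP53", "PTEN",
                                 "EGFR", "CDKN2A", "FILLER1", "FILLER2"),
                       target_size_mb = 1.3,
                       tumor_genes = c("BRAF", "NRAS", "NF1", "TP53",
                                       "PTEN", "EGFR", "CDKN2A"),
                       genome_size_mb = 3101.79) {
  panel_definition(genes, target_size_mb, tumor_genes, genome_size_mb)
}

clin_row <- function(id, subtype = "cutaneous", regimen = "combined",
                     response = "PD", pretreated = FALSE) {
  data.frame(sample_id = id, subtype = subtype, ici_regimen = regimen,
             recist_response = response, braf_meki_pretreated = pretreated,
             stringsAsFactors = FALSE)
}

var_row <- function(id, gene, class = "missense", change = "X1Y",
                    driver = TRUE, hotspot = FALSE) {
  data.frame(sample_id = id, gene = gene, variant_class = class,
             protein_change = change, is_driver = driver,
             is_hotspot = hotspot, stringsAsFactors = FALSE)
}

cnv_row <- function(id, gene, direction = "deletion", driver = TRUE) {
  data.frame(sample_id = id, gene = gene, direction = direction,
             is_driver = driver, stringsAsFactors = FALSE)
}

empty_variants <- function() var_row("x", "BRAF")[0, ]
empty_cnvs <- function() cnv_row("x", "BRAF")[0, ]

tiny_cohort <- function(clinical, variants = empty_variants(),
                        cnvs = empty_cnvs(), panel = tiny_panel()) {
  melanoma_cohort(clinical, variants, cnvs, panel)
}

# draw one element of a vector without the sample() scalar pitfall
pick1 <- function(x) x[sample.int(length(x), 1)]

# random 2x2 table with total size n <= 30 (all margins valid)
random_table <- function(max_n = 30) {
  n <- pick1(4:max_n)
  n1 <- pick1(1:(n - 1))
  k <- pick1(0:n)
  a <- pick1(max(0, k - (n - n1)):min(n1, k))
  c(a = a, b = n1 - a, c = k - a, d = (n - n1) - (k - a))
}

# Brute-force Fisher oracle: enumerate all 2x2 tables with the observed
# margins, probabilities from the hypergeometric mass function.
oracle_fisher <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(n1, k)
  probs <- stats::dhyper(support, n1, n2, k)
  p_obs <- stats::dhyper(a, n1, n2, k)
  list(greater = sum(probs[support >= a]),
       less = sum(probs[support <= a]),
       two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force Mann-Whitney oracle: enumerate every assignment of the
# pooled values to the first group; two-sided p = 2 * min tail of the
# rank-sum permutation distribution.
oracle_mw_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
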