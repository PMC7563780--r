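# Subtype-vs-rest enrichment of gene alterations, and Mann-Whitney burden
# comparisons between histopathological subtypes.
#
# Enrichment is the classic 2x2 exact problem: for each (gene, subtype)
# pair, cross-tabulate altered/unaltered against in-group/rest and test
# with the hypergeometric (Fisher) distribution. The one-sided enrichment
# tail is what oncoplot-style reports flag; the two-sided p and a
# Benjamini-Hochberg column are emitted alongside but the significance
# flag follows the raw one-sided p, matching how such cohort reports are
# conventionally read at alpha = 0.05.

#' Gene-by-subtype alteration enrichment (exact tests)
#'
#' For every panel gene and every histopathological subtype present,
#' builds the table (a = altered in group, b = unaltered in group,
#' c = altered in rest, d = unaltered in rest) and computes Fisher's exact
#' p, one-sided (enrichment tail) and two-sided. An alteration is any
#' qualifying driver SNV/INDEL or driver CNV (see [alteration_matrix()]).
#'
#' @param cohort a [melanoma_cohort()].
#' @param drivers_only restrict to driver alterations.
#' @param alpha significance threshold applied to the one-sided p
#'   (unadjusted); a BH-adjusted column `q_bh` is reported for reference.
#' @return data.frame ordered by (group, p_one_sided, gene) with columns
#'   `gene`, `group`, `a`, `b`, `c`, `d`, `direction`, `p_one_sided`,
#'   `p_two_sided`, `q_bh`, `significant`.
#' @export
gene_enrichment <- function(cohort, drivers_only = TRUE, alpha = 0.05) {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  subtypes <- unique(cohort$clinical$subtype)
  if (length(subtypes) < 2L)
    stop("enrichment requires at least two subtypes in the cohort",
         call. = FALSE)
  m <- alteration_matrix(cohort, include_cnv = TRUE,
                         drivers_only = drivers_only)
  subtype_of <- cohort$clinical$subtype[match(rownames(m),
                                              cohort$clinical$sample_id)]
  grid <- expand.grid(gene = colnames(m),
                      group = sort(subtypes),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gene <- grid$gene[i]; group <- grid$group[i]
    in_grp <- subtype_of == group
    alt <- m[, gene]
    a <- sum(alt & in_grp); b <- sum(!alt & in_grp)
    cc <- sum(alt & !in_grp); d <- sum(!alt & !in_grp)
    p1 <- fisher_p(a, b, cc, d, alternative = "greater")
    p2 <- fisher_p(a, b, cc, d, alternative = "two.sided")
    dir <- if (a / (a + b) >= cc / (cc + d)) "enriched" else "depleted"
    data.frame(gene = gene, group = group, a = a, b = b, c = cc, d = d,
               direction = dir, p_one_sided = p1, p_two_sided = p2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_one_sided, method = "BH")
  out$significant <- out$p_one_sided < alpha
  out <- out[order(out$group, out$p_one_sided, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fisher's exact p for a 2x2 table given as cell counts
# (a = success in group 1, b = failure in group 1, c, d likewise group 2).
fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                     alternative = alternative)$p.value
}

#' Compare a burden metric between each subtype and a reference subtype
#'
#' Two-sided Mann-Whitney U tests of `metric` for every non-reference
#' subtype against the reference (cutaneous by default, the convention for
#' melanoma cohort tables). For small groups (both sizes <= 12) the p-value
#' comes from exact enumeration of the permutation distribution of the
#' rank sum, which remains exact under ties; larger comparisons use the
#' normal approximation with tie correction.
#'
#' @param cohort a [melanoma_cohort()].
#' @param metric one of `"tmb"`, `"n_snv"`, `"n_cnv"`.
#' @param reference_subtype subtype every other subtype is compared to.
#' @return data.frame with columns `subtype`, `n`, `n_ref`, `U`,
#'   `p_value`, `method`.
#' @export
compare_burden <- function(cohort, metric = c("tmb", "n_snv", "n_cnv"),
                           reference_subtype = "cutaneous") {
  metric <- match.arg(metric)
  stopifnot(inherits(cohort, "melanoma_cohort"))
  burden <- cohort_tmb(cohort)
  x_all <- burden[[metric]]
  subtype <- cohort$clinical$subtype
  ref <- x_all[subtype == reference_subtype]
  if (length(ref) == 0L)
    stop("reference subtype '", reference_subtype, "' has no patients",
         call. = FALSE)
  others <- setdiff(unique(subtype), reference_subtype)
  rows <- lapply(sort(others), function(g) {
    y <- x_all[subtype == g]
    if (length(y) == 0L) {
      warning("no patients in subtype '", g, "'; comparison skipped",
              call. = FALSE)
      return(NULL)
    }
    mw <- mann_whitney(y, ref)
    data.frame(subtype = g, n = length(y), n_ref = length(ref),
               U = mw$U, p_value = mw$p_value, method = mw$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation p (tie-aware) when both groups have at most
#' `exact_max` observations, normal approximation with tie correction
#' otherwise. The exact two-sided p is `min(1, 2 * min(P(W <= w),
#' P(W >= w)))` over the permutation distribution of the rank sum `w`
#' of the first group.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for the exact branch.
#' @return list with `U` (of the first sample), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- mw_exact_p(r, n1)
    method <- "exact"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    method <- "normal_approx"
  }
  list(U = U, p_value = p, method = method)
}

# Exact permutation distribution of the group-1 rank sum via dynamic
# programming over items, counting subsets of size n1 by (size, rank sum).
# Midranks are doubled so tied ranks stay integral.
mw_exact_p <- function(r, n1) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  w_obs <- sum(r2[seq_len(n1)])
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # ways[k + 1, s + 1] = number of k-subsets of processed items with sum s
  ways <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  ways[1, 1] <- 1
  for (ri in r2) {
    for (k in n1:1) {
      src <- seq_len(smax + 1 - ri)
      ways[k + 1, src + ri] <- ways[k + 1, src + ri] + ways[k, src]
    }
  }
  counts <- ways[n1 + 1, ]
  total <- choose(n, n1)
  p_le <- sum(counts[seq_len(w_obs + 1)]) / total
  p_ge <- sum(counts[seq(w_obs + 1, smax + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}
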