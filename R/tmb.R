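# Adjusted tumor mutational burden for targeted panels.
#
# Targeted cancer panels are designed around known tumor suppressors and
# oncogenes, so variants in those genes occur far more often per panel
# megabase than they would genome-wide. Extrapolating them at the panel
# rate overrates the TMB. The adjustment splits the somatic count: variants
# outside the known-tumor-gene set are normalised by the panel target size
# (the usual panel-TMB estimate), while variants inside it are normalised by
# genome size, i.e. counted at the rate they would contribute to a
# whole-genome TMB.

#' Adjusted TMB for one sample
#'
#' `tmb = (n_somatic - n_tumorgene) / target_size_mb +
#'        n_tumorgene / genome_size_mb`
#'
#' where `n_somatic` counts all coding SNVs/INDELs of the sample (synonymous
#' included; CNVs never count) and `n_tumorgene` the subset falling in the
#' panel's known tumor genes. Both addends are returned so an alternative
#' normalisation can be audited or swapped in one place.
#'
#' @param variants variant table rows belonging to one sample (any columns
#'   beyond `gene` are ignored).
#' @param panel a [panel_definition()].
#' @param sample_id optional id carried through to the result.
#' @return list of class `tmb_result` with `sample_id`, `n_somatic`,
#'   `n_tumorgene`, `tmb`, `panel_term`, `genome_term` (mutations/Mb).
#' @export
compute_tmb <- function(variants, panel, sample_id = NA_character_) {
  stopifnot(inherits(panel, "panel_definition"))
  if (panel$target_size_mb <= 0)
    stop("configuration error: target_size_mb must be positive",
         call. = FALSE)
  n_somatic <- nrow(variants)
  n_tumorgene <- if (n_somatic)
    sum(variants$gene %in% panel$tumor_genes) else 0L
  panel_term <- (n_somatic - n_tumorgene) / panel$target_size_mb
  genome_term <- n_tumorgene / panel$genome_size_mb
  structure(list(sample_id = sample_id,
                 n_somatic = as.integer(n_somatic),
                 n_tumorgene = as.integer(n_tumorgene),
                 panel_term = panel_term, genome_term = genome_term,
                 tmb = panel_term + genome_term),
            class = "tmb_result")
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB %s: %.2f mut/Mb (%d somatic, %d in tumor genes)\n",
              x$sample_id, x$tmb, x$n_somatic, x$n_tumorgene))
  invisible(x)
}

#' Per-sample burden table for a whole cohort
#'
#' @param cohort a [melanoma_cohort()].
#' @return data.frame with one row per clinical patient: `sample_id`,
#'   `n_somatic`, `n_tumorgene`, `tmb` (mut/Mb), `n_snv` (alias of
#'   `n_somatic`), `n_cnv`.
#' @export
cohort_tmb <- function(cohort) {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  samples <- cohort$clinical$sample_id
  v_split <- split(cohort$variants, factor(cohort$variants$sample_id,
                                           levels = samples))
  res <- lapply(samples, function(s)
    compute_tmb(v_split[[s]], cohort$panel, sample_id = s))
  cnv_n <- table(factor(cohort$cnvs$sample_id, levels = samples))
  data.frame(sample_id = samples,
             n_somatic = vapply(res, `[[`, integer(1), "n_somatic"),
             n_tumorgene = vapply(res, `[[`, integer(1), "n_tumorgene"),
             tmb = vapply(res, `[[`, numeric(1), "tmb"),
             n_snv = vapply(res, `[[`, integer(1), "n_somatic"),
             n_cnv = as.integer(cnv_n),
             stringsAsFactors = FALSE)
}

#' Per-subtype burden summary
#'
#' Median, interquartile range and range of a burden metric by
#' histopathological subtype; the cohort-level descriptive statistics of a
#' clinical genetics report. Single-patient groups report their value as
#' both IQR endpoints.
#'
#' @param cohort a [melanoma_cohort()].
#' @param metric one of `"tmb"`, `"n_snv"`, `"n_cnv"`.
#' @return data.frame with columns `subtype`, `n`, `median`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
summarize_burden <- function(cohort, metric = c("tmb", "n_snv", "n_cnv")) {
  metric <- match.arg(metric)
  if (nrow(cohort$clinical) == 0L)
    stop("empty cohort", call. = FALSE)
  burden <- cohort_tmb(cohort)
  x <- burden[[metric]]
  groups <- split(x, cohort$clinical$subtype)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(subtype = g, n = length(v), median = q[2], q1 = q[1],
               q3 = q[3], min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  out[order(match(out$subtype, SUBTYPES)), , drop = FALSE]
}
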