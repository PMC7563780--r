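# Genomic subtype classification: BRAF / RAS / NF1 / triple wild-type.
#
# The TCGA-style genomic taxonomy of melanoma assigns each tumor to the
# highest-precedence class for which it carries a driver small variant:
# BRAF before RAS (NRAS/HRAS/KRAS) before NF1; a tumor with none of the
# three is triple wild-type (TWT). Precedence resolves the rare co-mutated
# tumors (e.g. simultaneous BRAF V600E and NRAS Q61 hotspots)
# deterministically. Only driver SNVs/INDELs count; amplifications of
# RAS-pathway genes do not change the class.

RAS_GENES <- c("NRAS", "HRAS", "KRAS")
CLASS_LABELS <- c("BRAF", "RAS", "NF1", "TWT")

#' Classify one patient's genomic subtype
#'
#' @param driver_variants variant-table rows for one patient; rows with
#'   `is_driver = FALSE` are ignored, CNVs are never passed here.
#' @param sample_id optional id carried through.
#' @return list of class `genomic_class` with `sample_id`, `label` (one of
#'   BRAF/RAS/NF1/TWT) and `evidence` (data.frame of qualifying gene /
#'   protein_change rows; empty iff label is TWT).
#' @export
classify_genomic_subtype <- function(driver_variants,
                                     sample_id = NA_character_) {
  v <- driver_variants
  if (is.null(v) || nrow(v) == 0L) {
    v <- empty_variant_table()
  } else {
    v <- v[v$is_driver, , drop = FALSE]
  }
  label <- if (any(v$gene == "BRAF")) "BRAF"
    else if (any(v$gene %in% RAS_GENES)) "RAS"
    else if (any(v$gene == "NF1")) "NF1"
    else "TWT"
  ev_genes <- switch(label, BRAF = "BRAF", RAS = RAS_GENES, NF1 = "NF1",
                     TWT = character())
  ev <- v[v$gene %in% ev_genes, c("gene", "protein_change"), drop = FALSE]
  rownames(ev) <- NULL
  structure(list(sample_id = sample_id, label = label, evidence = ev),
            class = "genomic_class")
}

#' @export
print.genomic_class <- function(x, ...) {
  ev <- if (nrow(x$evidence))
    paste(sprintf("%s:%s", x$evidence$gene, x$evidence$protein_change),
          collapse = "; ") else "none"
  cat(sprintf("%s -> %s (evidence: %s)\n", x$sample_id, x$label, ev))
  invisible(x)
}

#' Classify every patient in a cohort
#'
#' @param cohort a [melanoma_cohort()].
#' @return data.frame with one row per patient: `sample_id`, `label`,
#'   `evidence` (semicolon-joined `gene:protein_change`, empty for TWT).
#' @export
classify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  samples <- cohort$clinical$sample_id
  v <- cohort$variants[cohort$variants$is_driver, , drop = FALSE]
  v_split <- split(v, factor(v$sample_id, levels = samples))
  rows <- lapply(samples, function(s) {
    cls <- classify_genomic_subtype(v_split[[s]], sample_id = s)
    ev <- if (nrow(cls$evidence))
      paste(sprintf("%s:%s", cls$evidence$gene, cls$evidence$protein_change),
            collapse = ";") else ""
    data.frame(sample_id = s, label = cls$label, evidence = ev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genomic class counts for a cohort
#'
#' @param cohort a [melanoma_cohort()].
#' @return named integer vector over BRAF, RAS, NF1, TWT; sums to the
#'   number of patients.
#' @export
class_counts <- function(cohort) {
  cls <- classify_cohort(cohort)
  tab <- table(factor(cls$label, levels = CLASS_LABELS))
  out <- as.integer(tab)
  names(out) <- CLASS_LABELS
  out
}
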