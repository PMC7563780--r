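# Cohort data model and tab-delimited I/O.
#
# A cohort bundles four tables: per-patient clinical annotation, somatic
# small variants (SNVs/INDELs), gene-level copy number events, and the
# sequencing panel definition. All downstream analyses operate on this
# container; genomic coordinates are deliberately out of scope -- every
# analysis works on gene symbols and alteration classes.

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                     "splice", "synonymous")
CNV_DIRECTIONS  <- c("amplification", "deletion")
SUBTYPES        <- c("cutaneous", "acral", "mucosal", "uveal", "occult")
ICI_REGIMENS    <- c("combined", "anti_pd1", "none")
RECIST_LEVELS   <- c("PD", "SD", "PR", "not_applicable")

#' Define a sequencing panel
#'
#' A panel is the gene universe over which variants and copy number events
#' are reported, together with its target size and the subset of genes that
#' are known tumor suppressors or oncogenes ("known tumor genes"). Targeted
#' cancer panels over-sample these genes by design, which is why the
#' adjusted TMB (see [compute_tmb()]) normalises their variants by genome
#' size rather than panel size.
#'
#' @param genes character vector of HGNC-style gene symbols.
#' @param target_size_mb panel target territory in megabases (> 0).
#' @param tumor_genes subset of `genes` treated as known tumor genes.
#' @param genome_size_mb genome size in megabases; defaults to the GRCh37
#'   total of 3101.79 Mb.
#' @return An object of class `panel_definition`.
#' @export
panel_definition <- function(genes, target_size_mb, tumor_genes,
                             genome_size_mb = 3101.79) {
  genes <- unique(as.character(genes))
  tumor_genes <- unique(as.character(tumor_genes))
  if (length(genes) == 0L || any(!nzchar(genes)))
    stop("panel genes must be non-empty symbols", call. = FALSE)
  if (!is.numeric(target_size_mb) || length(target_size_mb) != 1L ||
      is.na(target_size_mb) || target_size_mb <= 0)
    stop("configuration error: target_size_mb must be a positive number",
         call. = FALSE)
  if (!is.numeric(genome_size_mb) || length(genome_size_mb) != 1L ||
      is.na(genome_size_mb) || genome_size_mb < target_size_mb)
    stop("configuration error: genome_size_mb must be >= target_size_mb",
         call. = FALSE)
  bad <- setdiff(tumor_genes, genes)
  if (length(bad))
    stop("tumor_genes not in panel gene set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(genes = genes, target_size_mb = target_size_mb,
                 tumor_genes = tumor_genes, genome_size_mb = genome_size_mb),
            class = "panel_definition")
}

#' Assemble a melanoma cohort from its component tables
#'
#' Validates the referential and value constraints that every analysis in
#' the package relies on: unique clinical sample ids, every alteration
#' attached to a known sample and a panel gene, enum-valued categorical
#' columns, and the clinical rule that a RECIST response is recorded if and
#' only if the patient received immune checkpoint inhibition.
#'
#' @param clinical data.frame with columns `sample_id`, `subtype`,
#'   `ici_regimen`, `recist_response`, `braf_meki_pretreated`.
#' @param variants data.frame with columns `sample_id`, `gene`,
#'   `variant_class`, `protein_change`, `is_driver`, `is_hotspot`.
#' @param cnvs data.frame with columns `sample_id`, `gene`, `direction`,
#'   `is_driver`.
#' @param panel a [panel_definition()].
#' @return An object of class `melanoma_cohort`: a list with elements
#'   `clinical`, `variants`, `cnvs`, `panel`.
#' @export
melanoma_cohort <- function(clinical, variants, cnvs, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  clinical <- validate_clinical(clinical)
  variants <- validate_variants(variants, clinical, panel)
  cnvs     <- validate_cnvs(cnvs, clinical, panel)
  structure(list(clinical = clinical, variants = variants, cnvs = cnvs,
                 panel = panel),
            class = "melanoma_cohort")
}

# case-insensitive enum matcher; unknown levels are rejected, never coerced
match_enum <- function(x, levels, column) {
  idx <- match(tolower(trimws(as.character(x))), tolower(levels))
  if (anyNA(idx)) {
    bad <- unique(as.character(x)[is.na(idx)])
    stop(sprintf("invalid value(s) in column '%s': %s (allowed: %s)",
                 column, paste(bad, collapse = ", "),
                 paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  levels[idx]
}

parse_logical <- function(x, column) {
  if (is.logical(x)) return(x)
  out <- c("true" = TRUE, "false" = FALSE)[tolower(trimws(as.character(x)))]
  if (anyNA(out))
    stop(sprintf("column '%s' must be true/false", column), call. = FALSE)
  unname(out)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s table: missing column(s) %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

validate_clinical <- function(clinical) {
  require_columns(clinical, c("sample_id", "subtype", "ici_regimen",
                              "recist_response", "braf_meki_pretreated"),
                  "clinical")
  clinical$sample_id <- as.character(clinical$sample_id)
  dup <- unique(clinical$sample_id[duplicated(clinical$sample_id)])
  if (length(dup))
    stop("uniqueness error: duplicate clinical sample_id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  clinical$subtype <- match_enum(clinical$subtype, SUBTYPES, "subtype")
  clinical$ici_regimen <- match_enum(clinical$ici_regimen, ICI_REGIMENS,
                                     "ici_regimen")
  clinical$recist_response <- match_enum(clinical$recist_response,
                                         RECIST_LEVELS, "recist_response")
  clinical$braf_meki_pretreated <-
    parse_logical(clinical$braf_meki_pretreated, "braf_meki_pretreated")
  bad <- xor(clinical$ici_regimen == "none",
             clinical$recist_response == "not_applicable")
  if (any(bad))
    stop("clinical error: recist_response must be not_applicable exactly ",
         "for ici_regimen = none; offending sample(s): ",
         paste(clinical$sample_id[bad], collapse = ", "), call. = FALSE)
  rownames(clinical) <- NULL
  clinical
}

check_referential <- function(df, clinical, panel, what) {
  unknown <- !(df$sample_id %in% clinical$sample_id)
  if (any(unknown))
    stop(sprintf(
      "referential-integrity error: %s rows reference unknown sample(s): %s",
      what,
      paste(sprintf("row %d (%s)", which(unknown), df$sample_id[unknown]),
            collapse = "; ")), call. = FALSE)
  off_panel <- !(df$gene %in% panel$genes)
  if (any(off_panel))
    stop(sprintf("%s rows reference genes outside the panel: %s", what,
                 paste(unique(df$gene[off_panel]), collapse = ", ")),
         call. = FALSE)
  invisible(df)
}

validate_variants <- function(variants, clinical, panel) {
  require_columns(variants, c("sample_id", "gene", "variant_class",
                              "protein_change", "is_driver"), "variant")
  if (!"is_hotspot" %in% names(variants)) {
    warning("variant table lacks optional column 'is_hotspot'; ",
            "defaulting to false", call. = FALSE)
    variants$is_hotspot <- FALSE
  }
  variants$sample_id <- as.character(variants$sample_id)
  variants$gene <- as.character(variants$gene)
  variants$protein_change <- as.character(variants$protein_change)
  if (nrow(variants)) {
    if (any(!nzchar(variants$gene)))
      stop("variant rows with empty gene symbol", call. = FALSE)
    variants$variant_class <- match_enum(variants$variant_class,
                                         VARIANT_CLASSES, "variant_class")
    variants$is_driver <- parse_logical(variants$is_driver, "is_driver")
    variants$is_hotspot <- parse_logical(variants$is_hotspot, "is_hotspot")
    syn_driver <- variants$variant_class == "synonymous" & variants$is_driver
    if (any(syn_driver))
      stop("variant error: synonymous records cannot be drivers; rows: ",
           paste(which(syn_driver), collapse = ", "), call. = FALSE)
    check_referential(variants, clinical, panel, "variant")
  } else {
    variants <- empty_variant_table()
  }
  rownames(variants) <- NULL
  variants
}

validate_cnvs <- function(cnvs, clinical, panel) {
  require_columns(cnvs, c("sample_id", "gene", "direction", "is_driver"),
                  "cnv")
  cnvs$sample_id <- as.character(cnvs$sample_id)
  cnvs$gene <- as.character(cnvs$gene)
  if (nrow(cnvs)) {
    cnvs$direction <- match_enum(cnvs$direction, CNV_DIRECTIONS, "direction")
    cnvs$is_driver <- parse_logical(cnvs$is_driver, "is_driver")
    check_referential(cnvs, clinical, panel, "cnv")
  } else {
    cnvs <- empty_cnv_table()
  }
  rownames(cnvs) <- NULL
  cnvs
}

empty_variant_table <- function() {
  data.frame(sample_id = character(), gene = character(),
             variant_class = character(), protein_change = character(),
             is_driver = logical(), is_hotspot = logical(),
             stringsAsFactors = FALSE)
}

empty_cnv_table <- function() {
  data.frame(sample_id = character(), gene = character(),
             direction = character(), is_driver = logical(),
             stringsAsFactors = FALSE)
}

#' Read a cohort from a directory of tab-delimited tables
#'
#' Expects `clinical.tsv`, `variants.tsv`, `cnv.tsv` and `panel.tsv` (one
#' gene per row with a `tumor_gene` column). Panel target and genome sizes
#' are run configuration, not part of the panel file.
#'
#' @param clinical_path,variants_path,cnv_path,panel_path file paths; or
#'   give `dir` to use the conventional file names.
#' @param dir directory containing the four conventional files.
#' @param target_size_mb,genome_size_mb panel geometry in megabases.
#' @return A [melanoma_cohort()].
#' @export
read_cohort <- function(dir = NULL,
                        clinical_path = file.path(dir, "clinical.tsv"),
                        variants_path = file.path(dir, "variants.tsv"),
                        cnv_path = file.path(dir, "cnv.tsv"),
                        panel_path = file.path(dir, "panel.tsv"),
                        target_size_mb = 1.3,
                        genome_size_mb = 3101.79) {
  paths <- c(clinical = clinical_path, variants = variants_path,
             cnv = cnv_path, panel = panel_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("validation error: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  read_tsv0 <- function(p)
    utils::read.delim(p, sep = "\t", quote = "", stringsAsFactors = FALSE,
                      colClasses = "character")
  panel_tab <- read_tsv0(panel_path)
  require_columns(panel_tab, c("gene", "tumor_gene"), "panel")
  panel <- panel_definition(
    genes = panel_tab$gene,
    target_size_mb = target_size_mb,
    tumor_genes = panel_tab$gene[parse_logical(panel_tab$tumor_gene,
                                               "tumor_gene")],
    genome_size_mb = genome_size_mb)
  melanoma_cohort(read_tsv0(clinical_path), read_tsv0(variants_path),
                  read_tsv0(cnv_path), panel)
}

#' Write a cohort as four tab-delimited tables
#'
#' Inverse of [read_cohort()]: writes `clinical.tsv`, `variants.tsv`,
#' `cnv.tsv` and `panel.tsv` into `dir`. Output is byte-deterministic for a
#' given cohort.
#'
#' @param cohort a [melanoma_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv0 <- function(df, name) {
    for (col in names(df))
      if (is.logical(df[[col]])) df[[col]] <- ifelse(df[[col]], "true", "false")
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv0(cohort$clinical, "clinical.tsv")
  write_tsv0(cohort$variants, "variants.tsv")
  write_tsv0(cohort$cnvs, "cnv.tsv")
  write_tsv0(data.frame(gene = cohort$panel$genes,
                        tumor_gene = cohort$panel$genes %in%
                          cohort$panel$tumor_genes),
             "panel.tsv")
  invisible(dir)
}

#' Patient-by-gene alteration presence matrix
#'
#' The boolean substrate for oncoplot-style counting, enrichment tests and
#' the resistance predictor. A cell is `TRUE` if the patient carries at
#' least one qualifying alteration in the gene; a patient with both an SNV
#' and a CNV in a gene counts once. Every clinical patient contributes a
#' row, including alteration-free patients; columns span the full panel so
#' the matrix shape does not depend on which genes happen to be altered.
#'
#' @param cohort a [melanoma_cohort()].
#' @param include_cnv include gene-level copy number events.
#' @param drivers_only restrict to alterations flagged as drivers
#'   (synonymous variants can never qualify).
#' @return logical matrix, rownames = sample ids, colnames = panel genes.
#' @export
alteration_matrix <- function(cohort, include_cnv = TRUE,
                              drivers_only = TRUE) {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  samples <- cohort$clinical$sample_id
  genes <- sort(cohort$panel$genes)
  m <- matrix(FALSE, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  v <- cohort$variants
  if (drivers_only) v <- v[v$is_driver, , drop = FALSE]
  if (nrow(v)) m[cbind(v$sample_id, v$gene)] <- TRUE
  if (include_cnv) {
    cn <- cohort$cnvs
    if (drivers_only) cn <- cn[cn$is_driver, , drop = FALSE]
    if (nrow(cn)) m[cbind(cn$sample_id, cn$gene)] <- TRUE
  }
  m
}

#' @export
print.melanoma_cohort <- function(x, ...) {
  cat(sprintf("melanoma cohort: %d patients, %d small variants, %d CNVs\n",
              nrow(x$clinical), nrow(x$variants), nrow(x$cnvs)))
  cat(sprintf("panel: %d genes (%d known tumor genes), %.2f Mb target, %.2f Mb genome\n",
              length(x$panel$genes), length(x$panel$tumor_genes),
              x$panel$target_size_mb, x$panel$genome_size_mb))
  print(table(subtype = x$clinical$subtype))
  invisible(x)
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("panel: %d genes, %d known tumor genes, target %.2f Mb, genome %.2f Mb\n",
              length(x$genes), length(x$tumor_genes), x$target_size_mb,
              x$genome_size_mb))
  invisible(x)
}
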