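# End-to-end pipeline: TMB -> classification -> enrichment -> predictor,
# written as a deterministic report bundle.

#' Run the full cohort analysis and write a report bundle
#'
#' Reads a cohort directory, runs every analysis stage and writes:
#' `tmb.tsv` (per-sample burden), `classes.tsv` (genomic subtype per
#' patient), `enrichment.tsv` (gene-by-subtype exact tests),
#' `burden_tests.tsv` (Mann-Whitney comparisons vs the reference subtype),
#' `performance.json` (2x2 performance of each predictor rule) and
#' `summary.txt` (plain-text cohort summary in oncoplot order). Identical
#' inputs and configuration give byte-identical bundles.
#'
#' @param cohort_dir directory with the four cohort TSVs (see
#'   [read_cohort()]).
#' @param out_dir output directory, created if needed.
#' @param target_size_mb,genome_size_mb panel geometry (run config).
#' @param alpha significance threshold for enrichment.
#' @param rules named list of [resistance_rule()]s; defaults to
#'   [default_rules()].
#' @param quiet suppress stage log lines on stderr.
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(cohort_dir, out_dir,
                         target_size_mb = 1.3, genome_size_mb = 3101.79,
                         alpha = 0.05, rules = default_rules(),
                         quiet = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("configuration error: alpha must lie in (0, 1)", call. = FALSE)
  log_stage <- function(...) if (!quiet) message("[melcohort] ", ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log_stage("reading cohort from ", cohort_dir)
  cohort <- read_cohort(cohort_dir, target_size_mb = target_size_mb,
                        genome_size_mb = genome_size_mb)

  write_tsv0 <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("wrote ", name)
  }

  log_stage("stage tmb")
  burden <- cohort_tmb(cohort)
  write_tsv0(burden, "tmb.tsv")

  log_stage("stage classify")
  classes <- classify_cohort(cohort)
  write_tsv0(classes, "classes.tsv")

  log_stage("stage enrich")
  enr <- gene_enrichment(cohort, alpha = alpha)
  write_tsv0(enr, "enrichment.tsv")
  btests <- do.call(rbind, lapply(c("tmb", "n_snv", "n_cnv"), function(metric) {
    bt <- compare_burden(cohort, metric)
    cbind(metric = metric, bt, stringsAsFactors = FALSE)
  }))
  write_tsv0(btests, "burden_tests.tsv")

  log_stage("stage predict")
  perf <- lapply(rules, function(r) evaluate_rule(cohort, r))
  perf_json <- lapply(perf, function(p) {
    p <- unclass(p)
    p$table <- c(p$a, p$b, p$c, p$d)
    p
  })
  jsonlite::write_json(perf_json, file.path(out_dir, "performance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log_stage("wrote performance.json")

  summary_txt <- cohort_summary_text(cohort, classes, burden)
  writeLines(summary_txt, file.path(out_dir, "summary.txt"))
  log_stage("wrote summary.txt")

  invisible(list(cohort = cohort, burden = burden, classes = classes,
                 enrichment = enr, burden_tests = btests,
                 performance = perf))
}

# Plain-text analogue of an oncoplot: per-gene driver alteration
# percentages over the whole cohort (descending), then per-subtype blocks.
cohort_summary_text <- function(cohort, classes, burden) {
  m <- alteration_matrix(cohort, include_cnv = TRUE, drivers_only = TRUE)
  cl <- cohort$clinical
  n <- nrow(cl)
  freq <- sort(colMeans(m), decreasing = TRUE)
  freq <- freq[freq > 0]
  lines <- c(
    sprintf("cohort: %d patients, %d somatic small variants, %d CNVs", n,
            nrow(cohort$variants), nrow(cohort$cnvs)),
    sprintf("median TMB: %.2f mut/Mb", stats::median(burden$tmb)),
    sprintf("genomic classes: %s",
            paste(sprintf("%s=%d", names(table(classes$label)),
                          table(classes$label)), collapse = " ")),
    "",
    "driver alteration frequency (whole cohort):",
    sprintf("  %-8s %5.1f%%  (%d/%d)", names(freq), 100 * freq,
            round(freq * n), n))
  for (st in intersect(SUBTYPES, unique(cl$subtype))) {
    sel <- cl$subtype == st
    f <- sort(colMeans(m[sel, , drop = FALSE]), decreasing = TRUE)
    f <- f[f > 0]
    f <- utils::head(f, 10)
    lines <- c(lines, "",
               sprintf("subtype %s (n = %d):", st, sum(sel)),
               if (length(f))
                 sprintf("  %-8s %5.1f%%  (%d/%d)", names(f), 100 * f,
                         round(f * sum(sel)), sum(sel))
               else "  no driver alterations")
  }
  lines
}
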