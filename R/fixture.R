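# Deterministic reference cohort fixture.
#
# An 82-patient melanoma cohort whose published summary counts are known
# exactly: histopathological subtype composition, ICI treatment and RECIST
# response split, driver small-variant counts for BRAF/NRAS/HRAS/KRAS/NF1
# including the co-mutated patients, MYC amplification structure, and every
# contingency count of the four resistance-predictor variants. The
# per-patient assignment was constructed once by hand to satisfy all of
# these constraints simultaneously (the overlap arithmetic between the
# gene-union and pretreatment clauses forces most of it) and is committed
# here as code; any change to a count is a breaking change. A constraint
# checker runs on every build and fails loudly if the assignment ever
# drifts.

fixture_tumor_genes <- function() {
  c("BRAF", "NRAS", "HRAS", "KRAS", "NF1", "TP53", "PTEN", "EGFR",
    "CDKN2A", "MYC", "GNAQ", "GNA11", "SF3B1", "BAP1", "KIT", "PDGFRA",
    "CDK4", "RICTOR", "CCND2", "CHEK2", "MET", "ERBB2", "ERBB3",
    "CTNNB1", "MDM2", "JAK2")
}

fixture_filler_genes <- function() {
  c("PTPRD", "ARID2", "SMARCA4", "ATM", "FANCA", "FANCC", "BRCA2",
    "CCND1", "CCND3", "CDK6", "GRIN2A", "KDR", "LRP1B", "NOTCH1",
    "PIK3CA", "ROS1", "ALK", "RET", "FGFR1", "FGFR2")
}

#' The reference panel used by the fixture
#'
#' 46 cancer-associated genes, 26 of which are flagged as known tumor
#' genes; 1.3 Mb target, GRCh37 genome size.
#'
#' @return a [panel_definition()].
#' @export
fixture_panel <- function() {
  panel_definition(genes = c(fixture_tumor_genes(), fixture_filler_genes()),
                   target_size_mb = 1.3,
                   tumor_genes = fixture_tumor_genes(),
                   genome_size_mb = 3101.79)
}

pid <- function(i) sprintf("P%03d", i)

#' Build the deterministic reference cohort
#'
#' @param check run the internal constraint checker (default `TRUE`).
#' @return a [melanoma_cohort()] of 82 patients.
#' @export
make_paper_fixture <- function(check = TRUE) {
  ids <- pid(1:82)
  subtype <- rep(c("cutaneous", "acral", "mucosal", "uveal", "occult"),
                 times = c(42, 14, 9, 8, 9))

  pd_ids <- pid(c(1:12, 18:20, 35:39, 43:45, 47:52, 57, 59:63, 66:69,
                  74:77, 80, 81))
  sd_ids <- pid(c(13, 15, 21, 23, 24, 40, 46, 53, 55, 64, 70, 71))
  pr_ids <- pid(c(14, 16, 22, 25:30, 41, 54, 56, 58, 65, 72, 78, 79, 82))
  none_ids <- pid(c(17, 31:34, 42, 73))
  anti_pd1_ids <- pid(c(25:30, 41, 55, 56, 62, 63, 68, 69, 71, 81))
  pretreated_ids <- pid(c(1:10, 13, 14, 43, 44, 74:77))

  response <- rep("not_applicable", 82)
  response[ids %in% pd_ids] <- "PD"
  response[ids %in% sd_ids] <- "SD"
  response[ids %in% pr_ids] <- "PR"
  regimen <- ifelse(ids %in% none_ids, "none",
                    ifelse(ids %in% anti_pd1_ids, "anti_pd1", "combined"))

  clinical <- data.frame(
    sample_id = ids, subtype = subtype, ici_regimen = regimen,
    recist_response = response,
    braf_meki_pretreated = ids %in% pretreated_ids,
    stringsAsFactors = FALSE)

  # --- driver small variants -------------------------------------------
  drv <- function(i, gene, class, change, hotspot = TRUE)
    data.frame(sample_id = pid(i), gene = gene, variant_class = class,
               protein_change = change, is_driver = TRUE,
               is_hotspot = hotspot, stringsAsFactors = FALSE)

  braf_v600 <- c(1:14, 16, 43, 44, 74:77)            # 20 V600 carriers
  braf_v600_change <- rep(c("V600E", "V600K", "V600R"),
                          length.out = length(braf_v600))
  braf_v600_change[c(1, 2, 3)] <- "V600E"            # the dual/NF1 cases
  nras_q61 <- c(1, 2, 18:31, 45, 57, 78, 79)         # 20 NRAS carriers
  nras_change <- rep(c("Q61K", "Q61R", "Q61L"), length.out = length(nras_q61))

  variants <- rbind(
    drv(braf_v600, "BRAF", "missense", braf_v600_change),
    drv(15, "BRAF", "missense", "P367S", hotspot = FALSE),
    drv(15, "BRAF", "missense", "K601E", hotspot = FALSE),
    drv(17, "BRAF", "missense", "G466E", hotspot = FALSE),
    drv(nras_q61, "NRAS", "missense", nras_change),
    drv(32, "HRAS", "missense", "Q61R"),
    drv(46, "KRAS", "missense", "G12D"),
    drv(58, "KRAS", "missense", "D119H"),
    drv(c(3, 4, 18, 33, 34), "NF1", "frameshift",
        c("Q1174fs", "R2450fs", "L626fs", "K1444fs", "S895fs"),
        hotspot = FALSE),
    drv(66:69, "GNA11", "missense", "Q209L"),
    drv(70:73, "GNAQ", "missense", "Q209P"),
    drv(c(66, 67, 70, 71), "SF3B1", "missense", "R625C"),
    drv(c(68, 69, 72, 73), "BAP1", "frameshift",
        c("E31fs", "Q267fs", "L14fs", "T93fs"), hotspot = FALSE),
    drv(c(9, 10, 37, 38, 50, 59, 64), "TP53", "missense",
        c("R175H", "R248Q", "R273H", "G245S", "R282W", "Y220C", "R249S"),
        hotspot = FALSE))

  # --- driver copy number events ---------------------------------------
  cnv <- function(i, gene, direction)
    data.frame(sample_id = pid(i), gene = gene, direction = direction,
               is_driver = TRUE, stringsAsFactors = FALSE)

  cnvs <- rbind(
    cnv(c(5, 6, 35, 36, 37, 39), "EGFR", "amplification"),
    cnv(c(7, 8, 43, 35, 36, 38, 47, 48, 49, 60, 66, 21, 22, 53),
        "PTEN", "deletion"),
    cnv(c(39, 47, 48, 49, 59, 51, 52, 61, 67, 80, 40, 54, 70, 82),
        "CDKN2A", "deletion"),
    cnv(c(66:73, 11, 12, 19, 20, 23, 45, 55, 57, 62, 63, 78, 81),
        "MYC", "amplification"),
    cnv(c(47, 48, 51, 52), "KIT", "amplification"),
    cnv(c(47, 48, 51, 52), "PDGFRA", "amplification"),
    cnv(c(49, 51), "CDK4", "amplification"),
    cnv(c(50, 52, 53), "RICTOR", "amplification"),
    cnv(59:63, "CCND2", "amplification"),
    cnv(c(60, 61, 64), "CHEK2", "deletion"))

  # --- deterministic passenger load ------------------------------------
  fillers <- fixture_filler_genes()
  snv_base <- c(cutaneous = 9, acral = 2, mucosal = 3, uveal = 3, occult = 8)
  cnv_base <- c(cutaneous = 4, acral = 8, mucosal = 15, uveal = 3,
                occult = 8)
  pass_v <- list(); pass_c <- list()
  for (i in 1:82) {
    nv <- snv_base[[subtype[i]]] + (i %% 5)
    if (nv > 0) {
      g <- fillers[((i + seq_len(nv)) %% length(fillers)) + 1]
      syn <- (i + seq_len(nv)) %% 4 == 0
      pass_v[[length(pass_v) + 1]] <- data.frame(
        sample_id = pid(i), gene = g,
        variant_class = ifelse(syn, "synonymous", "missense"),
        protein_change = ifelse(syn, "L100L", "A100V"),
        is_driver = FALSE, is_hotspot = FALSE, stringsAsFactors = FALSE)
    }
    nc <- min(cnv_base[[subtype[i]]] + (i %% 4), length(fillers))
    if (nc > 0) {
      g <- fillers[((i * 3 + seq_len(nc)) %% length(fillers)) + 1]
      g <- unique(g)
      pass_c[[length(pass_c) + 1]] <- data.frame(
        sample_id = pid(i), gene = g,
        direction = ifelse(seq_along(g) %% 2 == 0, "deletion",
                           "amplification"),
        is_driver = FALSE, stringsAsFactors = FALSE)
    }
  }
  variants <- rbind(variants, do.call(rbind, pass_v))
  cnvs <- rbind(cnvs, do.call(rbind, pass_c))
  variants <- variants[order(variants$sample_id, variants$gene,
                             variants$protein_change), ]
  cnvs <- cnvs[order(cnvs$sample_id, cnvs$gene), ]

  cohort <- melanoma_cohort(clinical, variants, cnvs, fixture_panel())
  if (check) check_fixture(cohort)
  cohort
}

# Internal constraint checker: every published count the fixture pins.
check_fixture <- function(cohort) {
  fail <- function(what) stop("fixture constraint violated: ", what,
                              call. = FALSE)
  cl <- cohort$clinical
  if (nrow(cl) != 82L) fail("82 patients")
  st <- table(cl$subtype)
  if (!identical(as.integer(st[c("cutaneous", "acral", "mucosal", "uveal",
                                 "occult")]), c(42L, 14L, 9L, 8L, 9L)))
    fail("subtype counts 42/14/9/8/9")
  ici <- cl$ici_regimen != "none"
  if (sum(ici) != 75L) fail("75 ICI-treated patients")
  resp <- table(cl$recist_response[ici])
  if (resp[["PD"]] != 45L || resp[["SD"]] != 12L || resp[["PR"]] != 18L)
    fail("RECIST split 45/12/18")

  v <- cohort$variants[cohort$variants$is_driver, ]
  carriers <- function(g) unique(v$sample_id[v$gene == g])
  if (length(carriers("BRAF")) != 23L) fail("23 BRAF-driver patients")
  if (length(carriers("NRAS")) != 20L) fail("20 NRAS-driver patients")
  if (length(carriers("HRAS")) != 1L) fail("1 HRAS patient")
  if (length(carriers("KRAS")) != 2L) fail("2 KRAS patients")
  if (length(carriers("NF1")) != 5L) fail("5 NF1 patients")
  if (length(intersect(carriers("BRAF"), carriers("NRAS"))) != 2L)
    fail("2 BRAF+NRAS double-hotspot patients")
  hotspot_brn <- union(carriers("BRAF"), carriers("NRAS"))
  if (length(intersect(carriers("NF1"), hotspot_brn)) != 3L)
    fail("3 NF1 patients with a BRAF/NRAS hotspot")

  cc <- class_counts(cohort)
  if (!identical(cc, c(BRAF = 23L, RAS = 21L, NF1 = 2L, TWT = 36L)))
    fail("genomic class counts 23/21/2/36")

  m <- alteration_matrix(cohort, include_cnv = TRUE, drivers_only = TRUE)
  myc <- m[, "MYC"]
  uveal_ids <- cl$sample_id[cl$subtype == "uveal"]
  if (!all(myc[uveal_ids])) fail("MYC amplified in all 8 uveal patients")
  if (sum(myc) != 20L) fail("MYC altered in 20/82 patients")

  # predictor contingency structure over the 75 ICI-treated patients
  tab <- function(rule) {
    perf <- evaluate_rule(cohort, rule)
    c(perf$a, perf$b, perf$c, perf$d)
  }
  rules <- default_rules()
  if (!identical(tab(rules$reduced), c(19L, 4L, 26L, 26L)))
    fail("reduced-rule table (19,4,26,26)")
  if (!identical(tab(rules$pretreat_or_gene), c(28L, 6L, 17L, 24L)))
    fail("union+pretreatment table (28,6,17,24)")
  if (!identical(tab(rules$plus_cdkn2a), c(33L, 10L, 12L, 20L)))
    fail("+CDKN2A table (33,10,12,20)")
  if (!identical(tab(rules$combination), c(9L, 0L, 36L, 30L)))
    fail("two-gene combination table (9,0,36,30)")

  rf <- response_frequencies(cohort, c("EGFR", "TP53", "PTEN"))
  if (!identical(rf$pd_n, c(6L, 6L, 11L)) ||
      !identical(rf$dc_n, c(0L, 1L, 3L)))
    fail("EGFR/TP53/PTEN response frequencies 6/0, 6/1, 11/3")

  braf_pd <- intersect(carriers("BRAF"), cl$sample_id[ici &
                       cl$recist_response == "PD"])
  braf_dc <- intersect(carriers("BRAF"), cl$sample_id[ici &
                       cl$recist_response != "PD"])
  pre <- cl$sample_id[cl$braf_meki_pretreated]
  if (length(braf_pd) != 18L || length(intersect(braf_pd, pre)) != 16L)
    fail("BRAF-mutated PD patients pretreated 16/18")
  if (length(braf_dc) != 4L || length(intersect(braf_dc, pre)) != 2L)
    fail("BRAF-mutated SD+PR patients pretreated 2/4")
  invisible(cohort)
}
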