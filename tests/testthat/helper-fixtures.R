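# In-code fixtures: small allele tables and participant generators used
# across the test files. Everything is built at test time; nothing binary.

# Write an allele-definition TSV (+ JSON sidecar) and load it.
make_allele_table <- function(rows, gene = "CYP2D6", build = "GRCh37",
                              region = NULL) {
  tsv <- tempfile(fileext = ".tsv")
  meta <- sub("\\.tsv$", ".json", tsv)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = gene, allele = r$allele,
               rsid = r$rsid %||% NA, chrom = r$chrom %||% NA,
               pos = r$pos %||% NA, ref = r$ref %||% NA,
               alt = r$alt %||% NA,
               `function` = r$fun, activity_value = r$act %||% NA,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  m <- list(gene = gene, build = build)
  if (!is.null(region)) {
    m$region_start <- region[1]
    m$region_end <- region[2]
  }
  jsonlite::write_json(m, meta, auto_unbox = TRUE)
  load_allele_definitions(tsv, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Toy 4-allele table with a genuine subset relation: *B's defining set is a
# superset of *A's single variant.
toy_table <- function() {
  make_allele_table(list(
    list(allele = "*1", fun = "normal", act = 1),
    list(allele = "*A", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 0),
    list(allele = "*B", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "decreased", act = 0.5),
    list(allele = "*C", rsid = "v3", chrom = "22", pos = 300, ref = "C",
         alt = "T", fun = "decreased", act = 0.5)
  ))
}

toy_table_superset <- function() {
  make_allele_table(list(
    list(allele = "*1", fun = "normal", act = 1),
    list(allele = "*A", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 0),
    list(allele = "*B2a", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "decreased", act = 0.5),
    list(allele = "*B2b", rsid = "v2", chrom = "22", pos = 200, ref = "T",
         alt = "C", fun = "decreased", act = 0.5)
  ))
}

# Independent matching oracle: enumerate, filter full matches, order by
# (specificity desc, activity asc, name asc), default to *1.
oracle_match <- function(hap, table) {
  hap[is.na(hap)] <- 0
  cand <- table$alleles[table$alleles$name != "*1", , drop = FALSE]
  full <- vapply(cand$name, function(a) {
    def <- table$defining[[a]]
    all(hap[def] == 1)
  }, logical(1))
  if (!any(full)) return("*1")
  hits <- cand[full, , drop = FALSE]
  act <- ifelse(is.na(hits$activity_value),
                c(none = 0, decreased = 0.5, normal = 1,
                  increased = 2)[hits$function_class],
                hits$activity_value)
  hits$name[order(-hits$n_variants, act, hits$name)][1]
}

# Cohort data generator for association-model tests: balanced covariates,
# phenotype and diabetes assigned independently.
make_cohort_data <- function(n, p_im = 0.25, p_pm = 0.05, p_diab = 0.1,
                             beta = c(), residual_sd = 4) {
  df <- data.frame(
    cyp2d6_phenotype = sample(c("NM", "IM", "PM"), n, replace = TRUE,
                              prob = c(1 - p_im - p_pm, p_im, p_pm)),
    diabetes = stats::runif(n) < p_diab,
    takes_antidiabetic = FALSE,
    takes_cyp2d6_inhibitor = stats::runif(n) < 0.06,
    bmi = stats::rnorm(n, 28.8, 5.66),
    age = stats::runif(n, 40, 70),
    sex = sample(c("Female", "Male"), n, replace = TRUE),
    ancestry = sample(c("European", "African"), n, replace = TRUE,
                      prob = c(0.95, 0.05)),
    stringsAsFactors = FALSE)
  df$takes_antidiabetic <- df$diabetes & stats::runif(n) < 0.7
  X <- hba1c_design(df, genes = "CYP2D6", interaction = TRUE)
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  b["(Intercept)"] <- 37
  b[names(beta)[names(beta) %in% names(b)]] <-
    beta[names(beta) %in% names(b)]
  df$hba1c <- as.vector(X %*% b) + stats::rnorm(n, 0, residual_sd)
  df
}
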