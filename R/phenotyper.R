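#' Call star-allele diplotypes from phased haplotypes
#'
#' Matches each sample's two phased haplotypes against a star-allele
#' definition table and returns one diplotype per sample. The diplotype is
#' unordered; calls are stored with the lower-ranked allele first (table
#' order), so `*1/*4` and `*4/*1` are the same record. For CYP2D6 the
#' Gaedigk activity score (sum of the two alleles' activity values) is
#' attached. Increased-function CYP2D6 alleles are refused: without
#' copy-number data ultra-rapid CYP2D6 status cannot be assigned, and
#' silently binning such alleles would misclassify them.
#'
#' @param hapA,hapB Matrices (samples x sites) of phased alternate-allele
#'   indicators (0/1/NA), column names = variant site ids, equal dimensions.
#'   `NA` is treated as reference by the matcher.
#' @param table A `cyp_allele_table`.
#' @param sample_ids Character vector of sample ids (default: rownames of
#'   `hapA`, else `S1..Sn`).
#' @return data.frame of class `cyp_diplotypes`: `sample_id`, `gene`,
#'   `allele_a`, `allele_b`, `diplotype` ("a/b"), `activity` (CYP2D6 only,
#'   else NA), `default_wildtype_a/b` flags.
#' @export
call_diplotypes <- function(hapA, hapB, table, sample_ids = NULL) {
  if (!identical(dim(hapA), dim(hapB))) {
    stop("hapA and hapB must have identical dimensions")
  }
  n <- nrow(hapA)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(hapA)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (table$gene == "CYP2D6" &&
      any(table$alleles$function_class == "increased")) {
    stop("increased-function CYP2D6 alleles are not supported without ",
         "copy-number data (ultra-rapid metabolizers cannot be assigned)")
  }
  ca <- match_haplotypes(hapA, table)
  cb <- match_haplotypes(hapB, table)

  ord <- seq_len(nrow(table$alleles))
  names(ord) <- table$alleles$name
  swap <- ord[ca$allele] > ord[cb$allele]
  a1 <- ifelse(swap, cb$allele, ca$allele)
  a2 <- ifelse(swap, ca$allele, cb$allele)

  act <- rep(NA_real_, n)
  if (table$gene == "CYP2D6") {
    vals <- table$alleles$activity_value
    names(vals) <- table$alleles$name
    act <- vals[a1] + vals[a2]
  }
  out <- data.frame(
    sample_id = sample_ids,
    gene = table$gene,
    allele_a = a1,
    allele_b = a2,
    diplotype = paste(a1, a2, sep = "/"),
    activity = unname(act),
    default_wildtype_a = ifelse(swap, cb$is_default_wildtype,
                                ca$is_default_wildtype),
    default_wildtype_b = ifelse(swap, ca$is_default_wildtype,
                                cb$is_default_wildtype),
    stringsAsFactors = FALSE
  )
  attr(out, "missing_site_events") <- sum(ca$missing) + sum(cb$missing)
  class(out) <- c("cyp_diplotypes", "data.frame")
  out
}

#' CYP2D6 activity-score to phenotype mapping
#'
#' Bins a Gaedigk activity score into a metabolizer phenotype. The default
#' mapping assigns 0 to poor (PM), 0.5–1 to intermediate (IM) and 1.5–2 to
#' normal (NM) metabolizers; the alternative `"legacy"` mapping keeps a
#' score of 1 in the normal group, reflecting earlier guidance. Scores
#' outside \{0, 0.5, 1, 1.5, 2\} are an error (they cannot arise without
#' copy-number alleles).
#'
#' @param activity Numeric vector of activity scores.
#' @param scheme `"default"` or `"legacy"`.
#' @return Character vector of `"PM"`, `"IM"`, `"NM"`.
#' @export
assign_cyp2d6_phenotype <- function(activity, scheme = c("default", "legacy")) {
  scheme <- match.arg(scheme)
  ok <- activity %in% c(0, 0.5, 1, 1.5, 2)
  if (any(!ok)) {
    stop("activity score(s) outside {0, 0.5, 1, 1.5, 2}: ",
         paste(unique(activity[!ok]), collapse = ", "))
  }
  im_max <- if (scheme == "default") 1 else 0.5
  ifelse(activity == 0, "PM", ifelse(activity <= im_max, "IM", "NM"))
}

#' CYP2C19 diplotype to phenotype mapping
#'
#' CYP2C19 phenotypes are assigned from the function classes of the two
#' alleles: two no-function alleles give a poor metabolizer (PM); one
#' no-function allele paired with a normal allele gives an intermediate
#' metabolizer (IM); two normal alleles a normal metabolizer (NM); one
#' increased-function allele with a normal allele a rapid metabolizer (RM);
#' and two increased-function alleles an ultra-rapid metabolizer (UM).
#' The no-function + increased-function combination (e.g. *2/*17) follows
#' the CPIC convention of IM by default; set `none_increased = "RM"` to
#' bin it with the rapid group instead.
#'
#' @param fa,fb Character vectors of function classes
#'   (`"none"`, `"normal"`, `"increased"`).
#' @param none_increased Label for the no-function/increased combination.
#' @return Character vector of `"PM"`, `"IM"`, `"NM"`, `"RM"`, `"UM"`.
#' @export
assign_cyp2c19_phenotype <- function(fa, fb,
                                     none_increased = c("IM", "RM")) {
  none_increased <- match.arg(none_increased)
  key <- paste(pmin(fa, fb), pmax(fa, fb), sep = "+")
  map <- c("none+none" = "PM",
           "none+normal" = "IM",
           "increased+none" = none_increased,
           "normal+normal" = "NM",
           "increased+normal" = "RM",
           "increased+increased" = "UM")
  out <- unname(map[key])
  if (any(is.na(out))) {
    stop("no phenotype mapping for function-class combination(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "))
  }
  out
}

#' Assign metabolizer phenotypes to called diplotypes
#'
#' Dispatches on the table's gene: CYP2D6 phenotypes come from the activity
#' score via [assign_cyp2d6_phenotype()]; CYP2C19 phenotypes from the two
#' alleles' function classes via [assign_cyp2c19_phenotype()].
#'
#' @param diplotypes A `cyp_diplotypes` data.frame from [call_diplotypes()].
#' @param table The matching `cyp_allele_table`.
#' @param ... Passed to the gene-specific mapping (`scheme` or
#'   `none_increased`).
#' @return The input data.frame with a `phenotype` column added.
#' @export
assign_phenotypes <- function(diplotypes, table, ...) {
  if (!identical(unique(diplotypes$gene), table$gene)) {
    stop("diplotypes and definition table refer to different genes")
  }
  if (table$gene == "CYP2D6") {
    diplotypes$phenotype <- assign_cyp2d6_phenotype(diplotypes$activity, ...)
  } else {
    fun <- table$alleles$function_class
    names(fun) <- table$alleles$name
    diplotypes$phenotype <- assign_cyp2c19_phenotype(
      unname(fun[diplotypes$allele_a]), unname(fun[diplotypes$allele_b]), ...)
  }
  diplotypes
}

#' Phenotype frequency table
#'
#' Tabulates metabolizer phenotype counts and percentages per gene, in the
#' layout of a cohort-description table (`count (pct%)`). Percentages are
#' rounded to one decimal.
#'
#' @param phenotypes Either a data.frame with `gene` and `phenotype`
#'   columns, or a named integer vector of counts for a single gene
#'   (names = phenotype labels).
#' @param gene Gene label used when `phenotypes` is a count vector.
#' @return data.frame `gene, phenotype, n, pct, formatted`, ordered
#'   NM, IM, PM, RM, UM within gene. Empty input gives an empty table with
#'   a warning.
#' @export
#' @examples
#' phenotype_frequencies(c(NM = 22486, IM = 7433, PM = 1660), gene = "CYP2D6")
phenotype_frequencies <- function(phenotypes, gene = "CYP2D6") {
  if (is.data.frame(phenotypes)) {
    if (!nrow(phenotypes)) {
      warning("empty cohort: returning empty frequency table")
      return(data.frame(gene = character(), phenotype = character(),
                        n = integer(), pct = numeric(),
                        formatted = character(), stringsAsFactors = FALSE))
    }
    pieces <- lapply(split(phenotypes, phenotypes$gene), function(d) {
      counts <- table(d$phenotype)
      phenotype_frequencies(setNames(as.integer(counts), names(counts)),
                            gene = d$gene[1])
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    return(out)
  }
  order_ref <- c("NM", "IM", "PM", "RM", "UM")
  labels <- intersect(order_ref, names(phenotypes))
  labels <- c(labels, setdiff(names(phenotypes), order_ref))
  n <- as.integer(phenotypes[labels])
  pct <- round(100 * n / sum(n), 1)
  data.frame(gene = gene, phenotype = labels, n = n, pct = pct,
             formatted = sprintf("%d (%.1f%%)", n, pct),
             stringsAsFactors = FALSE, row.names = NULL)
}
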