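#' Load a star-allele definition table
#'
#' Reads a tab-separated star-allele definition table plus an optional JSON
#' sidecar carrying gene/build/region metadata, validates it, and returns a
#' `cyp_allele_table` object used by the haplotype matcher and phenotyper.
#'
#' The TSV has one row per (allele, defining variant) with columns
#' `gene, allele, rsid, chrom, pos, ref, alt, function, activity_value`.
#' The reference allele `*1` is represented by a single row with empty
#' variant fields. Coordinates are 1-based, as in VCF.
#'
#' @param path Path to the definition TSV.
#' @param metadata Path to a JSON sidecar with fields `gene`, `build`,
#'   `region_start`, `region_end`. Defaults to `path` with a `.json`
#'   extension when such a file exists; otherwise metadata is inferred
#'   from the table (no region check possible).
#'
#' @return An object of class `cyp_allele_table`: a list with elements
#'   `gene`, `build`, `region` (length-2 numeric or `NULL`), `sites`
#'   (data.frame `id, chrom, pos, ref, alt`), `alleles` (data.frame
#'   `name, function_class, activity_value, n_variants`) and `defining`
#'   (named list mapping allele name to its defining site ids).
#' @export
#' @examples
#' tab <- load_allele_definitions(cyp_fixture_path("CYP2C19"))
#' tab
load_allele_definitions <- function(path, metadata = NULL) {
  if (!file.exists(path)) {
    stop("allele definition table not found: ", path)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  needed <- c("gene", "allele", "rsid", "chrom", "pos", "ref", "alt",
              "function.", "activity_value")
  # read.delim mangles the reserved word "function" to "function."
  if (!"function." %in% names(raw) && "function_class" %in% names(raw)) {
    names(raw)[names(raw) == "function_class"] <- "function."
  }
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("definition table is missing columns: ",
         paste(gsub("\\.$", "", missing_cols), collapse = ", "))
  }
  if (is.null(metadata)) {
    cand <- sub("\\.tsv$", ".json", path)
    if (file.exists(cand)) metadata <- cand
  }
  meta <- list(gene = unique(raw$gene)[1], build = NA_character_,
               region_start = NA_real_, region_end = NA_real_)
  if (!is.null(metadata)) {
    meta_in <- jsonlite::read_json(metadata, simplifyVector = TRUE)
    meta[names(meta_in)] <- meta_in
  }
  if (length(unique(raw$gene)) != 1L) {
    stop("definition table must describe exactly one gene, found: ",
         paste(unique(raw$gene), collapse = ", "))
  }
  if (!identical(unique(raw$gene), meta$gene)) {
    stop("gene in table (", unique(raw$gene), ") does not match metadata (",
         meta$gene, ")")
  }

  raw$pos <- suppressWarnings(as.numeric(raw$pos))
  raw$activity_value <- suppressWarnings(as.numeric(raw$activity_value))
  has_variant <- !is.na(raw$rsid)

  ## --- allele-level table -------------------------------------------------
  allele_names <- unique(raw$allele)
  per_allele <- lapply(allele_names, function(a) {
    rows <- raw[raw$allele == a, , drop = FALSE]
    fun <- unique(rows$function.)
    act <- unique(rows$activity_value)
    if (length(fun) != 1L || length(act) > 1L) {
      stop("allele ", a, " has inconsistent function/activity annotations")
    }
    list(name = a, function_class = fun,
         activity_value = if (length(act)) act else NA_real_,
         variants = rows$rsid[!is.na(rows$rsid)])
  })
  names(per_allele) <- allele_names

  ## --- validation ---------------------------------------------------------
  dup_rows <- duplicated(raw[c("allele", "rsid")]) & has_variant
  if (any(dup_rows)) {
    stop("definition error: duplicate (allele, variant) rows for ",
         paste(unique(raw$allele[dup_rows]), collapse = ", "))
  }
  if (sum(allele_names == "*1") != 1L) {
    stop("definition error: table must contain exactly one *1 allele")
  }
  ref_def <- per_allele[["*1"]]
  if (length(ref_def$variants) || !identical(ref_def$function_class, "normal")) {
    stop("definition error: *1 must have no defining variants and normal function")
  }
  ok_fun <- c("normal", "decreased", "none", "increased")
  for (d in per_allele) {
    if (!d$function_class %in% ok_fun) {
      stop("definition error: unknown function class '", d$function_class,
           "' for allele ", d$name)
    }
    if (d$name != "*1" && !length(d$variants)) {
      stop("definition error: allele ", d$name, " has no defining variants")
    }
    expected <- c(none = 0, decreased = 0.5, normal = 1)[d$function_class]
    if (!is.na(expected) && !is.na(d$activity_value) &&
        d$activity_value != expected) {
      stop("definition error: activity value ", d$activity_value,
           " inconsistent with function class '", d$function_class,
           "' for allele ", d$name)
    }
  }

  ## --- variant site table -------------------------------------------------
  vr <- raw[has_variant, c("rsid", "chrom", "pos", "ref", "alt")]
  names(vr)[1] <- "id"
  sites <- unique(vr)
  if (anyDuplicated(sites$id)) {
    stop("definition error: variant id used with conflicting coordinates/alleles: ",
         paste(sites$id[duplicated(sites$id)], collapse = ", "))
  }
  if (nrow(sites)) {
    if (any(is.na(sites$pos)) || any(sites$pos <= 0)) {
      stop("definition error: variant positions must be positive integers")
    }
    if (any(sites$ref == sites$alt)) {
      stop("definition error: ref and alt allele identical at ",
           paste(sites$id[sites$ref == sites$alt], collapse = ", "))
    }
    if (!is.na(meta$region_start) && !is.na(meta$region_end)) {
      outside <- sites$pos < meta$region_start | sites$pos > meta$region_end
      if (any(outside)) {
        stop("definition error: variants outside the extraction region: ",
             paste(sites$id[outside], collapse = ", "))
      }
    }
  }
  rownames(sites) <- NULL

  alleles <- data.frame(
    name = allele_names,
    function_class = vapply(per_allele, `[[`, "", "function_class"),
    activity_value = vapply(per_allele, `[[`, 0, "activity_value"),
    n_variants = vapply(per_allele, function(d) length(d$variants), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )

  structure(list(
    gene = meta$gene,
    build = meta$build,
    region = if (!is.na(meta$region_start)) c(start = meta$region_start,
                                              end = meta$region_end) else NULL,
    sites = sites,
    alleles = alleles,
    defining = lapply(per_allele, `[[`, "variants")
  ), class = "cyp_allele_table")
}

#' @export
print.cyp_allele_table <- function(x, ...) {
  cat("Star-allele definition table:", x$gene,
      if (!is.na(x$build)) paste0("(", x$build, ")"), "\n")
  cat(" ", nrow(x$alleles), "alleles over", nrow(x$sites), "variant sites\n")
  print(x$alleles, row.names = FALSE)
  invisible(x)
}

#' Path to a bundled star-allele fixture table
#'
#' The package ships reconstruction-quality definition tables for CYP2D6
#' (*1, *3, *4, *6, *9, *10, *17, *41) and CYP2C19 (*1, *2, *3, *17) with
#' real rsIDs and GRCh37 coordinates and CPIC-style function classes.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @return Path to the fixture TSV (its JSON sidecar sits alongside).
#' @export
cyp_fixture_path <- function(gene = c("CYP2D6", "CYP2C19")) {
  gene <- match.arg(gene)
  fn <- paste0(tolower(gene), "_alleles.tsv")
  p <- system.file("extdata", fn, package = "cypmeta")
  if (!nzchar(p)) stop("fixture table not installed: ", fn)
  p
}

## Score used to break ties among fully matching alleles: lower = less
## functional. CYP2C19 increased-function alleles carry NA activity, so the
## function class supplies the ordering there.
.allele_rank <- function(table) {
  act <- table$alleles$activity_value
  cls <- c(none = 0, decreased = 0.5, normal = 1, increased = 2)
  ifelse(is.na(act), cls[table$alleles$function_class], act)
}

#' Match one phased haplotype to a star allele
#'
#' A haplotype matches a star allele when it carries the alternate allele at
#' every one of the allele's defining variant sites. When several alleles
#' fully match, the allele with the most defining variants wins (most
#' specific); remaining ties go to the lowest-activity allele (conservative
#' toward impaired metabolism), then to the first allele name. A haplotype
#' matching no non-reference allele is called `*1` by default (wild-type),
#' the convention for panels that do not type every known variant.
#' Missing genotypes are treated as reference: they cannot support a match,
#' and are counted so that wild-type inflation can be monitored.
#'
#' @param hap Named integer/logical vector over the table's variant site ids:
#'   1/TRUE = alternate allele present, 0/FALSE = reference, NA = missing.
#' @param table A `cyp_allele_table`.
#' @return A list of class `haplotype_call`: `allele_name`,
#'   `matched_variants`, `is_default_wildtype`, `tie` (logical: several
#'   alleles matched maximally), `missing_defining_sites` (count of NA
#'   genotypes at defining sites of the table).
#' @export
#' @examples
#' tab <- load_allele_definitions(cyp_fixture_path("CYP2C19"))
#' hap <- setNames(c(1, 0, 0), tab$sites$id)
#' match_haplotype(hap, tab)
match_haplotype <- function(hap, table) {
  H <- matrix(hap, nrow = 1, dimnames = list(NULL, names(hap)))
  res <- match_haplotypes(H, table)
  structure(list(
    allele_name = res$allele[1],
    matched_variants = res$matched_variants[1],
    is_default_wildtype = res$is_default_wildtype[1],
    tie = res$tie[1],
    missing_defining_sites = res$missing[1]
  ), class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  cat("Haplotype call:", x$allele_name,
      if (x$is_default_wildtype) "(default wild-type)" else
        sprintf("(%d defining variant%s matched)", x$matched_variants,
                if (x$matched_variants == 1) "" else "s"), "\n")
  invisible(x)
}

#' Match many haplotypes at once
#'
#' Vectorised form of [match_haplotype()] over a haplotype matrix.
#'
#' @param H Matrix (haplotypes x sites) of 0/1/NA alternate-allele
#'   indicators; column names are variant site ids from `table`.
#' @param table A `cyp_allele_table`.
#' @return data.frame with one row per haplotype: `allele`,
#'   `matched_variants`, `is_default_wildtype`, `tie`, `missing`.
#' @export
match_haplotypes <- function(H, table) {
  n <- nrow(H)
  site_ids <- table$sites$id
  ## absent sites behave like missing genotypes (treated as reference)
  G <- matrix(NA_real_, n, length(site_ids), dimnames = list(NULL, site_ids))
  present <- intersect(colnames(H), site_ids)
  if (length(present)) G[, present] <- as.numeric(H[, present, drop = FALSE])
  n_missing <- if (length(site_ids)) rowSums(is.na(G)) else rep(0L, n)
  G[is.na(G)] <- 0

  alleles <- table$alleles
  cand <- alleles$name[alleles$name != "*1"]
  rank_all <- .allele_rank(table)
  names(rank_all) <- alleles$name

  ## full-match indicator per candidate allele, then resolve per haplotype:
  ## most defining variants first, then lowest activity, then lowest name
  ## (the last leg keeps calls invariant to table row order); a tie is any
  ## haplotype where several alleles match at the maximal specificity
  hits <- vapply(cand, function(a) {
    def <- table$defining[[a]]
    rowSums(G[, def, drop = FALSE]) == length(def)
  }, logical(n))
  hits <- matrix(hits, nrow = n, dimnames = list(NULL, cand))
  nvar <- vapply(cand, function(a) length(table$defining[[a]]), 0L)
  cand_order <- cand[order(-nvar, rank_all[cand], cand)]
  best <- rep("*1", n)
  best_nvar <- rep(0L, n)
  tie <- rep(FALSE, n)
  for (a in cand_order) {
    pick <- hits[, a] & best == "*1"
    best[pick] <- a
    best_nvar[pick] <- nvar[[a]]
  }
  if (length(cand)) {
    max_nvar_hit <- apply(hits, 1, function(h) {
      if (!any(h)) 0L else max(nvar[h])
    })
    n_at_max <- rowSums(hits & rep(nvar, each = n) ==
                          matrix(max_nvar_hit, n, length(cand)))
    tie <- n_at_max > 1L
  }
  data.frame(
    allele = best,
    matched_variants = best_nvar,
    is_default_wildtype = best == "*1",
    tie = tie,
    missing = as.integer(n_missing),
    stringsAsFactors = FALSE
  )
}

#' Gaedigk activity score of a diplotype
#'
#' The activity score is the sum of the two alleles' activity values
#' (0 = no function, 0.5 = decreased, 1 = normal), giving a score in
#' \[0, 2\] on a 0.5 grid for panels without copy-number data. Symmetric in
#' its two arguments.
#'
#' @param allele_a,allele_b Star-allele names present in `table`.
#' @param table A `cyp_allele_table`.
#' @return Numeric activity score.
#' @export
#' @examples
#' tab <- load_allele_definitions(cyp_fixture_path("CYP2D6"))
#' activity_score("*1", "*4", tab)  # 1
activity_score <- function(allele_a, allele_b, table) {
  vals <- table$alleles$activity_value
  names(vals) <- table$alleles$name
  unknown <- setdiff(c(allele_a, allele_b), names(vals))
  if (length(unknown)) {
    stop("unknown allele name(s): ", paste(unknown, collapse = ", "))
  }
  a <- vals[[allele_a]]; b <- vals[[allele_b]]
  if (is.na(a) || is.na(b)) {
    stop("activity score undefined for alleles without an activity value (",
         allele_a, "/", allele_b, ")")
  }
  a + b
}
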