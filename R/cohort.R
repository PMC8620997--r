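#' Load drug knowledge tables
#'
#' Reads the synonym map (proprietary -> generic), CYP substrate map,
#' inhibitor lists and drug-class table from TSV files. The package ships
#' editable fixture tables assembled from standard prescribing references;
#' the defaults point at those.
#'
#' @param synonyms,substrates,inhibitors,classes Paths to the four TSVs.
#' @return List of class `drug_knowledge`: `synonyms` (named character,
#'   lower-cased proprietary -> generic), `cyp2d6_substrates`,
#'   `cyp2c19_substrates`, `cyp2d6_inhibitors`, `cyp2c19_inhibitors`
#'   (character vectors), `classes` (named character drug -> class).
#' @export
load_drug_knowledge <- function(
    synonyms = system.file("extdata", "drug_synonyms.tsv", package = "cypmeta"),
    substrates = system.file("extdata", "drug_substrates.tsv", package = "cypmeta"),
    inhibitors = system.file("extdata", "drug_inhibitors.tsv", package = "cypmeta"),
    classes = system.file("extdata", "drug_classes.tsv", package = "cypmeta")) {
  for (p in c(synonyms, substrates, inhibitors, classes)) {
    if (!nzchar(p) || !file.exists(p)) stop("knowledge table not found: ", p)
  }
  syn <- utils::read.delim(synonyms, stringsAsFactors = FALSE)
  sub <- utils::read.delim(substrates, stringsAsFactors = FALSE)
  inh <- utils::read.delim(inhibitors, stringsAsFactors = FALSE)
  cls <- utils::read.delim(classes, stringsAsFactors = FALSE)
  if (!nrow(sub) || !nrow(inh)) {
    stop("configuration error: empty substrate or inhibitor table")
  }
  structure(list(
    synonyms = stats::setNames(tolower(syn$generic), tolower(syn$proprietary)),
    cyp2d6_substrates = tolower(sub$drug[sub$gene == "CYP2D6"]),
    cyp2c19_substrates = tolower(sub$drug[sub$gene == "CYP2C19"]),
    cyp2d6_inhibitors = tolower(inh$drug[inh$gene == "CYP2D6"]),
    cyp2c19_inhibitors = tolower(inh$drug[inh$gene == "CYP2C19"]),
    classes = stats::setNames(cls$class, tolower(cls$drug))
  ), class = "drug_knowledge")
}

#' Normalize free-text medication names
#'
#' Case-insensitive harmonization of recorded medication names: proprietary
#' names are mapped to their generic equivalent via the synonym map; names
#' already generic are lower-cased and passed through; unrecognized names
#' are passed through unchanged (lower-cased) and reported in the
#' `"unmatched"` attribute so data-curation gaps are visible rather than
#' silently dropped.
#'
#' @param raw_names Character vector of free-text drug names.
#' @param knowledge A `drug_knowledge` object.
#' @return Character vector of generic names, with attribute `unmatched`
#'   listing names found in neither the synonym map nor any knowledge table.
#' @export
#' @examples
#' k <- load_drug_knowledge()
#' normalize_medications(c("Seroxat", "PAROXETINE", "xyzzy"), k)
normalize_medications <- function(raw_names, knowledge) {
  low <- tolower(trimws(raw_names))
  out <- ifelse(low %in% names(knowledge$synonyms),
                unname(knowledge$synonyms[low]), low)
  known <- unique(c(unname(knowledge$synonyms),
                    knowledge$cyp2d6_substrates, knowledge$cyp2c19_substrates,
                    knowledge$cyp2d6_inhibitors, knowledge$cyp2c19_inhibitors,
                    names(knowledge$classes)))
  attr(out, "unmatched") <- unique(out[!out %in% known])
  out
}

#' Flag enzyme-inhibitor exposure
#'
#' Sets `takes_cyp2d6_inhibitor` / `takes_cyp2c19_inhibitor` per record:
#' TRUE iff any normalized medication appears in the respective inhibitor
#' list. `exclude` removes drugs from consideration — used to avoid flagging
#' a cohort's own index drug, which would make the inhibitor covariate
#' constant within that cohort.
#'
#' @param records data.frame with a `medications` list-column (character
#'   vectors of normalized generic names).
#' @param knowledge A `drug_knowledge` object.
#' @param exclude Character vector of drugs to ignore when flagging.
#' @return `records` with the two flag columns set.
#' @export
flag_inhibitors <- function(records, knowledge, exclude = NULL) {
  d6 <- setdiff(knowledge$cyp2d6_inhibitors, exclude)
  c19 <- setdiff(knowledge$cyp2c19_inhibitors, exclude)
  records$takes_cyp2d6_inhibitor <-
    vapply(records$medications, function(m) any(m %in% d6), logical(1))
  records$takes_cyp2c19_inhibitor <-
    vapply(records$medications, function(m) any(m %in% c19), logical(1))
  records
}

#' Apply participant-level exclusions
#'
#' Removes participants reporting antidiabetic medication while denying a
#' diabetes diagnosis (diagnostic uncertainty) and, when `require_hba1c`,
#' participants without an HbA1c measurement. Per-reason counts are
#' returned so exclusion flow can be reported.
#'
#' @param records Participant data.frame with `takes_antidiabetic`,
#'   `diabetes` and `hba1c` columns.
#' @param require_hba1c Drop records with missing HbA1c?
#' @return List with `kept` (data.frame) and `log` (data.frame
#'   `reason, n`).
#' @export
apply_exclusions <- function(records, require_hba1c = TRUE) {
  bad_dm <- records$takes_antidiabetic & !records$diabetes
  no_hba1c <- if (require_hba1c) !bad_dm & is.na(records$hba1c) else
    rep(FALSE, nrow(records))
  list(
    kept = records[!bad_dm & !no_hba1c, , drop = FALSE],
    log = data.frame(
      reason = c("antidiabetic_without_diabetes", "missing_hba1c"),
      n = c(sum(bad_dm), sum(no_hba1c)),
      stringsAsFactors = FALSE)
  )
}

#' Build drug-defined analysis cohorts
#'
#' Builds the cohorts the association stage models:
#' \itemize{
#'   \item one single-drug cohort per antidepressant taken by at least
#'     `single_drug_min` participants (or per drug in `pin_drugs` when
#'     supplied, regardless of counts), analysed for the gene(s) whose
#'     substrate the drug is;
#'   \item a grouped tricyclic cohort excluding amitriptyline (whose high
#'     frequency would dominate a pooled TCA analysis), modelled for both
#'     genes since tertiary-amine TCAs are sequential CYP2C19/CYP2D6
#'     substrates;
#'   \item a grouped antipsychotics cohort over all CYP2D6-substrate
#'     antipsychotics, modelled for CYP2D6 only.
#' }
#' A participant taking several study drugs contributes to every matching
#' cohort; membership is not exclusive.
#'
#' @param records Participant data.frame (normalized `medications`
#'   list-column, exclusions already applied).
#' @param knowledge A `drug_knowledge` object.
#' @param single_drug_min Minimum participant count for an independent
#'   single-drug cohort (default 1800).
#' @param comparator Comparison used against the threshold; default `>=`.
#' @param pin_drugs Optional character vector pinning the single-drug list.
#' @return Named list of cohorts, each a list
#'   `label, genes, drugs, members`.
#' @export
build_cohorts <- function(records, knowledge, single_drug_min = 1800,
                          comparator = `>=`, pin_drugs = NULL) {
  if (!length(knowledge$cyp2d6_substrates) &&
      !length(knowledge$cyp2c19_substrates)) {
    stop("configuration error: empty substrate knowledge")
  }
  cls <- knowledge$classes
  takes <- function(drugs) {
    vapply(records$medications, function(m) any(m %in% drugs), logical(1))
  }
  antidep_classes <- c("SSRI", "SNRI", "TCA", "other_antidepressant")
  antidep <- names(cls)[cls %in% antidep_classes]

  cohorts <- list()
  if (is.null(pin_drugs)) {
    counts <- vapply(antidep, function(d) sum(takes(d)), 0L)
    singles <- names(counts)[comparator(counts, single_drug_min)]
  } else {
    singles <- tolower(pin_drugs)
  }
  for (d in sort(singles)) {
    genes <- c(if (d %in% knowledge$cyp2d6_substrates) "CYP2D6",
               if (d %in% knowledge$cyp2c19_substrates) "CYP2C19")
    if (is.null(genes)) next
    members <- records[takes(d), , drop = FALSE]
    cohorts[[d]] <- list(label = d, genes = genes, drugs = d,
                         members = members)
  }

  tcas <- setdiff(names(cls)[cls == "TCA"], "amitriptyline")
  cohorts[["tricyclics_excl_amitriptyline"]] <- list(
    label = "tricyclics_excl_amitriptyline",
    genes = c("CYP2D6", "CYP2C19"), drugs = tcas,
    members = records[takes(tcas), , drop = FALSE])

  aps <- intersect(names(cls)[cls == "antipsychotic"],
                   knowledge$cyp2d6_substrates)
  cohorts[["antipsychotics_cyp2d6"]] <- list(
    label = "antipsychotics_cyp2d6", genes = "CYP2D6", drugs = aps,
    members = records[takes(aps), , drop = FALSE])

  cohorts
}
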