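#' Run the full phenotyping and association pipeline
#'
#' Orchestrates simulate (optional) -> variant/sample QC (optional) ->
#' diplotype and phenotype calling -> cohort building -> association
#' modelling into one reproducible run. Inputs, thresholds and model
#' options come from a single configuration (YAML file or list); every
#' stage writes its log/output under `out_dir`, and a manifest records the
#' seed and MD5 hashes of all file inputs so a run can be reproduced
#' exactly.
#'
#' Configuration fields:
#' \describe{
#'   \item{`out_dir`}{Output directory (created if absent). Required.}
#'   \item{`seed`}{Integer seed used for all randomness.}
#'   \item{`simulate`}{List of [sim_config()] arguments; when present the
#'     cohort is simulated and written to `out_dir` (phased VCF per gene +
#'     participant TSV), then read back through the standard readers.}
#'   \item{`inputs`}{When not simulating: `participants` (TSV path) and
#'     `vcf` (named list gene -> phased VCF path).}
#'   \item{`allele_tables`}{Optional named list gene -> definition TSV path
#'     (default: bundled fixtures).}
#'   \item{`qc`}{Optional: `variant_metrics` (TSV with id, maf, info_score,
#'     genotyped, is_star_defining, cluster_review_pass), `sample_qc`
#'     (TSV with sample_id, missingness, sex_mismatch, excess_relatedness),
#'     `kinship` (TSV with id1, id2, kinship).}
#'   \item{`cohorts`}{`single_drug_min` (default 1800), optional
#'     `pin_drugs`.}
#'   \item{`model`}{`interaction` (default TRUE), `scheme` for the CYP2D6
#'     activity bins.}
#' }
#'
#' @param config YAML file path or configuration list.
#' @return Invisibly, the run report: per-stage logs, phenotype frequency
#'   table, per-cohort coefficient tables and verdicts, and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config

  ## ---- validation: fail before any compute ------------------------------
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  file_inputs <- character()
  collect <- function(x) if (!is.null(x)) file_inputs <<- c(file_inputs, x)
  collect(unlist(cfg$inputs$vcf))
  collect(cfg$inputs$participants)
  collect(unlist(cfg$allele_tables))
  collect(cfg$qc$variant_metrics)
  collect(cfg$qc$sample_qc)
  collect(cfg$qc$kinship)
  missing_files <- file_inputs[!file.exists(file_inputs)]
  if (length(missing_files)) {
    stop("config error: missing input file(s): ",
         paste(missing_files, collapse = ", "))
  }
  if (is.null(cfg$simulate) && (is.null(cfg$inputs$participants) ||
                                is.null(cfg$inputs$vcf))) {
    stop("config error: either 'simulate' or 'inputs' (participants + vcf) ",
         "must be provided")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  report <- list(seed = cfg$seed, stages = list())
  knowledge <- load_drug_knowledge()
  tables <- if (!is.null(cfg$allele_tables)) {
    lapply(cfg$allele_tables, load_allele_definitions)
  } else {
    list(CYP2D6 = load_allele_definitions(cyp_fixture_path("CYP2D6")),
         CYP2C19 = load_allele_definitions(cyp_fixture_path("CYP2C19")))
  }

  ## ---- stage: simulate or load ------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- NULL          # pipeline seed governs the whole run
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_cohort(scfg, tables = tables, knowledge = knowledge)
    vcf_paths <- list()
    for (g in names(tables)) {
      p <- file.path(cfg$out_dir, paste0(tolower(g), "_phased.vcf"))
      write_phased_vcf(sim$haplotypes[[g]]$hapA, sim$haplotypes[[g]]$hapB,
                       tables[[g]], p)
      vcf_paths[[g]] <- p
    }
    part_path <- file.path(cfg$out_dir, "participants.tsv")
    pcols <- setdiff(names(sim$participants),
                     c("medications", grep("_diplotype$|_phenotype$|_inhibitor$",
                                           names(sim$participants),
                                           value = TRUE)))
    utils::write.table(sim$participants[pcols], part_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth[setdiff(names(sim$truth),
                                         "linear_predictor")],
                       file.path(cfg$out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$simulate <- list(n = scfg$n_participants,
                                   n_clipped = sim$n_clipped)
  } else {
    vcf_paths <- cfg$inputs$vcf
    part_path <- cfg$inputs$participants
  }
  participants <- utils::read.delim(part_path, stringsAsFactors = FALSE)
  haps <- lapply(names(tables)[names(tables) %in% names(vcf_paths)],
                 function(g) read_phased_vcf(vcf_paths[[g]], tables[[g]]))
  names(haps) <- names(tables)[names(tables) %in% names(vcf_paths)]

  ## ---- stage: QC ---------------------------------------------------------
  if (!is.null(cfg$qc)) {
    qc_log <- list()
    thr <- do.call(qc_thresholds, if (is.null(cfg$qc$thresholds)) list()
                   else cfg$qc$thresholds)
    if (!is.null(cfg$qc$variant_metrics)) {
      vm <- utils::read.delim(cfg$qc$variant_metrics,
                              stringsAsFactors = FALSE)
      fv <- filter_variants(vm, thr)
      rescued <- rescue_rare_variants(fv$rescue_candidates, thr)
      keep_ids <- c(fv$retained$id, rescued$id)
      for (g in names(haps)) {
        drop <- setdiff(colnames(haps[[g]]$hapA), keep_ids)
        haps[[g]]$hapA[, drop] <- NA_integer_
        haps[[g]]$hapB[, drop] <- NA_integer_
      }
      utils::write.table(fv$log, file.path(cfg$out_dir,
                                           "variant_exclusions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      qc_log$variants <- list(retained = length(keep_ids),
                              rescued = nrow(rescued),
                              excluded = nrow(fv$log))
    }
    if (!is.null(cfg$qc$sample_qc)) {
      sq <- utils::read.delim(cfg$qc$sample_qc, stringsAsFactors = FALSE)
      kp <- if (!is.null(cfg$qc$kinship)) {
        utils::read.delim(cfg$qc$kinship, stringsAsFactors = FALSE)
      } else NULL
      ex <- exclude_samples(sq, kp, thr)
      participants <- participants[participants$sample_id %in% ex$kept, ,
                                   drop = FALSE]
      for (g in names(haps)) {
        keep <- rownames(haps[[g]]$hapA) %in% ex$kept
        haps[[g]]$hapA <- haps[[g]]$hapA[keep, , drop = FALSE]
        haps[[g]]$hapB <- haps[[g]]$hapB[keep, , drop = FALSE]
      }
      utils::write.table(ex$removed, file.path(cfg$out_dir,
                                               "sample_exclusions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      qc_log$samples <- list(kept = length(ex$kept),
                             removed = nrow(ex$removed))
    }
    report$stages$qc <- qc_log
  }

  ## ---- stage: phenotype ---------------------------------------------------
  pheno_rows <- list()
  for (g in names(haps)) {
    H <- haps[[g]]
    ids <- rownames(H$hapA)
    dip <- call_diplotypes(H$hapA, H$hapB, tables[[g]], sample_ids = ids)
    scheme_args <- if (g == "CYP2D6" && !is.null(cfg$model$scheme)) {
      list(scheme = cfg$model$scheme)
    } else list()
    dip <- do.call(assign_phenotypes, c(list(dip, tables[[g]]), scheme_args))
    pheno_rows[[g]] <- dip
    m <- match(participants$sample_id, dip$sample_id)
    participants[[paste0(tolower(g), "_diplotype")]] <- dip$diplotype[m]
    participants[[paste0(tolower(g), "_phenotype")]] <- dip$phenotype[m]
  }
  pheno_all <- do.call(rbind, pheno_rows)
  freq <- phenotype_frequencies(pheno_all)
  utils::write.table(pheno_all, file.path(cfg$out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(freq, file.path(cfg$out_dir,
                                     "phenotype_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$phenotype <- freq

  ## ---- stage: cohorts -----------------------------------------------------
  participants$medications <- lapply(
    strsplit(participants$medications_raw, ";", fixed = TRUE),
    function(m) normalize_medications(m[nzchar(m)], knowledge))
  participants <- flag_inhibitors(participants, knowledge)
  excl <- apply_exclusions(participants)
  utils::write.table(excl$log, file.path(cfg$out_dir,
                                         "participant_exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cohorts <- build_cohorts(excl$kept, knowledge,
                           single_drug_min = if (is.null(cfg$cohorts$single_drug_min))
                             1800 else cfg$cohorts$single_drug_min,
                           pin_drugs = cfg$cohorts$pin_drugs)
  report$stages$cohorts <- list(
    exclusions = excl$log,
    sizes = vapply(cohorts, function(co) nrow(co$members), 0L))

  ## ---- stage: association -------------------------------------------------
  grouped_labels <- c("tricyclics_excl_amitriptyline", "antipsychotics_cyp2d6")
  assoc <- list()
  for (lab in names(cohorts)) {
    co <- cohorts[[lab]]
    family <- if (lab %in% grouped_labels) "grouped" else "single_drug"
    res <- tryCatch({
      want_ix <- isTRUE(cfg$model$interaction %||% TRUE)
      fit <- NULL
      interaction_dropped <- FALSE
      if (want_ix) {
        ## small cohorts can have empty phenotype-by-diabetes cells; fall
        ## back to the main-effects model rather than failing the stage
        fit <- tryCatch(
          suppressWarnings(fit_hba1c_model(co$members, genes = co$genes,
                                           interaction = TRUE,
                                           cohort_label = lab)),
          error = function(e) NULL)
        interaction_dropped <- is.null(fit)
      }
      if (is.null(fit)) {
        fit <- suppressWarnings(fit_hba1c_model(
          co$members, genes = co$genes, interaction = FALSE,
          cohort_label = lab))
      }
      tab <- apply_thresholds(fit, family = family)
      out <- list(table = tab, observations = fit$observations,
                  r2 = fit$r2, adj_r2 = fit$adj_r2, family = family,
                  interaction_dropped = interaction_dropped)
      if (fit$interaction) {
        out$decision <- test_interaction(fit)
        if (out$decision == "stratify") {
          strat <- tryCatch(
            suppressWarnings(fit_stratified(co$members, genes = co$genes,
                                            cohort_label = lab)),
            error = function(e) NULL)
          if (!is.null(strat)) {
            out$stratified <- lapply(strat, function(f)
              apply_thresholds(f, family = family))
          }
        }
      }
      out
    }, error = function(e) list(error = conditionMessage(e),
                                family = family))
    if (!is.null(res$table)) {
      utils::write.table(res$table,
                         file.path(cfg$out_dir,
                                   paste0("assoc_", lab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    assoc[[lab]] <- res
  }
  report$stages$association <- assoc

  ## ---- manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("cypmeta")),
    seed = cfg$seed,
    inputs = if (length(file_inputs)) {
      as.list(tools::md5sum(file_inputs))
    } else list(),
    n_participants = nrow(participants),
    cohorts = as.list(report$stages$cohorts$sizes))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$manifest <- manifest
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
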