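#' Default star-allele frequencies
#'
#' European-like star-allele frequencies for the bundled definition panels,
#' chosen so that simulated metabolizer phenotype shares approximate a large
#' European-ancestry biobank cohort (CYP2D6 PM near 5%, CYP2C19 PM near 3.4%
#' and UM near 4%). These are simulation defaults, not population estimates.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @return Named numeric vector of haplotype frequencies summing to 1.
#' @export
default_allele_frequencies <- function(gene = c("CYP2D6", "CYP2C19")) {
  gene <- match.arg(gene)
  switch(gene,
         CYP2D6 = c("*1" = 0.655, "*3" = 0.010, "*4" = 0.185, "*6" = 0.010,
                    "*9" = 0.030, "*10" = 0.020, "*17" = 0.005,
                    "*41" = 0.085),
         CYP2C19 = c("*1" = 0.596, "*2" = 0.180, "*3" = 0.004,
                     "*17" = 0.220))
}

#' Default generative coefficients for simulated HbA1c
#'
#' Named vector of linear-model coefficients (model-matrix naming) used by
#' the cohort simulator: a diabetes shift of 6.85 mmol/mol and CYP2D6
#' IM/PM shifts of 0.23 and 2.43 mmol/mol in the style of a published
#' paroxetine cohort, plus nuisance effects (antidiabetic treatment, BMI,
#' age, sex, ancestry, inhibitor exposure) set to plausible magnitudes with
#' the intercept placed so mean HbA1c lands near 37.1 mmol/mol.
#'
#' @return Named numeric vector.
#' @export
default_generative_coefficients <- function() {
  c("(Intercept)" = 21.4,
    "diabetesTRUE" = 6.85,
    "cyp2d6_phenotypeIM" = 0.23,
    "cyp2d6_phenotypePM" = 2.43,
    "takes_antidiabeticTRUE" = 8.0,
    "takes_cyp2d6_inhibitorTRUE" = 0.3,
    "takes_cyp2c19_inhibitorTRUE" = 0.35,
    "bmi" = 0.35,
    "age" = 0.08,
    "sexMale" = -0.3,
    "ancestryAdmixedEuropean" = 0.5,
    "ancestryAfrican" = 1.5,
    "ancestryEastAsian" = 0.8,
    "ancestrySouthAsian" = 1.2,
    "ancestryOther" = 0.6)
}

#' Simulation configuration
#'
#' Validated container of all generative settings for the synthetic
#' biobank-style cohort: haplotype frequencies per gene, medication
#' assignment probabilities, disease prevalence, covariate distributions
#' (age uniform on 40–70 years; BMI normal with mean 28.8 and SD 5.66
#' kg/m^2; roughly two-thirds female), generative HbA1c coefficients,
#' residual SD and seed.
#'
#' @param n_participants Cohort size.
#' @param allele_frequencies Named list per gene of haplotype frequency
#'   vectors (must sum to 1; allele names must exist in the matching
#'   definition table).
#' @param drug_probabilities Named numeric vector: per-drug probability that
#'   a participant takes the drug (independent draws).
#' @param diabetes_prevalence Probability of diabetes.
#' @param antidiabetic_given_diabetes Probability a diabetic participant
#'   takes antidiabetic medication.
#' @param n_antidiabetic_without_diabetes Exact number of records violating
#'   the antidiabetic-without-diabetes rule (injected to exercise the
#'   exclusion step).
#' @param age_range,bmi_mean,bmi_sd,female_share Covariate distributions.
#' @param ancestry_probs Named probabilities of ancestry groups.
#' @param coefficients Generative HbA1c coefficients (model-matrix naming).
#' @param residual_sd Residual SD of simulated HbA1c (> 0).
#' @param proprietary_rate Probability that a recorded medication name is
#'   replaced by a proprietary synonym (exercises name normalization).
#' @param missing_hba1c_rate Probability of a missing HbA1c measurement.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_participants = 500,
                       allele_frequencies = list(
                         CYP2D6 = default_allele_frequencies("CYP2D6"),
                         CYP2C19 = default_allele_frequencies("CYP2C19")),
                       drug_probabilities = c(paroxetine = 0.25,
                                              fluoxetine = 0.25,
                                              venlafaxine = 0.15,
                                              amitriptyline = 0.25,
                                              olanzapine = 0.05,
                                              omeprazole = 0.20),
                       diabetes_prevalence = 0.089,
                       antidiabetic_given_diabetes = 0.7,
                       n_antidiabetic_without_diabetes = 0,
                       age_range = c(40, 70),
                       bmi_mean = 28.8, bmi_sd = 5.66,
                       female_share = 0.689,
                       ancestry_probs = c(European = 0.938,
                                          AdmixedEuropean = 0.025,
                                          African = 0.009,
                                          EastAsian = 0.001,
                                          SouthAsian = 0.012,
                                          Other = 0.015),
                       coefficients = default_generative_coefficients(),
                       residual_sd = 5.8,
                       proprietary_rate = 0.10,
                       missing_hba1c_rate = 0,
                       seed = NULL) {
  for (g in names(allele_frequencies)) {
    f <- allele_frequencies[[g]]
    if (abs(sum(f) - 1) > 1e-8) {
      stop("allele frequencies for ", g, " must sum to 1 (got ", sum(f), ")")
    }
    if (any(f < 0)) stop("negative allele frequency for ", g)
  }
  probs <- c(drug_probabilities, diabetes_prevalence,
             antidiabetic_given_diabetes, female_share, proprietary_rate,
             missing_hba1c_rate, ancestry_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (residual_sd <= 0) stop("residual_sd must be positive")
  structure(list(
    n_participants = n_participants,
    allele_frequencies = allele_frequencies,
    drug_probabilities = drug_probabilities,
    diabetes_prevalence = diabetes_prevalence,
    antidiabetic_given_diabetes = antidiabetic_given_diabetes,
    n_antidiabetic_without_diabetes = n_antidiabetic_without_diabetes,
    age_range = age_range, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    female_share = female_share, ancestry_probs = ancestry_probs,
    coefficients = coefficients, residual_sd = residual_sd,
    proprietary_rate = proprietary_rate,
    missing_hba1c_rate = missing_hba1c_rate, seed = seed
  ), class = "sim_config")
}

#' Simulate phased haplotypes under Hardy–Weinberg equilibrium
#'
#' Draws two independent star alleles per participant from the supplied
#' haplotype frequencies (random mating) and renders each haplotype as a
#' phased alternate-allele indicator vector carrying exactly its allele's
#' defining variants.
#'
#' @param n Number of participants.
#' @param table A `cyp_allele_table`.
#' @param frequencies Named haplotype frequencies; names must be alleles of
#'   `table` (alleles omitted get frequency 0); must sum to 1.
#' @param sample_ids Optional ids (default `S1..Sn`).
#' @param seed Optional integer seed.
#' @return List: `hapA`, `hapB` (0/1 matrices samples x sites), `truth`
#'   (data.frame `sample_id, gene, allele_a, allele_b` of the generative
#'   draws, unordered pair sorted by table order).
#' @export
simulate_haplotypes <- function(n, table,
                                frequencies = default_allele_frequencies(table$gene),
                                sample_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(names(frequencies), table$alleles$name)
  if (length(unknown)) {
    stop("frequencies name allele(s) absent from the definition table: ",
         paste(unknown, collapse = ", "))
  }
  if (abs(sum(frequencies) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  alleles <- names(frequencies)
  drawA <- sample(alleles, n, replace = TRUE, prob = frequencies)
  drawB <- sample(alleles, n, replace = TRUE, prob = frequencies)

  render <- function(draw) {
    H <- matrix(0L, n, nrow(table$sites),
                dimnames = list(sample_ids, table$sites$id))
    for (a in setdiff(unique(draw), "*1")) {
      H[draw == a, table$defining[[a]]] <- 1L
    }
    H
  }
  ord <- stats::setNames(seq_len(nrow(table$alleles)), table$alleles$name)
  swap <- ord[drawA] > ord[drawB]
  truth <- data.frame(
    sample_id = sample_ids, gene = table$gene,
    allele_a = ifelse(swap, drawB, drawA),
    allele_b = ifelse(swap, drawA, drawB),
    stringsAsFactors = FALSE)
  list(hapA = render(drawA), hapB = render(drawB), truth = truth)
}

#' Write phased genotypes as a VCF
#'
#' Renders phased haplotype matrices as a minimal plain-text VCF 4.2 file
#' (GT field only, `|`-separated), sorted by position, suitable for
#' round-tripping through standard VCF readers.
#'
#' @param hapA,hapB 0/1 matrices (samples x sites; column names = site ids
#'   in `table`).
#' @param table The `cyp_allele_table` providing site coordinates and the
#'   genome build recorded in the header.
#' @param path Output file path.
#' @param sample_ids Sample names (default rownames of `hapA`).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hapA, hapB, table, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- rownames(hapA)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(hapA)))
  sites <- table$sites[order(table$sites$chrom, table$sites$pos), ,
                       drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cypmeta",
    if (!is.na(table$build)) paste0("##reference=", table$build),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    id <- sites$id[i]
    gt <- paste0(hapA[, id], "|", hapB[, id])
    paste(c(sites$chrom[i], format(sites$pos[i], scientific = FALSE), id,
            sites$ref[i], sites$alt[i], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read phased genotypes from a VCF
#'
#' Reads a phased VCF restricted to a gene region and returns
#' alternate-allele indicator matrices for the two haplotypes over the
#' definition table's variant sites. Sites are matched by ID, falling back
#' to `chrom:pos`. Unphased genotypes are an error naming the sample and
#' site; sites absent from the VCF come back as `NA` (treated as reference
#' downstream). A genome build recorded in the VCF header that differs from
#' the table's build triggers a warning.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param table A `cyp_allele_table`.
#' @return List `hapA`, `hapB`: matrices samples x sites (0/1/NA).
#' @export
read_phased_vcf <- function(path, table) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ref_line <- grep("^##reference=", v@meta, value = TRUE)
  if (length(ref_line) && !is.na(table$build)) {
    build <- sub("^##reference=", "", ref_line[1])
    if (!identical(build, table$build)) {
      warning("VCF genome build (", build, ") differs from definition table (",
              table$build, ")")
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  vcf_keys <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                     paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                     fix[, "ID"])
  samples <- colnames(gt)
  n <- length(samples)
  site_ids <- table$sites$id
  hapA <- matrix(NA_integer_, n, length(site_ids),
                 dimnames = list(samples, site_ids))
  hapB <- hapA
  for (j in seq_along(site_ids)) {
    key2 <- paste0(table$sites$chrom[j], ":", table$sites$pos[j])
    row <- which(vcf_keys == site_ids[j] | vcf_keys == key2)
    if (!length(row)) next
    g <- gt[row[1], ]
    bad <- grepl("/", g, fixed = TRUE)
    if (any(bad)) {
      stop("unphased genotype for sample ", samples[which(bad)[1]],
           " at site ", site_ids[j])
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    hapA[, j] <- as.integer(vapply(parts, `[`, "", 1) != "0")
    hapB[, j] <- as.integer(vapply(parts, `[`, "", 2) != "0")
    miss <- is.na(g)
    hapA[miss, j] <- NA_integer_
    hapB[miss, j] <- NA_integer_
  }
  list(hapA = hapA, hapB = hapB)
}

#' Simulate a participant table
#'
#' Generates the non-genetic side of the synthetic cohort: medications
#' (independent per-drug Bernoulli draws, with a configurable fraction of
#' names replaced by proprietary synonyms to exercise normalization),
#' diabetes status, antidiabetic flags — including an exact configured
#' number of antidiabetic-without-diabetes records — and covariates.
#' HbA1c is left `NA` here; it is generated from the linear model once
#' phenotypes are known (see [simulate_cohort()]).
#'
#' @param cfg A [sim_config()].
#' @param knowledge Optional `drug_knowledge` used to look up proprietary
#'   synonyms for name injection.
#' @return data.frame: `sample_id`, `medications_raw` (semicolon-joined
#'   recorded names), `diabetes`, `takes_antidiabetic`, `hba1c` (NA), `bmi`,
#'   `age`, `sex`, `ancestry`.
#' @export
simulate_participants <- function(cfg, knowledge = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_participants
  ids <- paste0("S", seq_len(n))
  drugs <- names(cfg$drug_probabilities)
  med <- lapply(seq_len(n), function(i) character(0))
  for (d in drugs) {
    takes <- stats::rbinom(n, 1, cfg$drug_probabilities[[d]]) == 1
    med[takes] <- lapply(med[takes], c, d)
  }
  if (!is.null(knowledge) && cfg$proprietary_rate > 0) {
    rev_map <- split(names(knowledge$synonyms), unname(knowledge$synonyms))
    med <- lapply(med, function(m) {
      if (!length(m)) return(m)
      swap <- stats::runif(length(m)) < cfg$proprietary_rate
      m[swap] <- vapply(m[swap], function(d) {
        alts <- rev_map[[d]]
        if (is.null(alts)) d else alts[1]
      }, "")
      m
    })
  }
  diabetes <- stats::rbinom(n, 1, cfg$diabetes_prevalence) == 1
  antidiab <- diabetes & stats::rbinom(n, 1,
                                       cfg$antidiabetic_given_diabetes) == 1
  k <- cfg$n_antidiabetic_without_diabetes
  if (k > 0) {
    pool <- which(!diabetes)
    if (length(pool) < k) stop("not enough non-diabetic records to inject ",
                               k, " rule violations")
    antidiab[pool[seq_len(k)]] <- TRUE
  }
  data.frame(
    sample_id = ids,
    medications_raw = vapply(med, paste, "", collapse = ";"),
    diabetes = diabetes,
    takes_antidiabetic = antidiab,
    hba1c = NA_real_,
    bmi = stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd),
    age = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
    sex = ifelse(stats::rbinom(n, 1, cfg$female_share) == 1,
                 "Female", "Male"),
    ancestry = sample(names(cfg$ancestry_probs), n, replace = TRUE,
                      prob = cfg$ancestry_probs),
    stringsAsFactors = FALSE
  )
}

#' Build the HbA1c model design matrix
#'
#' Constructs the model matrix used both to generate synthetic HbA1c and to
#' fit the association model, with the same preprocessing as
#' [fit_hba1c_model()]: NM as phenotype reference, largest ancestry group as
#' reference, constant covariates dropped.
#'
#' @param data Participant data.frame with phenotype and covariate columns.
#' @param genes Genes in scope.
#' @param interaction,include_diabetes Model structure switches.
#' @param covariates Covariate columns to include when present.
#' @return Numeric model matrix.
#' @export
hba1c_design <- function(data, genes = "CYP2D6", interaction = TRUE,
                         include_diabetes = TRUE,
                         covariates = c("takes_antidiabetic",
                                        "takes_cyp2d6_inhibitor",
                                        "takes_cyp2c19_inhibitor",
                                        "bmi", "age", "sex", "ancestry")) {
  pheno_cols <- paste0(tolower(genes), "_phenotype")
  inh_all <- c("takes_cyp2d6_inhibitor", "takes_cyp2c19_inhibitor")
  inh_keep <- paste0("takes_", tolower(genes), "_inhibitor")
  covariates <- setdiff(covariates, setdiff(inh_all, inh_keep))
  covariates <- intersect(covariates, names(data))
  df <- data
  for (pc in pheno_cols) {
    df[[pc]] <- stats::relevel(factor(as.character(df[[pc]])), ref = "NM")
  }
  if ("ancestry" %in% covariates) {
    a <- factor(as.character(df$ancestry))
    df$ancestry <- stats::relevel(a, ref = names(which.max(table(a))))
  }
  if ("sex" %in% covariates) df$sex <- factor(as.character(df$sex))
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(df[[cv]])) > 1L, logical(1))]
  rhs <- c(if (include_diabetes) "diabetes", pheno_cols,
           if (include_diabetes && interaction) paste0("diabetes:", pheno_cols),
           covariates)
  stats::model.matrix(stats::as.formula(paste("~", paste(rhs, collapse = " + "))),
                      data = df)
}

#' Simulate HbA1c from a linear model
#'
#' Generates `y = X beta + epsilon` with i.i.d. normal errors, then clips
#' to the HbA1c assay analytical range of 15–184 mmol/mol (clip events are
#' counted: clipping slightly biases extreme simulations and should be
#' rare under realistic settings).
#'
#' @param X Design matrix (e.g. from [hba1c_design()]).
#' @param coefficients Named coefficient vector. Every name must be a
#'   column of `X`; columns of `X` without a named coefficient default
#'   to 0.
#' @param residual_sd Residual standard deviation.
#' @param seed Optional integer seed.
#' @return List: `hba1c` (numeric vector), `n_clipped` (count),
#'   `linear_predictor`.
#' @export
simulate_hba1c <- function(X, coefficients, residual_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  extra <- setdiff(names(coefficients), colnames(X))
  if (length(extra)) {
    stop("coefficient name(s) not in design: ", paste(extra, collapse = ", "))
  }
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[names(coefficients)] <- coefficients
  lp <- as.vector(X %*% beta)
  y <- lp + stats::rnorm(nrow(X), 0, residual_sd)
  clipped <- y < 15 | y > 184
  y <- pmin(pmax(y, 15), 184)
  list(hba1c = y, n_clipped = sum(clipped), linear_predictor = lp)
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator: phased haplotypes per gene (Hardy–Weinberg draws
#' from star-allele frequencies), diplotype/phenotype truth, participant
#' table, inhibitor flags, and HbA1c from the configured linear model.
#'
#' @param cfg A [sim_config()].
#' @param tables Named list of `cyp_allele_table`s (default: bundled
#'   CYP2D6 + CYP2C19 fixtures).
#' @param knowledge A `drug_knowledge` (default: bundled fixtures).
#' @return List: `participants` (data.frame incl. phenotypes and HbA1c),
#'   `haplotypes` (per gene: `hapA`, `hapB`, `truth`), `truth`
#'   (per-sample generative diplotypes/phenotypes and linear predictor),
#'   `n_clipped`.
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            tables = list(
                              CYP2D6 = load_allele_definitions(cyp_fixture_path("CYP2D6")),
                              CYP2C19 = load_allele_definitions(cyp_fixture_path("CYP2C19"))),
                            knowledge = load_drug_knowledge()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_participants
  part <- simulate_participants(
    within_seed_null(cfg), knowledge = knowledge)
  haps <- list()
  for (g in names(tables)) {
    freqs <- cfg$allele_frequencies[[g]]
    if (is.null(freqs)) stop("no allele frequencies configured for ", g)
    haps[[g]] <- simulate_haplotypes(n, tables[[g]], freqs,
                                     sample_ids = part$sample_id)
    dip <- call_diplotypes(haps[[g]]$hapA, haps[[g]]$hapB, tables[[g]],
                           sample_ids = part$sample_id)
    dip <- assign_phenotypes(dip, tables[[g]])
    part[[paste0(tolower(g), "_diplotype")]] <- dip$diplotype
    part[[paste0(tolower(g), "_phenotype")]] <- dip$phenotype
  }
  part$medications <- strsplit(part$medications_raw, ";", fixed = TRUE)
  part$medications <- lapply(part$medications, function(m)
    normalize_medications(m[nzchar(m)], knowledge))
  part <- flag_inhibitors(part, knowledge)

  genes <- names(tables)
  X <- hba1c_design(part, genes = genes, interaction = TRUE)
  ## coefficients for covariate levels absent from this realisation (e.g. an
  ## ancestry group with no members) cannot enter the design; drop them
  beta <- cfg$coefficients[names(cfg$coefficients) %in% colnames(X)]
  sim <- simulate_hba1c(X, beta, cfg$residual_sd)
  part$hba1c <- sim$hba1c
  if (cfg$missing_hba1c_rate > 0) {
    part$hba1c[stats::runif(n) < cfg$missing_hba1c_rate] <- NA_real_
  }
  truth <- part[c("sample_id", grep("_diplotype$|_phenotype$", names(part),
                                    value = TRUE))]
  truth$linear_predictor <- sim$linear_predictor
  list(participants = part, haplotypes = haps, truth = truth,
       n_clipped = sim$n_clipped)
}

## internal: copy of cfg with seed removed, so nested generators do not
## reset the RNG stream mid-run
within_seed_null <- function(cfg) {
  cfg$seed <- NULL
  cfg
}
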