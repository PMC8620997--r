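d6 <- load_allele_definitions(cyp_fixture_path("CYP2D6"))
c19 <- load_allele_definitions(cyp_fixture_path("CYP2C19"))

test_that("the simulator is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 150, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$truth, s2$truth)
  # byte-identical VCF output
  f1 <- tempfile(); f2 <- tempfile()
  write_phased_vcf(s1$haplotypes$CYP2D6$hapA, s1$haplotypes$CYP2D6$hapB,
                   d6, f1)
  write_phased_vcf(s2$haplotypes$CYP2D6$hapA, s2$haplotypes$CYP2D6$hapB,
                   d6, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("degenerate and mismatched frequency inputs behave as specified", {
  set.seed(1)
  sim <- simulate_haplotypes(50, d6, c("*1" = 1.0))
  expect_true(all(sim$hapA == 0) && all(sim$hapB == 0))
  dip <- call_diplotypes(sim$hapA, sim$hapB, d6)
  expect_true(all(dip$diplotype == "*1/*1"))
  expect_error(simulate_haplotypes(10, d6, c("*1" = 0.5, "*99" = 0.5)),
               "absent")
  expect_error(simulate_haplotypes(10, d6, c("*1" = 0.6, "*4" = 0.1)),
               "sum to 1")
})

test_that("configured count of antidiabetic-without-diabetes rows is injected exactly", {
  cfg <- sim_config(n_participants = 500,
                    n_antidiabetic_without_diabetes = 49, seed = 4)
  part <- simulate_participants(cfg)
  expect_equal(sum(part$takes_antidiabetic & !part$diabetes), 49)
  # a zero-probability drug is never assigned
  cfg2 <- sim_config(n_participants = 300,
                     drug_probabilities = c(paroxetine = 0.5,
                                            venlafaxine = 0),
                     seed = 5)
  part2 <- simulate_participants(cfg2)
  expect_false(any(grepl("venlafaxine", part2$medications_raw)))
})

test_that("simulated HbA1c follows y = X beta + noise with assay-range clipping", {
  X <- cbind("(Intercept)" = rep(1, 2000))
  # noiseless intercept-only model reproduces the mean exactly
  y0 <- simulate_hba1c(X, c("(Intercept)" = 37.1), residual_sd = 1e-12)
  expect_equal(y0$hba1c, rep(37.1, 2000), tolerance = 1e-6)
  expect_equal(y0$n_clipped, 0)
  # law of total variance at scale
  set.seed(6)
  df <- make_cohort_data(20000, beta = c(diabetesTRUE = 6.85,
                                         cyp2d6_phenotypePM = 2.43))
  Xd <- hba1c_design(df, interaction = FALSE)
  beta <- setNames(numeric(ncol(Xd)), colnames(Xd))
  beta["(Intercept)"] <- 37; beta["diabetesTRUE"] <- 6.85; beta["bmi"] <- 0.3
  sim <- simulate_hba1c(Xd, beta, residual_sd = 4)
  expect_equal(var(sim$hba1c), var(sim$linear_predictor) + 16,
               tolerance = 0.05 * (var(sim$linear_predictor) + 16))
  # clipping triggers and is logged
  low <- simulate_hba1c(X, c("(Intercept)" = 10), residual_sd = 1)
  expect_true(all(low$hba1c >= 15))
  expect_gt(low$n_clipped, 0)
  # coefficient names must match the design
  expect_error(simulate_hba1c(X, c(nosuch = 1), 1), "not in design")
})

test_that("simulate -> write VCF -> read -> call round-trips diplotypes exactly", {
  set.seed(8)
  for (tab in list(d6, c19)) {
    sim <- simulate_haplotypes(300, tab)
    vcf <- tempfile(fileext = ".vcf")
    write_phased_vcf(sim$hapA, sim$hapB, tab, vcf)
    h <- read_phased_vcf(vcf, tab)
    dip <- call_diplotypes(h$hapA, h$hapB, tab)
    truth_dip <- paste(sim$truth$allele_a, sim$truth$allele_b, sep = "/")
    expect_identical(dip$diplotype, truth_dip)
  }
})

test_that("unphased genotypes and build mismatches are surfaced on read", {
  set.seed(9)
  sim <- simulate_haplotypes(5, d6)
  vcf <- tempfile(fileext = ".vcf")
  write_phased_vcf(sim$hapA, sim$hapB, d6, vcf)
  txt <- readLines(vcf)
  body <- length(txt)
  txt[body] <- gsub("|", "/", txt[body], fixed = TRUE)
  writeLines(txt, vcf)
  expect_error(read_phased_vcf(vcf, d6), "unphased")
  # build mismatch warns
  write_phased_vcf(sim$hapA, sim$hapB, d6, vcf)
  tab38 <- d6
  tab38$build <- "GRCh38"
  expect_warning(read_phased_vcf(vcf, tab38), "build")
})

test_that("simulated diplotype frequencies obey Hardy-Weinberg products", {
  set.seed(10)
  n <- 4000
  freqs <- default_allele_frequencies("CYP2D6")
  sim <- simulate_haplotypes(n, d6, freqs)
  dip <- call_diplotypes(sim$hapA, sim$hapB, d6)
  for (pair in list(c("*1", "*1"), c("*1", "*4"), c("*4", "*4"),
                    c("*1", "*41"))) {
    p <- freqs[[pair[1]]] * freqs[[pair[2]]]
    if (pair[1] != pair[2]) p <- 2 * p
    obs <- mean(dip$diplotype %in% paste(pair, collapse = "/"))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se + 1e-9)
  }
})

test_that("CYP2C19 frequencies tuned for a 4.2% UM share are recovered at biobank scale", {
  set.seed(12)
  n <- 31579
  freqs <- default_allele_frequencies("CYP2C19")
  # UM share is the squared increased-allele frequency; tune *17 for 4.2%
  f17 <- sqrt(0.042)
  scale <- (1 - f17) / (1 - freqs[["*17"]])
  freqs <- c(freqs[c("*1", "*2", "*3")] * scale, "*17" = f17)
  sim <- simulate_haplotypes(n, c19, freqs)
  dip <- assign_phenotypes(call_diplotypes(sim$hapA, sim$hapB, c19), c19)
  um <- mean(dip$phenotype == "UM")
  se <- sqrt(0.042 * 0.958 / n)
  expect_lt(abs(um - 0.042), 3 * se)
})

test_that("a full simulated cohort flags a true PM effect at the single-drug threshold", {
  # end-to-end identifiability: generate with the default effect sizes,
  # fit the association model, and check the PM verdict across seeds
  hits <- 0
  seeds <- 1:5
  for (s in seeds) {
    cfg <- sim_config(n_participants = 20000, seed = s)
    sim <- simulate_cohort(cfg)
    fit <- suppressWarnings(fit_hba1c_model(sim$participants,
                                            genes = "CYP2D6",
                                            interaction = FALSE))
    tab <- apply_thresholds(fit, family = "single_drug")
    if (tab$label[tab$term == "CYP2D6 PM"] == "significant") hits <- hits + 1
  }
  expect_gte(hits, 4)
})
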