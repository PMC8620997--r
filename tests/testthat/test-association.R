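test_that("null cohorts recover zero phenotype effects", {
  set.seed(21)
  df <- make_cohort_data(5000, beta = c(), residual_sd = 4)
  fit <- fit_hba1c_model(df, interaction = FALSE)
  tab <- fit$table
  for (term in c("CYP2D6 IM", "CYP2D6 PM")) {
    row <- tab[tab$term == term, ]
    expect_lt(abs(row$estimate), 3 * (row$conf.high - row$estimate) / 1.96)
  }
  expect_equal(fit$observations, 5000)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  # per-level n matches the data
  expect_equal(tab$n[tab$term == "CYP2D6 PM"],
               sum(df$cyp2d6_phenotype == "PM"))
})

test_that("doubling the residual noise doubles Wald CI widths exactly", {
  set.seed(22)
  df <- make_cohort_data(800)
  X <- hba1c_design(df, interaction = FALSE)
  eps <- rnorm(800)
  df$hba1c <- 37 + eps
  w1 <- {
    f <- fit_hba1c_model(df, interaction = FALSE)
    f$table$conf.high - f$table$conf.low
  }
  df$hba1c <- 37 + 2 * eps
  w2 <- {
    f <- fit_hba1c_model(df, interaction = FALSE)
    f$table$conf.high - f$table$conf.low
  }
  expect_equal(w2, 2 * w1, tolerance = 1e-10)
})

test_that("adding a constant to HbA1c shifts only the intercept", {
  set.seed(23)
  df <- make_cohort_data(600)
  f1 <- fit_hba1c_model(df, interaction = FALSE)
  df$hba1c <- df$hba1c + 10
  f2 <- fit_hba1c_model(df, interaction = FALSE)
  c1 <- coef(f1); c2 <- coef(f2)
  expect_equal(c2[["(Intercept)"]] - c1[["(Intercept)"]], 10,
               tolerance = 1e-8)
  expect_equal(c1[names(c1) != "(Intercept)"],
               c2[names(c2) != "(Intercept)"], tolerance = 1e-8)
})

test_that("stratification decision uses strict p < 0.05 on interaction terms", {
  fake <- function(p) structure(list(table = data.frame(
    term = c("Diabetes", "Diabetes: CYP2D6 PM"), p = c(0.001, p),
    stringsAsFactors = FALSE)), class = "hba1c_fit")
  expect_identical(test_interaction(fake(0.003)), "stratify")
  expect_identical(test_interaction(fake(0.5)), "pooled")
  expect_identical(test_interaction(fake(0.05)), "pooled")  # boundary
  no_ix <- structure(list(table = data.frame(term = "Diabetes", p = 0.01)),
                     class = "hba1c_fit")
  expect_error(test_interaction(no_ix), "interaction")
})

test_that("stratified fits drop diabetes terms and center on zero under the null", {
  set.seed(24)
  df <- make_cohort_data(3000, p_diab = 0.3)
  strata <- fit_stratified(df)
  for (f in strata) {
    expect_false(any(grepl("Diabetes", f$table$term)))
    for (term in c("CYP2D6 IM", "CYP2D6 PM")) {
      row <- f$table[f$table$term == term, ]
      expect_true(row$conf.low < 0 && row$conf.high > 0 ||
                    abs(row$estimate) < 1)
    }
  }
  expect_equal(strata$diabetes$observations +
                 strata$no_diabetes$observations, 3000)
})

test_that("nested thresholds label significance per analysis family", {
  tab <- data.frame(term = c("a", "b", "c", "d"),
                    p = c(7.77e-5, 0.0165, 0.018, 0.5),
                    stringsAsFactors = FALSE)
  single <- apply_thresholds(tab, family = "single_drug")
  expect_identical(single$label, c("significant", "suggestive", "ns", "ns"))
  expect_equal(unname(attr(single, "thresholds")),
               c(0.05 / 6, 0.1 / 6))
  grouped <- apply_thresholds(data.frame(term = "x", p = 0.03),
                              family = "grouped")
  expect_identical(grouped$label, "suggestive")
  expect_equal(unname(attr(grouped, "thresholds")), c(0.025, 0.05))
  expect_error(apply_thresholds(tab, family = "other"))
})

test_that("degenerate designs fail loudly", {
  set.seed(25)
  df <- make_cohort_data(300, p_diab = 0.2)
  # antidiabetic identical to diabetes -> aliased column
  df$takes_antidiabetic <- df$diabetes
  expect_error(fit_hba1c_model(df, interaction = FALSE), "collinear")
  # missing required column
  expect_error(fit_hba1c_model(df[setdiff(names(df), "hba1c")]),
               "missing required")
  # declared-but-empty phenotype level is dropped with a warning
  df2 <- make_cohort_data(300, p_pm = 0)
  df2$cyp2d6_phenotype <- factor(df2$cyp2d6_phenotype,
                                 levels = c("NM", "IM", "PM"))
  expect_warning(fit_hba1c_model(df2, interaction = FALSE), "empty")
  # stratum smaller than the parameter count names the stratum
  df3 <- make_cohort_data(60, p_diab = 0.05)
  expect_error(suppressWarnings(fit_stratified(df3)), "stratum")
})

test_that("model object methods delegate coherently", {
  set.seed(26)
  df <- make_cohort_data(500)
  fit <- fit_hba1c_model(df, interaction = FALSE, cohort_label = "toy")
  expect_output(print(fit), "toy")
  expect_s3_class(summary(fit), "summary.lm")
  expect_equal(length(residuals(fit)), 500)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_equal(nrow(simulate(fit, nsim = 2, seed = 1)), 500)
  expect_equal(unname(predict(fit)[1]),
               unname(predict(fit, newdata = df[1, ])[1]), tolerance = 1e-8)
})
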