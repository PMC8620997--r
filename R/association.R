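#' Fit the HbA1c metabolizer-phenotype linear model
#'
#' Ordinary-least-squares model of HbA1c (mmol/mol) on CYP metabolizer
#' phenotype with normal metabolizers (NM) as the reference level, diabetes
#' status, and their interaction, adjusted for antidiabetic treatment,
#' enzyme-inhibitor exposure, BMI, age, sex and ancestry group. For cohorts
#' modelled for both genes, both genes' phenotype indicators enter one model
#' (no gene-by-gene interaction). Wald 95% confidence intervals and
#' two-sided p-values are reported per term, together with per-level counts,
#' the number of observations and (adjusted) R-squared, in the layout of a
#' published association table.
#'
#' Phenotype levels with no members are dropped with a warning. Covariates
#' that are constant in the cohort are dropped from the design (and
#' recorded in the fit) rather than producing a rank-deficient model; any
#' remaining aliased coefficient is an error naming the collinear columns.
#' Missing values are handled by complete-case analysis within the cohort,
#' with the dropped count recorded.
#'
#' @param data Participant data.frame: `hba1c`, `diabetes` (logical),
#'   `<gene>_phenotype` factors/characters (e.g. `cyp2d6_phenotype`), plus
#'   the covariate columns.
#' @param genes Genes whose phenotypes enter the model
#'   (`"CYP2D6"`, `"CYP2C19"`, or both).
#' @param interaction Include phenotype-by-diabetes interaction terms?
#' @param include_diabetes Include the diabetes main effect (and hence allow
#'   interactions)? Stratified fits set this to `FALSE`.
#' @param covariates Covariate column names to adjust for; inhibitor flags
#'   are selected per gene automatically from
#'   `takes_cyp2d6_inhibitor`/`takes_cyp2c19_inhibitor` when present in
#'   this vector.
#' @param cohort_label Optional label carried to print output.
#' @param robust Use heteroskedasticity-robust (HC1) standard errors
#'   (requires the sandwich package)? Classical OLS by default.
#' @return Object of class `hba1c_fit`; see Details. Supports `print()`,
#'   `summary()`, `coef()`, `confint()`, `predict()`, `residuals()`,
#'   `simulate()` and `plot()`.
#' @details The returned object is a list: `fit` (the underlying `lm`),
#'   `table` (data.frame `term, n, estimate, conf.low, conf.high, p`),
#'   `observations`, `r2`, `adj_r2`, `genes`, `interaction`,
#'   `dropped_levels`, `dropped_constant`, `n_incomplete`, `cohort_label`.
#' @export
fit_hba1c_model <- function(data, genes = "CYP2D6", interaction = TRUE,
                            include_diabetes = TRUE,
                            covariates = c("takes_antidiabetic",
                                           "takes_cyp2d6_inhibitor",
                                           "takes_cyp2c19_inhibitor",
                                           "bmi", "age", "sex", "ancestry"),
                            cohort_label = NULL, robust = FALSE) {
  stopifnot(is.data.frame(data))
  if (!nrow(data)) stop("empty cohort")
  genes <- match.arg(genes, c("CYP2D6", "CYP2C19"), several.ok = TRUE)
  pheno_cols <- paste0(tolower(genes), "_phenotype")
  miss <- setdiff(c("hba1c", if (include_diabetes) "diabetes", pheno_cols),
                  names(data))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))

  ## per-gene inhibitor flags only for the genes in scope
  inh_all <- c("takes_cyp2d6_inhibitor", "takes_cyp2c19_inhibitor")
  inh_keep <- paste0("takes_", tolower(genes), "_inhibitor")
  covariates <- setdiff(covariates, setdiff(inh_all, inh_keep))
  covariates <- intersect(covariates, names(data))

  used <- c("hba1c", if (include_diabetes) "diabetes", pheno_cols, covariates)
  cc <- stats::complete.cases(data[used])
  n_incomplete <- sum(!cc)
  df <- data[cc, used, drop = FALSE]
  if (!nrow(df)) stop("no complete cases in cohort")

  dropped_levels <- character()
  for (pc in pheno_cols) {
    orig_lev <- if (is.factor(data[[pc]])) levels(data[[pc]]) else
      unique(as.character(data[[pc]]))
    f <- factor(as.character(df[[pc]]))
    empty <- setdiff(orig_lev, levels(f))
    lev <- levels(f)
    if (!"NM" %in% lev) stop("no normal metabolizers (reference level) in ", pc)
    f <- stats::relevel(f, ref = "NM")
    if (length(empty)) {
      warning("dropping empty phenotype level(s) in ", pc, ": ",
              paste(empty, collapse = ", "))
      dropped_levels <- c(dropped_levels, paste0(pc, ":", empty))
    }
    df[[pc]] <- f
  }
  if ("ancestry" %in% covariates) {
    a <- factor(as.character(df$ancestry))
    biggest <- names(which.max(table(a)))
    df$ancestry <- stats::relevel(a, ref = biggest)
  }
  if ("sex" %in% covariates) df$sex <- factor(as.character(df$sex))

  ## constant columns cannot be estimated; drop them instead of failing
  dropped_constant <- character()
  for (cv in covariates) {
    if (length(unique(df[[cv]])) < 2L) {
      dropped_constant <- c(dropped_constant, cv)
    }
  }
  covariates <- setdiff(covariates, dropped_constant)

  rhs <- c(if (include_diabetes) "diabetes", pheno_cols,
           if (include_diabetes && interaction)
             paste0("diabetes:", pheno_cols),
           covariates)
  form <- stats::as.formula(paste("hba1c ~", paste(rhs, collapse = " + ")))
  n_par <- length(rhs) + 1L
  if (nrow(df) <= n_par) {
    stop("cohort has fewer observations (", nrow(df),
         ") than model parameters")
  }
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }

  if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE) ||
        !requireNamespace("lmtest", quietly = TRUE)) {
      stop("robust = TRUE requires the sandwich and lmtest packages")
    }
    vc <- sandwich::vcovHC(fit, type = "HC1")
    ct <- lmtest::coeftest(fit, vcov. = vc)
    est <- ct[, 1]; se <- ct[, 2]; p <- ct[, 4]
    tcrit <- stats::qt(0.975, df = fit$df.residual)
    ci <- cbind(est - tcrit * se, est + tcrit * se)
  } else {
    sm <- stats::summary.lm(fit)
    est <- sm$coefficients[, 1]
    p <- sm$coefficients[, 4]
    ci <- stats::confint(fit)
  }

  tab <- data.frame(
    term = .pretty_terms(names(est)),
    n = .term_level_n(names(est), df),
    estimate = unname(est),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2]),
    p = unname(p),
    stringsAsFactors = FALSE
  )
  sm <- stats::summary.lm(fit)
  structure(list(
    fit = fit, table = tab,
    observations = nrow(df),
    r2 = unname(sm$r.squared), adj_r2 = unname(sm$adj.r.squared),
    genes = genes, interaction = interaction && include_diabetes,
    include_diabetes = include_diabetes,
    dropped_levels = dropped_levels, dropped_constant = dropped_constant,
    n_incomplete = n_incomplete, cohort_label = cohort_label,
    robust = robust
  ), class = "hba1c_fit")
}

.pretty_terms <- function(x) {
  x <- gsub("cyp2d6_phenotype", "CYP2D6 ", x, fixed = TRUE)
  x <- gsub("cyp2c19_phenotype", "CYP2C19 ", x, fixed = TRUE)
  x <- gsub("diabetesTRUE", "Diabetes", x, fixed = TRUE)
  x <- gsub("takes_antidiabeticTRUE", "Takes antidiabetic", x, fixed = TRUE)
  x <- gsub("takes_cyp2d6_inhibitorTRUE", "Takes CYP2D6 inhibitor", x,
            fixed = TRUE)
  x <- gsub("takes_cyp2c19_inhibitorTRUE", "Takes CYP2C19 inhibitor", x,
            fixed = TRUE)
  gsub(":", ": ", x, fixed = TRUE)
}

## per-level member counts for the table's n column
.term_level_n <- function(raw, df) {
  vapply(raw, function(tn) {
    if (tn == "(Intercept)") return(NA_integer_)
    parts <- strsplit(tn, ":", fixed = TRUE)[[1]]
    sel <- rep(TRUE, nrow(df))
    for (p in parts) {
      hit <- FALSE
      if (p == "diabetesTRUE") { sel <- sel & df$diabetes; hit <- TRUE }
      for (pc in grep("_phenotype$", names(df), value = TRUE)) {
        if (startsWith(p, pc)) {
          sel <- sel & df[[pc]] == sub(pc, "", p, fixed = TRUE)
          hit <- TRUE
        }
      }
      if (!hit && endsWith(p, "TRUE") &&
          sub("TRUE$", "", p) %in% names(df)) {
        sel <- sel & df[[sub("TRUE$", "", p)]]
        hit <- TRUE
      }
      if (!hit) return(NA_integer_)
    }
    sum(sel)
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.hba1c_fit <- function(x, digits = 3, ...) {
  cat("HbA1c metabolizer-phenotype model",
      if (!is.null(x$cohort_label)) paste0("(", x$cohort_label, ")"), "\n")
  cat("  genes:", paste(x$genes, collapse = " + "),
      if (x$interaction) " [phenotype x diabetes interaction]", "\n", sep = "")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$CI <- sprintf("%.*f, %.*f", digits - 1, x$table$conf.low,
                    digits - 1, x$table$conf.high)
  tab$p <- format.pval(x$table$p, digits = digits, eps = 1e-16)
  print(tab[c("term", "n", "estimate", "CI", "p")], row.names = FALSE)
  cat(sprintf("Observations: %d   R2/R2 adjusted: %.3f/%.3f\n",
              x$observations, x$r2, x$adj_r2))
  if (x$n_incomplete) cat("  (", x$n_incomplete,
                          "incomplete records dropped )\n")
  invisible(x)
}

#' @export
summary.hba1c_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.hba1c_fit <- function(object, pretty = TRUE, ...) {
  cf <- stats::coef(object$fit)
  if (pretty) names(cf) <- .pretty_terms(names(cf))
  cf
}

#' @export
confint.hba1c_fit <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$fit, level = level, ...)
  rownames(ci) <- .pretty_terms(rownames(ci))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.hba1c_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.hba1c_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
simulate.hba1c_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Violin plot of HbA1c by metabolizer phenotype
#'
#' Kernel-density "violin" of the modelled HbA1c values per phenotype level
#' of the first gene in the fit, drawn with base graphics.
#'
#' @param x An `hba1c_fit`.
#' @param gene Gene to display (default: first in the fit).
#' @param col Fill colour.
#' @param ... Passed to `plot.default` for the frame.
#' @export
plot.hba1c_fit <- function(x, gene = x$genes[1], col = "grey80", ...) {
  df <- x$fit$model
  pc <- paste0(tolower(gene), "_phenotype")
  ph <- df[[pc]]
  y <- df$hba1c
  lev <- levels(ph)
  plot(NA, xlim = c(0.5, length(lev) + 0.5), ylim = range(y),
       xaxt = "n", xlab = paste(gene, "metabolic phenotype"),
       ylab = "HbA1c (mmol/mol)", ...)
  graphics::axis(1, at = seq_along(lev), labels = lev)
  for (i in seq_along(lev)) {
    yy <- y[ph == lev[i]]
    if (length(yy) < 2) next
    d <- stats::density(yy)
    w <- 0.4 * d$y / max(d$y)
    graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                      col = col, border = "grey40")
    graphics::segments(i - 0.1, stats::median(yy), i + 0.1,
                       stats::median(yy), lwd = 2)
  }
  invisible(x)
}

#' Decide whether to stratify on diabetes status
#'
#' Inspects the phenotype-by-diabetes interaction terms of a pooled fit and
#' returns `"stratify"` when any interaction p-value is below `alpha`
#' (strict inequality; default 0.05), else `"pooled"`.
#'
#' @param fit An `hba1c_fit` with interaction terms.
#' @param alpha Decision threshold.
#' @return `"stratify"` or `"pooled"`.
#' @export
test_interaction <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "hba1c_fit"))
  ix <- grepl("^Diabetes: ", fit$table$term)
  if (!any(ix)) stop("model contains no phenotype-by-diabetes interaction terms")
  if (any(fit$table$p[ix] < alpha)) "stratify" else "pooled"
}

#' Fit diabetes-stratified models
#'
#' Refits the phenotype model separately in participants with and without
#' diabetes, dropping the diabetes main effect and interactions (constant
#' within stratum). Used after [test_interaction()] indicates effect
#' modification.
#'
#' @param data Cohort data.frame (as for [fit_hba1c_model()]) including a
#'   logical `diabetes` column.
#' @param genes,covariates,cohort_label,robust As in [fit_hba1c_model()].
#' @return List of class `hba1c_fit_strata` with elements `diabetes` and
#'   `no_diabetes`, each an `hba1c_fit`.
#' @export
fit_stratified <- function(data, genes = "CYP2D6",
                           covariates = c("takes_antidiabetic",
                                          "takes_cyp2d6_inhibitor",
                                          "takes_cyp2c19_inhibitor",
                                          "bmi", "age", "sex", "ancestry"),
                           cohort_label = NULL, robust = FALSE) {
  out <- list()
  for (st in c("diabetes", "no_diabetes")) {
    sub <- data[if (st == "diabetes") data$diabetes else !data$diabetes, ,
                drop = FALSE]
    if (!nrow(sub)) stop("empty stratum: ", st)
    out[[st]] <- tryCatch(
      fit_hba1c_model(sub, genes = genes, interaction = FALSE,
                      include_diabetes = FALSE, covariates = covariates,
                      cohort_label = paste0(cohort_label,
                                            if (!is.null(cohort_label)) " / ",
                                            st),
                      robust = robust),
      error = function(e) stop("stratum '", st, "': ", conditionMessage(e),
                               call. = FALSE))
  }
  class(out) <- "hba1c_fit_strata"
  out
}

#' @export
print.hba1c_fit_strata <- function(x, ...) {
  cat("== Diabetes stratum ==\n"); print(x$diabetes, ...)
  cat("== No-diabetes stratum ==\n"); print(x$no_diabetes, ...)
  invisible(x)
}

#' Nested multiple-testing significance thresholds
#'
#' The analysis families are nested (single-drug cohorts overlap the grouped
#' cohorts), so a global Bonferroni correction would be too stringent.
#' Instead each family carries its own adjusted thresholds: the two grouped
#' analyses use significant p < 0.05/2 = 0.025 and suggestive p < 0.1/2 =
#' 0.05; the six single-drug analyses use significant p < 0.05/6 and
#' suggestive p < 0.1/6 (exact fractions; the conventional rounded values
#' 0.0083 and 0.017 lie within them). Raw p-values are always reported
#' alongside the verdicts.
#'
#' @param x An `hba1c_fit` or a data.frame with `term` and `p` columns.
#' @param family `"single_drug"` or `"grouped"`.
#' @return The coefficient table with logical `significant` and
#'   `suggestive` columns and a `label` column
#'   (`"significant"`, `"suggestive"`, `"ns"`), plus a `"thresholds"`
#'   attribute.
#' @export
#' @examples
#' apply_thresholds(data.frame(term = "CYP2D6 PM", p = 7.77e-5),
#'                  family = "single_drug")
apply_thresholds <- function(x, family = c("single_drug", "grouped")) {
  family <- match.arg(family)
  tab <- if (inherits(x, "hba1c_fit")) x$table else x
  stopifnot(is.data.frame(tab), all(c("term", "p") %in% names(tab)))
  th <- switch(family,
               single_drug = c(significant = 0.05 / 6, suggestive = 0.1 / 6),
               grouped = c(significant = 0.05 / 2, suggestive = 0.1 / 2))
  tab$significant <- tab$p < th[["significant"]]
  tab$suggestive <- tab$p < th[["suggestive"]]
  tab$label <- ifelse(tab$significant, "significant",
                      ifelse(tab$suggestive, "suggestive", "ns"))
  attr(tab, "thresholds") <- th
  tab
}
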