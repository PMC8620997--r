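#' Post-imputation QC thresholds
#'
#' Bundles the variant- and sample-level quality-control thresholds used
#' throughout the pipeline. Defaults follow standard biobank post-imputation
#' practice: common variants are kept at minor allele frequency >= 1% and
#' imputation information score >= 0.3; rare star-allele-defining imputed
#' variants are rescued at the stricter information threshold of 0.6; samples
#' are dropped above 10% genotype missingness; and one member of every pair
#' with kinship > 0.083 (third-degree relatives) is removed.
#'
#' @param maf_min Minimum minor allele frequency for the common-variant rule.
#' @param info_min Minimum imputation information score (common rule).
#' @param rare_rescue_info_min Information threshold for rescuing rare
#'   star-allele-defining imputed variants; must be >= `info_min`.
#' @param sample_missingness_max Maximum per-sample genotype missingness.
#' @param kinship_max Maximum tolerated pairwise kinship coefficient.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, info_min = 0.3,
                          rare_rescue_info_min = 0.6,
                          sample_missingness_max = 0.10,
                          kinship_max = 0.083) {
  vals <- c(maf_min = maf_min, info_min = info_min,
            rare_rescue_info_min = rare_rescue_info_min,
            sample_missingness_max = sample_missingness_max,
            kinship_max = kinship_max)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  if (rare_rescue_info_min < info_min) {
    stop("rare_rescue_info_min must be >= info_min")
  }
  structure(as.list(vals), class = "qc_thresholds")
}

#' Filter variants by the common-variant QC rule
#'
#' Applies the post-imputation filter: a variant is retained iff its minor
#' allele frequency and information score both meet the common thresholds.
#' Star-allele-defining variants that fail the common rule are not discarded
#' outright but routed to [rescue_rare_variants()], since the variants that
#' define impaired-function star alleles are typically rare and would
#' otherwise all be lost. Every excluded variant gets exactly one primary
#' reason (`maf` is checked before `info`).
#'
#' @param variants data.frame with columns `id`, `maf`, `info_score`,
#'   `genotyped` (logical), `is_star_defining` (logical). Optional
#'   `cluster_review_pass` (logical) is carried through for rescue.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `retained` (data.frame), `rescue_candidates`
#'   (data.frame of star-defining failures), and `log` (data.frame
#'   `id, reason` for non-rescuable exclusions).
#' @export
filter_variants <- function(variants, thresholds = qc_thresholds()) {
  stopifnot(all(c("id", "maf", "info_score", "genotyped",
                  "is_star_defining") %in% names(variants)))
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE)) {
    stop("minor allele frequencies must lie in [0, 0.5]")
  }
  pass_maf <- variants$maf >= thresholds$maf_min
  pass_info <- variants$info_score >= thresholds$info_min
  keep <- pass_maf & pass_info
  fail <- !keep
  to_rescue <- fail & variants$is_star_defining
  reason <- ifelse(!pass_maf, "maf", "info")
  list(
    retained = variants[keep, , drop = FALSE],
    rescue_candidates = variants[to_rescue, , drop = FALSE],
    log = data.frame(id = variants$id[fail & !to_rescue],
                     reason = reason[fail & !to_rescue],
                     stringsAsFactors = FALSE)
  )
}

#' Rescue rare star-allele-defining variants
#'
#' Rare star-allele-defining variants failing the common QC rule are given a
#' second chance: imputed candidates are kept when their information score
#' meets the stricter rescue threshold (default 0.6); directly genotyped
#' candidates are kept when they passed an upstream intensity-cluster review
#' (supplied as the boolean `cluster_review_pass`; the visual review itself
#' happens outside this package).
#'
#' @param candidates data.frame of star-defining variants that failed the
#'   common rule (as produced by [filter_variants()]); genotyped rows need a
#'   `cluster_review_pass` column.
#' @param thresholds A [qc_thresholds()] object.
#' @return data.frame of rescued variants.
#' @export
rescue_rare_variants <- function(candidates, thresholds = qc_thresholds()) {
  if (!nrow(candidates)) return(candidates)
  if (!all(candidates$is_star_defining)) {
    stop("rescue candidates must all be star-allele-defining variants")
  }
  imputed_ok <- !candidates$genotyped &
    candidates$info_score >= thresholds$rare_rescue_info_min
  geno_ok <- candidates$genotyped &
    if ("cluster_review_pass" %in% names(candidates)) {
      candidates$cluster_review_pass %in% TRUE
    } else FALSE
  candidates[imputed_ok | geno_ok, , drop = FALSE]
}

#' Exclude samples on missingness, sex mismatch, relatedness and kinship
#'
#' Applies the sample-level exclusions in a fixed order of primary reasons:
#' genotype missingness, reported-vs-genetic sex mismatch, excess relatedness
#' (a precomputed flag for individuals with many third-degree relatives),
#' then pairwise kinship pruning. Kinship pruning removes, greedily, the
#' sample involved in the most remaining over-threshold pairs (ties broken
#' by sample id) until no pair exceeds the threshold — the standard
#' max-retention strategy when a study states only that "one of each pair"
#' was dropped.
#'
#' @param samples data.frame with columns `sample_id`, `missingness`,
#'   `sex_mismatch` (logical), `excess_relatedness` (logical).
#' @param kin_pairs data.frame with columns `id1`, `id2`, `kinship`
#'   (may be empty/NULL).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `kept` (character vector of sample ids) and `removed`
#'   (data.frame `sample_id, reason`).
#' @export
exclude_samples <- function(samples, kin_pairs = NULL,
                            thresholds = qc_thresholds()) {
  stopifnot(all(c("sample_id", "missingness", "sex_mismatch",
                  "excess_relatedness") %in% names(samples)))
  if (any(samples$missingness < 0 | samples$missingness > 1)) {
    stop("missingness must lie in [0, 1]")
  }
  removed <- data.frame(sample_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop1 <- samples$missingness > thresholds$sample_missingness_max
  drop2 <- !drop1 & samples$sex_mismatch
  drop3 <- !drop1 & !drop2 & samples$excess_relatedness
  ids1 <- samples$sample_id[drop1]
  ids2 <- samples$sample_id[drop2]
  ids3 <- samples$sample_id[drop3]
  removed <- rbind(
    removed,
    data.frame(sample_id = c(ids1, ids2, ids3),
               reason = c(rep("missingness", length(ids1)),
                          rep("sex_mismatch", length(ids2)),
                          rep("excess_relatedness", length(ids3))),
               stringsAsFactors = FALSE)
  )
  kept <- setdiff(samples$sample_id, removed$sample_id)

  if (!is.null(kin_pairs) && nrow(kin_pairs)) {
    if (any(kin_pairs$kinship < 0 | kin_pairs$kinship > 0.5)) {
      stop("kinship coefficients must lie in [0, 0.5]")
    }
    unknown <- setdiff(c(kin_pairs$id1, kin_pairs$id2), samples$sample_id)
    if (length(unknown)) {
      stop("kinship pairs reference unknown sample id(s): ",
           paste(unique(unknown), collapse = ", "))
    }
    kp <- kin_pairs[kin_pairs$kinship > thresholds$kinship_max &
                      kin_pairs$id1 %in% kept & kin_pairs$id2 %in% kept, ,
                    drop = FALSE]
    while (nrow(kp)) {
      deg <- table(c(kp$id1, kp$id2))
      worst <- names(deg)[deg == max(deg)]
      victim <- sort(worst)[1]
      removed <- rbind(removed, data.frame(sample_id = victim,
                                           reason = "kinship",
                                           stringsAsFactors = FALSE))
      kept <- setdiff(kept, victim)
      kp <- kp[kp$id1 != victim & kp$id2 != victim, , drop = FALSE]
    }
  }
  list(kept = kept, removed = removed)
}
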