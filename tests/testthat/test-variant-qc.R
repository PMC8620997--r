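make_variants <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    id = paste0("v", seq_len(n)),
    maf = runif(n, 0, 0.5),
    info_score = runif(n),
    genotyped = runif(n) < 0.3,
    is_star_defining = runif(n) < 0.2,
    cluster_review_pass = runif(n) < 0.5,
    stringsAsFactors = FALSE)
}

test_that("common-variant rule retains and excludes with one reason each", {
  v <- data.frame(
    id = c("a", "b", "c"),
    maf = c(0.005, 0.30, 0.20),
    info_score = c(0.9, 0.95, 0.1),
    genotyped = FALSE, is_star_defining = FALSE,
    stringsAsFactors = FALSE)
  out <- filter_variants(v, qc_thresholds())
  expect_identical(out$retained$id, "b")
  expect_identical(out$log$reason[out$log$id == "a"], "maf")
  expect_identical(out$log$reason[out$log$id == "c"], "info")
})

test_that("per-variant rule application partitions the input and ignores order", {
  v <- make_variants(100)
  out <- filter_variants(v)
  expect_equal(nrow(out$retained) + nrow(out$rescue_candidates) +
                 nrow(out$log), 100)
  # brute-force oracle per variant
  keep <- v$maf >= 0.01 & v$info_score >= 0.3
  expect_setequal(out$retained$id, v$id[keep])
  expect_setequal(out$rescue_candidates$id, v$id[!keep & v$is_star_defining])
  # order invariance
  out2 <- filter_variants(v[sample(nrow(v)), ])
  expect_setequal(out2$retained$id, out$retained$id)
})

test_that("raising thresholds never grows the retained set", {
  v <- make_variants(200, seed = 3)
  base <- filter_variants(v, qc_thresholds())$retained$id
  for (t in list(qc_thresholds(maf_min = 0.05),
                 qc_thresholds(info_min = 0.6, rare_rescue_info_min = 0.6),
                 qc_thresholds(maf_min = 0.1, info_min = 0.8,
                               rare_rescue_info_min = 0.8))) {
    expect_true(all(filter_variants(v, t)$retained$id %in% base))
  }
})

test_that("rare-variant rescue applies the stricter info threshold and review flag", {
  cand <- data.frame(
    id = c("r1", "r2", "r3", "r4"),
    maf = 0.002,
    info_score = c(0.65, 0.55, 0.2, 0.9),
    genotyped = c(FALSE, FALSE, TRUE, TRUE),
    is_star_defining = TRUE,
    cluster_review_pass = c(NA, NA, FALSE, TRUE),
    stringsAsFactors = FALSE)
  out <- rescue_rare_variants(cand, qc_thresholds())
  expect_setequal(out$id, c("r1", "r4"))
  cand$is_star_defining[1] <- FALSE
  expect_error(rescue_rare_variants(cand), "star-allele-defining")
})

test_that("sample exclusions apply reasons in the documented order", {
  s <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    missingness = c(0.12, 0.01, 0.01, 0.01),
    sex_mismatch = c(TRUE, TRUE, FALSE, FALSE),
    excess_relatedness = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  out <- exclude_samples(s)
  rs <- setNames(out$removed$reason, out$removed$sample_id)
  expect_identical(unname(rs["a"]), "missingness")  # beats sex mismatch
  expect_identical(unname(rs["b"]), "sex_mismatch")
  expect_identical(unname(rs["c"]), "excess_relatedness")
  expect_identical(out$kept, "d")
  expect_equal(nrow(out$removed), 3)
})

test_that("one of each over-threshold kinship pair is removed; chains prune greedily", {
  s <- data.frame(sample_id = c("A", "B", "C"), missingness = 0,
                  sex_mismatch = FALSE, excess_relatedness = FALSE,
                  stringsAsFactors = FALSE)
  # single pair above threshold
  out <- exclude_samples(s[1:2, ], data.frame(id1 = "A", id2 = "B",
                                              kinship = 0.09))
  expect_equal(length(out$kept), 1)
  # chain A-B, B-C: removing B (highest degree) keeps A and C;
  # brute force over removal orders confirms 2 is the max retained
  out2 <- exclude_samples(s, data.frame(id1 = c("A", "B"),
                                        id2 = c("B", "C"),
                                        kinship = c(0.1, 0.1)))
  expect_setequal(out2$kept, c("A", "C"))
  # below-threshold pair untouched
  out3 <- exclude_samples(s, data.frame(id1 = "A", id2 = "B",
                                        kinship = 0.08))
  expect_setequal(out3$kept, c("A", "B", "C"))
  # unknown id is an input error
  expect_error(exclude_samples(s, data.frame(id1 = "A", id2 = "Z",
                                             kinship = 0.2)), "unknown")
})

test_that("no over-threshold pair survives pruning on random kinship graphs", {
  set.seed(11)
  for (k in 1:10) {
    n <- 30
    s <- data.frame(sample_id = sprintf("s%02d", 1:n), missingness = 0,
                    sex_mismatch = FALSE, excess_relatedness = FALSE,
                    stringsAsFactors = FALSE)
    m <- 40
    kp <- data.frame(id1 = sample(s$sample_id, m, TRUE),
                     id2 = sample(s$sample_id, m, TRUE),
                     kinship = runif(m, 0, 0.3), stringsAsFactors = FALSE)
    kp <- kp[kp$id1 != kp$id2, ]
    out <- exclude_samples(s, kp)
    resid <- kp[kp$id1 %in% out$kept & kp$id2 %in% out$kept, ]
    expect_true(all(resid$kinship <= 0.083))
    expect_equal(sort(c(out$kept, out$removed$sample_id)), sort(s$sample_id))
  }
})
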