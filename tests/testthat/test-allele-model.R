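test_that("a minimal legal table loads and invalid tables are rejected", {
  tab <- make_allele_table(list(
    list(allele = "*1", fun = "normal", act = 1),
    list(allele = "*4", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 0)))
  expect_s3_class(tab, "cyp_allele_table")
  expect_equal(nrow(tab$alleles), 2)

  # same variant listed twice for one allele
  expect_error(make_allele_table(list(
    list(allele = "*1", fun = "normal", act = 1),
    list(allele = "*4", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 0),
    list(allele = "*4", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 0))), "duplicate")

  # no *1 row
  expect_error(make_allele_table(list(
    list(allele = "*4", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 0))), "\\*1")

  # variant outside the declared extraction region
  expect_error(make_allele_table(list(
    list(allele = "*1", fun = "normal", act = 1),
    list(allele = "*4", rsid = "v1", chrom = "22", pos = 99, ref = "G",
         alt = "A", fun = "none", act = 0)),
    region = c(100, 1e6)), "outside")

  # activity inconsistent with function class
  expect_error(make_allele_table(list(
    list(allele = "*1", fun = "normal", act = 1),
    list(allele = "*4", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 1))), "inconsistent")
})

test_that("bundled CYP2C19 panel carries the expected function classes", {
  tab <- load_allele_definitions(cyp_fixture_path("CYP2C19"))
  fun <- setNames(tab$alleles$function_class, tab$alleles$name)
  expect_identical(unname(fun[c("*2", "*3", "*17")]),
                   c("none", "none", "increased"))
  expect_identical(unname(fun["*1"]), "normal")
})

test_that("haplotype matching agrees with a brute-force oracle on all toy haplotypes", {
  for (tab in list(toy_table(), toy_table_superset())) {
    sites <- tab$sites$id
    grids <- expand.grid(rep(list(0:1), length(sites)))
    for (i in seq_len(nrow(grids))) {
      hap <- setNames(as.integer(grids[i, ]), sites)
      call <- match_haplotype(hap, tab)
      expect_identical(call$allele_name, oracle_match(hap, tab))
      # partition: *1 iff no non-*1 allele fully matches
      expect_identical(call$is_default_wildtype, call$allele_name == "*1")
    }
  }
})

test_that("the real *10/*4 subset relation resolves to the most specific allele", {
  tab <- load_allele_definitions(cyp_fixture_path("CYP2D6"))
  hap <- setNames(rep(0L, nrow(tab$sites)), tab$sites$id)
  hap["rs1065852"] <- 1L
  expect_identical(match_haplotype(hap, tab)$allele_name, "*10")
  hap["rs3892097"] <- 1L
  call <- match_haplotype(hap, tab)
  expect_identical(call$allele_name, "*4")
  expect_equal(call$matched_variants, 2)
})

test_that("matching is invariant to definition-table row order", {
  base_rows <- list(
    list(allele = "*1", fun = "normal", act = 1),
    list(allele = "*A", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "none", act = 0),
    list(allele = "*B", rsid = "v1", chrom = "22", pos = 100, ref = "G",
         alt = "A", fun = "decreased", act = 0.5),
    list(allele = "*C", rsid = "v3", chrom = "22", pos = 300, ref = "C",
         alt = "T", fun = "decreased", act = 0.5))
  ref_tab <- make_allele_table(base_rows)
  sites <- ref_tab$sites$id
  grids <- expand.grid(rep(list(0:1), length(sites)))
  set.seed(42)
  for (k in 1:5) {
    tab_p <- make_allele_table(sample(base_rows))
    for (i in seq_len(nrow(grids))) {
      hap <- setNames(as.integer(grids[i, ]), sites)
      expect_identical(match_haplotype(hap, tab_p)$allele_name,
                       match_haplotype(hap, ref_tab)$allele_name)
    }
  }
})

test_that("ties among equally specific matches go to the lower-activity allele", {
  # *A (none) and *B (decreased) share the same single defining variant
  tab <- toy_table()
  hap <- setNames(c(1L, 0L), tab$sites$id)
  call <- match_haplotype(hap, tab)
  expect_identical(call$allele_name, "*A")
  expect_true(call$tie)
})

test_that("missing genotypes cannot support a match and are counted", {
  tab <- toy_table_superset()
  hap <- setNames(c(1L, NA), tab$sites$id)   # v1 alt, v2 unknown
  call <- match_haplotype(hap, tab)
  expect_identical(call$allele_name, "*A")   # *B2a/*A tie -> none wins... *A
  expect_equal(call$missing_defining_sites, 1)
  hap_all_na <- setNames(c(NA, NA), tab$sites$id)
  call2 <- match_haplotype(hap_all_na, tab)
  expect_identical(call2$allele_name, "*1")
  expect_true(call2$is_default_wildtype)
})

test_that("adding alternate alleles never decreases matched_variants", {
  tab <- toy_table_superset()
  sites <- tab$sites$id
  set.seed(7)
  for (k in 1:50) {
    hap <- setNames(rbinom(length(sites), 1, 0.5), sites)
    m0 <- match_haplotype(hap, tab)$matched_variants
    zero <- which(hap == 0)
    if (!length(zero)) next
    hap[sample(zero, 1)] <- 1L
    expect_gte(match_haplotype(hap, tab)$matched_variants, m0)
  }
})

test_that("activity score is additive, symmetric, and rejects unknown alleles", {
  tab <- load_allele_definitions(cyp_fixture_path("CYP2D6"))
  expect_equal(activity_score("*1", "*1", tab), 2)
  expect_equal(activity_score("*4", "*4", tab), 0)
  expect_equal(activity_score("*1", "*4", tab), 1)
  expect_equal(activity_score("*41", "*1", tab), 1.5)
  # symmetry over all pairs
  for (a in tab$alleles$name) for (b in tab$alleles$name) {
    expect_equal(activity_score(a, b, tab), activity_score(b, a, tab))
  }
  expect_error(activity_score("*1", "*99", tab), "unknown")
})
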