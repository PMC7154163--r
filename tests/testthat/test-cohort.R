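toy_cohort <- function() {
  as_cohort(
    tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1),
                   sex = c(0, 1, 1), age = c(40.5, 55, 61),
                   snp1 = c(0, 1, 2)),
    kinds = c(sex = "binary", age = "continuous", snp1 = "genotype012"))
}

test_that("cohort validation enforces types, outcomes and kinds", {
  co <- toy_cohort()
  expect_s3_class(co, "cure_cohort")
  expect_equal(unname(cohort_kinds(co)),
               c("binary", "continuous", "genotype012"))

  base <- tibble::tibble(time = c(1, 2), event = c(1, 0), g = c(0, 3))
  expect_error(as_cohort(base, kinds = c(g = "genotype012")),
               "'g'.*\\{0, 1, 2\\}")
  expect_error(as_cohort(tibble::tibble(time = c(1, -2), event = c(1, 0))),
               "nonnegative")
  expect_error(as_cohort(tibble::tibble(time = c(1, 2), event = c(1, 2))),
               "0/1")
  expect_error(as_cohort(base, kinds = c(g = "weird")), "unknown kind")
  # kind inference: 0/1 -> binary, character -> categorical, rest continuous
  co2 <- as_cohort(tibble::tibble(time = 1, event = 1, a = 0, b = "x",
                                  c = 1.7))
  expect_equal(unname(cohort_kinds(co2)),
               c("binary", "categorical", "continuous"))
})

test_that("cohort files round-trip through CSV plus schema sidecar", {
  co <- toy_cohort()
  csv <- withr::local_tempfile(fileext = ".csv")
  schema <- withr::local_tempfile(fileext = ".schema")
  write_cohort(co, csv, schema)
  back <- read_cohort(csv, schema)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(co))
  expect_equal(cohort_kinds(back), cohort_kinds(co))
})

test_that("imputation follows the mean / most-common-class rules", {
  co <- as_cohort(
    tibble::tibble(time = 1:4, event = c(1, 0, 1, 1),
                   x = c(1, 2, NA, NA), b = c(0, 0, 1, NA),
                   s = c(0, NA, 0, 2)),
    kinds = c(x = "continuous", b = "binary", s = "genotype012"))
  imp <- impute_missing(co)
  expect_equal(imp$x, c(1, 2, 1.5, 1.5))
  expect_equal(imp$b, c(0, 0, 1, 0))    # mode 0
  expect_equal(imp$s, c(0, 0, 0, 2))    # mode 0
  expect_equal(attr(imp, "imputation_report"), c(x = 2L, b = 1L, s = 1L))
  # tie goes to the lowest class
  co2 <- as_cohort(tibble::tibble(time = 1:3, event = c(1, 1, 0),
                                  b = c(0, 1, NA)), kinds = c(b = "binary"))
  expect_equal(impute_missing(co2)$b[3], 0)
  # idempotence and no-op on complete data
  expect_equal(tibble::as_tibble(impute_missing(imp)),
               tibble::as_tibble(imp), ignore_attr = TRUE)
  expect_error(impute_missing(as_cohort(
    tibble::tibble(time = 1:2, event = c(1, 0), z = c(NA_real_, NA)),
    kinds = c(z = "continuous"))), "entirely missing")
})

test_that("MAF filter uses folded allele frequencies", {
  n0 <- 50; n1 <- 40; n2 <- 10   # allele freq 0.3
  co <- as_cohort(
    tibble::tibble(time = 1:100, event = rep(c(1, 0), 50),
                   keep = c(rep(0, n0), rep(1, n1), rep(2, n2)),
                   mono = rep(0, 100),
                   rare = c(rep(0, 95), rep(1, 5)),
                   flip = c(rep(2, 60), rep(1, 30), rep(0, 10))),
    kinds = c(keep = "genotype012", mono = "genotype012",
              rare = "genotype012", flip = "genotype012"))
  out <- maf_filter(co, threshold = 0.25)
  # 0.3 > 0.25 kept; monomorphic and rare dropped; folded 1 - 0.75 = 0.25
  # is not strictly greater than the threshold, so dropped too
  expect_equal(setdiff(names(cohort_kinds(co)), names(cohort_kinds(out))),
               c("mono", "rare", "flip"))
  expect_equal(attr(out, "maf_dropped"), 3)
  expect_equal(attr(maf_filter(co, threshold = 0), "maf_dropped"), 1)
})

test_that("treatment encoding maps drugs to groups and dummies", {
  labs <- c("Etanercept", "Rituximab", "Tocilizumab", "Etanercept")
  enc <- encode_treatment(labs)
  expect_equal(enc$immunogenicity, c(1, 3, 2, 1))
  expect_equal(sum(startsWith(names(enc), "drug_")), 3)
  expect_equal(enc$drug_Etanercept, c(1, 0, 0, 1))
  expect_error(encode_treatment(c("Etanercept", "Aspirin")), "Aspirin")
  # full map: 8 drugs -> 8 dummies + 1 ordered column
  all8 <- names(drug_immunogenicity_groups())
  expect_equal(ncol(encode_treatment(all8)), 9)
})

test_that("config files round-trip flat key-value sets", {
  path <- withr::local_tempfile()
  write_config(list(alpha = 0.5, mode = "subspace", n = 100L), path)
  back <- read_config(path)
  expect_equal(back$alpha, 0.5)
  expect_equal(back$mode, "subspace")
  expect_equal(back$n, 100)
})
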