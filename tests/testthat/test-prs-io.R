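test_that("weight files parse with metadata and either separator", {
  for (sep in c("\t", ",")) {
    fx <- make_weight_file(n = 313, sep = sep, name = "PRS313TEST")
    w <- suppressMessages(parse_weights(fx$path))
    expect_s3_class(w, "prs_weights")
    expect_equal(nrow(w$variants), 313)
    expect_equal(w$name, "PRS313TEST")
    expect_setequal(w$variants$variant, fx$variants$variant)
  }
})

test_that("malformed weight files are rejected with located messages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#name=EMPTY", path)
  expect_error(parse_weights(path), "no data rows")
  writeLines(c("variant\teffect_allele\tweight",
               "1_100_A_G\tG\t0.1",
               "1_100_A_G\tG\t0.2"), path)
  expect_error(parse_weights(path), "1_100_A_G")
  writeLines(c("variant\teffect_allele\tweight",
               "1_100_A_G\tT\t0.1"), path)
  expect_error(parse_weights(path), "neither allele")
  writeLines(c("variant\teffect_allele\tweight",
               "1_100_A_G\tG\tnotanumber"), path)
  expect_error(parse_weights(path), "unparseable weight")
  expect_error(parse_weights("/nonexistent/weights.tsv"), "not found")
})

test_that("CHEK2-linked exclusion removes exactly the tagged pair", {
  fx <- make_weight_file(n = 313)
  w <- suppressMessages(parse_weights(fx$path))
  w311 <- suppressMessages(exclude_variants(w))
  expect_equal(nrow(w311$variants), 311)
  expect_false(any(chek2_linked_variants() %in% w311$variants$variant))
  # idempotent and order-independent
  again <- suppressMessages(exclude_variants(w311))
  expect_identical(again$variants, w311$variants)
  rev_excl <- suppressMessages(
    exclude_variants(w, rev(chek2_linked_variants())))
  expect_identical(rev_excl$variants, w311$variants)
  # empty exclusion list leaves the set alone
  expect_identical(exclude_variants(w, character())$variants, w$variants)
})

test_that("a set holding only one of the pair loses only that one", {
  fx <- make_weight_file(n = 306)
  w <- suppressMessages(parse_weights(fx$path))
  keep <- w$variants$variant != "22_29551872_A_G"
  w$variants <- w$variants[keep, ]            # 305 left, one CHEK2-linked
  out <- suppressMessages(exclude_variants(w))
  expect_equal(nrow(out$variants), 304)
})

test_that("PRS scoring matches the brute-force double loop", {
  fx <- make_weight_file(n = 10, with_chek2 = FALSE)
  gx <- make_genotype_file(fx$variants, n_samples = 5)
  w <- suppressMessages(parse_weights(fx$path))
  g <- read_genotypes(gx$path)
  s <- score_prs(g, w)
  expect_equal(unname(s), oracle_score(gx$dosage, fx$variants),
               tolerance = 1e-12)
  # trivial cases
  g0 <- genotype_matrix(matrix(0, 3, 10,
                               dimnames = list(letters[1:3],
                                               fx$variants$variant)))
  expect_equal(unname(score_prs(g0, w)), rep(0, 3))
  w1 <- w; w1$variants <- data.frame(variant = "1_100_A_G",
                                     effect_allele = "G", weight = 0.1)
  g1 <- genotype_matrix(matrix(2, 1, 1, dimnames = list("s", "1_100_A_G")))
  expect_equal(unname(score_prs(g1, w1)), 0.2)
})

test_that("ref-coded effect alleles are flipped and missingness is explicit", {
  w <- structure(list(name = "t", alpha = NA,
                      variants = data.frame(variant = "1_100_A_G",
                                            effect_allele = "A",
                                            weight = 1)),
                 class = "prs_weights")
  g <- genotype_matrix(matrix(0.5, 1, 1, dimnames = list("s", "1_100_A_G")))
  expect_equal(unname(suppressMessages(score_prs(g, w))), 1.5)  # 2 - 0.5
  gna <- genotype_matrix(matrix(c(1, NA), 2, 1,
                                dimnames = list(c("a", "b"), "1_100_A_G")))
  expect_error(suppressMessages(score_prs(gna, w)), "missing dosages")
  s <- suppressMessages(score_prs(gna, w, missing_policy = "mean_impute"))
  expect_equal(unname(s), c(1, 1))            # imputed at the observed mean
  wmiss <- w; wmiss$variants$variant <- "2_200_C_T"
  wmiss$variants$effect_allele <- "T"
  expect_error(score_prs(g, wmiss), "2_200_C_T")
})

test_that("standardization is the affine z-score map", {
  expect_equal(standardize(-0.424, -0.424, 0.611), 0)
  expect_equal(standardize(-0.424 + 0.611, -0.424, 0.611), 1)
  set.seed(3)
  x <- rnorm(500, 2, 3)
  z <- standardize(x, mean(x), sd(x))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize(1, 0, 0), "positive")
})
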