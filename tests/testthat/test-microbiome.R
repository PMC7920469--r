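mkCounts <- function(m) {
  dimnames(m) <- list(sprintf("s%d", seq_len(nrow(m))),
                      sprintf("t%d", seq_len(ncol(m))))
  m
}

test_that("zero replacement and log transform follow the stated rule", {
  # column (0, 2, 8): global positive minimum 2, zeros become 1
  m <- mkCounts(matrix(c(0, 2, 8), 3, 1))
  expect_equal(unname(preprocessCounts(m, relative = FALSE)[, 1]),
               c(log(1), log(2), log(8)))
  # no zeros: replacement is a no-op, pure log transform
  m2 <- mkCounts(matrix(c(1, 2, 4, 8), 2, 2))
  expect_equal(preprocessCounts(m2, relative = FALSE), log(m2))
  # output is finite for any valid input
  m3 <- mkCounts(matrix(c(0, 1, 5, 2, 3, 0), 3, 2))
  expect_true(all(is.finite(preprocessCounts(m3, relative = FALSE))))
  expect_true(all(is.finite(preprocessCounts(m3, relative = TRUE))))
})

test_that("per-taxon replacement errors on an all-zero taxon, naming it", {
  m <- mkCounts(matrix(c(1, 2, 0, 0), 2, 2))
  expect_error(preprocessCounts(m, pseudoMode = "per_taxon_min",
                                relative = FALSE), "t2")
  expect_error(preprocessCounts(mkCounts(matrix(c(1, 0, 2, 0), 2, 2)),
                                relative = TRUE), "zero total")
})

test_that("relative-abundance conversion happens before zero replacement", {
  m <- mkCounts(matrix(c(1, 0, 9, 10), 2, 2))  # rows sum to 10
  out <- preprocessCounts(m, relative = TRUE)
  # abundances: (.1, 0, .9, 1) -> zero replaced by .05
  expect_equal(unname(out), log(matrix(c(.1, .05, .9, 1), 2, 2)))
})

test_that("BMI groups use the exact cut points", {
  expect_equal(bmiGroup(c(18.49, 18.5, 24.99, 25, 29.99, 30, 35)),
               c("uw", "nor", "nor", "ow", "ow", "ob", "ob"))
  expect_error(bmiGroup(c(20, -1)), "positive")
})

test_that("groupings subset samples and encode obesity", {
  pheno <- data.frame(sample_id = paste0("s", 1:5),
                      bmi = c(17, 22, 31, 27, 33))   # uw nor ob ow ob
  g <- buildGrouping(pheno, "uw+ob")
  expect_equal(g$sampleIds, c("s1", "s3", "s5"))
  expect_equal(g$y, c(0L, 1L, 1L))
  gAll <- buildGrouping(pheno, "all")
  expect_equal(gAll$sampleIds, pheno$sample_id)
  expect_equal(gAll$y, c(0L, 0L, 1L, 0L, 1L))
  expect_error(buildGrouping(pheno, "uw+nor"), "valid options")
  expect_error(buildGrouping(pheno[1:2, ], "all"), "single outcome class")
})

test_that("synthetic count tables hit the target zero fraction", {
  fracs <- vapply(1:5, function(s)
    mean(generateSyntheticCounts(n = 100, p = 40, seed = s)$counts == 0),
    numeric(1))
  expect_true(all(abs(fracs - 0.3) < 0.02))
  noZero <- generateSyntheticCounts(n = 50, p = 20, zeroFraction = 0,
                                    seed = 3)
  expect_true(all(noZero$counts > 0))
  expect_error(generateSyntheticCounts(zeroFraction = 1), "zeroFraction")
})

test_that("synthetic tables are reproducible with labeled support", {
  a <- generateSyntheticCounts(n = 60, p = 25, seed = 11)
  b <- generateSyntheticCounts(n = 60, p = 25, seed = 11)
  expect_identical(a, b)
  expect_length(a$support, 5)
  expect_true(all(a$support %in% seq_len(25)))
  expect_identical(rownames(a$counts), a$pheno$sample_id)
  # obese samples, and only they, have BMI >= 30
  grp <- bmiGroup(a$pheno$bmi)
  expect_true(all(a$pheno$bmi[grp == "ob"] >= 30))
  expect_true(all(a$pheno$bmi[grp != "ob"] < 30))
})

test_that("taxon selection reports map back to input names", {
  syn <- generateSyntheticCounts(n = 150, p = 30, effectSize = 2, seed = 21)
  rep <- selectTaxa(syn$counts, syn$pheno, grouping = "all", q = 0.2,
                    k = 2, seed = 21, nlambda = 40)
  expect_true(all(rep$taxon %in% colnames(syn$counts)))
  expect_true(all(c("taxon", "selected_by_KO", "selected_by_AKO", "q") %in%
                  names(rep)))
  expect_true(all(rep$q == 0.2))
  res <- attr(rep, "result")
  expect_s4_class(res, "AggregationResult")
  # deterministic rerun
  rep2 <- selectTaxa(syn$counts, syn$pheno, grouping = "all", q = 0.2,
                     k = 2, seed = 21, nlambda = 40)
  expect_identical(rep$taxon, rep2$taxon)
})

test_that("taxon selection validates its inputs", {
  syn <- generateSyntheticCounts(n = 60, p = 10, seed = 31)
  phenoBad <- syn$pheno
  phenoBad$sample_id[1] <- "missing_sample"
  expect_error(selectTaxa(syn$counts, phenoBad, seed = 1), "absent")
  # proportional taxa become constant on the relative scale and are
  # dropped, leaving too few to analyze
  flat <- mkCounts(matrix(rep(1:60, 2), 60, 2))
  rownames(flat) <- syn$pheno$sample_id
  expect_error(selectTaxa(flat, syn$pheno, seed = 1),
               "fewer than 2 non-constant taxa")
})

test_that("count and phenotype tables round-trip through TSV and CSV", {
  syn <- generateSyntheticCounts(n = 20, p = 6, seed = 41)
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = rownames(syn$counts), syn$counts,
                   check.names = FALSE)
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readCountTable(tsv)
  expect_equal(back, syn$counts)
  csv <- tempfile(fileext = ".csv")
  write.csv(syn$pheno, csv, row.names = FALSE)
  phback <- readPhenotypeTable(csv)
  expect_equal(phback$sample_id, syn$pheno$sample_id)
  expect_equal(phback$bmi, syn$pheno$bmi, tolerance = 1e-12)
  expect_error(readCountTable(tempfile()), "not found")
})
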