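fake_deconv <- function(calls, noc = 2L) {
  structure(list(calls = calls, noc = noc, p_threshold = 0.9,
                 sample_id = "fake"), class = "mps_deconv")
}

fake_calls <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$determinate <- mixdeconv:::is_determinate(df$posterior, df$dropout, 0.9)
  df
}

fake_profile <- function(id, genos) {
  structure(list(sample_id = id, genotypes = genos),
            class = "genotype_profile")
}

test_that("the determinate rule is strict-below on 0.9 and excludes drop-out", {
  expect_false(mixdeconv:::is_determinate(0.89, FALSE, 0.9))
  expect_true(mixdeconv:::is_determinate(0.90, FALSE, 0.9))
  expect_true(mixdeconv:::is_determinate(0.95, FALSE, 0.9))
  expect_false(mixdeconv:::is_determinate(0.99, TRUE, 0.9))
})

test_that("classification partitions calls into Correct/Wrong/Undetermined", {
  calls <- fake_calls(
    locus = c("L1", "L1", "L2", "L2", "L3", "L3"),
    contributor = c(1L, 2L, 1L, 2L, 1L, 2L),
    allele1 = c("a", "c", "a", "Q", "b", "a"),
    allele2 = c("b", "c", "a", "c", "b", "c"),
    posterior = c(0.97, 0.95, 0.89, 0.99, 0.90, 0.92),
    dropout = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  truth <- list(
    fake_profile("T1", list(L1 = c("a", "b"), L2 = c("a", "a"),
                            L3 = c("b", "b"))),
    fake_profile("T2", list(L1 = c("c", "c"), L2 = c("c", "c"),
                            L3 = c("a", "a"))))
  rec <- classify_deconvolution(fake_deconv(calls), truth, c(0.75, 0.25))
  expect_identical(nrow(rec), 6L)
  cls <- setNames(rec$classification, paste(rec$locus, rec$contributor))
  expect_identical(cls[["L1 1"]], "Correct")       # 0.97, matches
  expect_identical(cls[["L1 2"]], "Correct")
  expect_identical(cls[["L2 1"]], "Undetermined")  # 0.89 < 0.9
  expect_identical(cls[["L2 2"]], "Undetermined")  # drop-out proposed
  expect_identical(cls[["L3 1"]], "Correct")       # exactly 0.90
  expect_identical(cls[["L3 2"]], "Wrong")         # one wrong allele
  # partition: every record has exactly one class
  expect_true(all(rec$classification %in%
                    c("Correct", "Wrong", "Undetermined")))
  expect_error(classify_deconvolution(fake_deconv(calls), truth[1],
                                      c(1)), "truth profiles")
})

test_that("equal-proportion contributors are matched by the pairing with fewest errors", {
  calls <- fake_calls(
    locus = c("L1", "L1"), contributor = c(1L, 2L),
    allele1 = c("a", "c"), allele2 = c("a", "c"),
    posterior = c(0.99, 0.99), dropout = c(FALSE, FALSE))
  truth <- list(fake_profile("T1", list(L1 = c("c", "c"))),
                fake_profile("T2", list(L1 = c("a", "a"))))
  rec <- classify_deconvolution(fake_deconv(calls), truth, c(0.5, 0.5))
  expect_identical(rec$classification, c("Correct", "Correct"))
})

test_that("consensus keeps only identical determinate calls", {
  c1 <- fake_calls(locus = c("L1", "L2", "L3"), contributor = 1L,
                   allele1 = c("a", "a", "a"), allele2 = c("b", "b", "b"),
                   posterior = c(0.99, 0.99, 0.99),
                   dropout = c(FALSE, FALSE, FALSE))
  c2 <- fake_calls(locus = c("L1", "L2", "L3"), contributor = 1L,
                   allele1 = c("a", "a", "a"), allele2 = c("b", "c", "b"),
                   posterior = c(0.99, 0.99, 0.5),
                   dropout = c(FALSE, FALSE, FALSE))
  cons <- consensus(fake_deconv(c1, 1L), fake_deconv(c2, 1L))
  expect_identical(cons$determinate, c(TRUE, FALSE, FALSE))
  expect_identical(cons$allele1[1], "a")
  # consensus never invents a genotype absent from a replicate
  expect_true(all(is.na(cons$allele1[!cons$determinate])))

  c3 <- fake_calls(locus = "L9", contributor = 1L, allele1 = "a",
                   allele2 = "b", posterior = 0.99, dropout = FALSE)
  expect_error(consensus(fake_deconv(c1, 1L), fake_deconv(c3, 1L)),
               "different loci")
})

test_that("RMP is the HWE product over determinate loci", {
  freqs <- manual_freqs(rep("L1", 2), c("a", "b"), c(0.5, 0.5))
  empty <- data.frame(locus = character(0), allele1 = character(0),
                      allele2 = character(0), determinate = logical(0))
  expect_identical(random_match_probability(empty, freqs), 1)

  het <- data.frame(locus = "L1", allele1 = "a", allele2 = "b",
                    determinate = TRUE)
  expect_equal(random_match_probability(het, freqs), 0.5)

  # ten-locus product against an independently coded oracle
  set.seed(404)
  loci <- sprintf("L%02d", 1:10)
  p <- runif(10, 0.05, 0.6)
  q <- runif(10, 0.05, 0.35)
  freqs10 <- manual_freqs(rep(loci, each = 2),
                          rep(c("a", "b"), 10),
                          as.vector(rbind(p, q)))
  hom <- runif(10) < 0.4
  prof <- data.frame(locus = loci, allele1 = "a",
                     allele2 = ifelse(hom, "a", "b"), determinate = TRUE)
  got <- random_match_probability(prof, freqs10)
  want <- prod(ifelse(hom, p^2, 2 * p * q))
  expect_equal(got, want, tolerance = 1e-12)

  # RMP never increases as determinate loci are added
  partial <- prof[1:5, ]
  expect_gte(random_match_probability(partial, freqs10), got)
})

test_that("proportion comparison runs Shapiro-Wilk and Wilcoxon as specified", {
  x <- c(1.1, 1.3, 1.0, 1.2, 1.15, 1.4, 1.05, 1.25)
  same <- compare_proportion_estimates(x, x, expected_ratio = 1)
  expect_gt(same$wilcoxon_p, 0.99)

  set.seed(7)
  a <- 1 + abs(rnorm(45, 0, 0.05))
  b <- a + 1
  shift <- compare_proportion_estimates(a, b, expected_ratio = 1)
  expect_lt(shift$wilcoxon_p, 0.001)
  expect_false(is.na(shift$shapiro_p[["mh"]]))

  const <- compare_proportion_estimates(rep(2, 10), x, expected_ratio = 2)
  expect_true(is.na(const$shapiro_p[["mh"]]))   # degenerate group flagged
  expect_true(is.finite(const$wilcoxon_p))

  expect_error(compare_proportion_estimates(c(1, 2), x), "at least 3")
})

test_that("summary tables partition to 100% and report the error rate", {
  rec <- data.frame(
    ratio = rep(c("3:1", "1:1"), each = 6),
    contributor = rep(c(1L, 2L), 6),
    classification = c("Correct", "Wrong", "Correct", "Undetermined",
                       "Correct", "Correct",
                       rep("Undetermined", 6)),
    stringsAsFactors = FALSE)
  s <- summarize_records(rec)
  row_sums <- s$table$pct_correct + s$table$pct_wrong +
    s$table$pct_undetermined
  expect_true(all(abs(row_sums - 100) <= 0.1 + 1e-9))
  expect_identical(s$wrong, 1L)
  expect_identical(s$total, 12L)
  all_undet <- summarize_records(
    data.frame(ratio = "1:1", contributor = 1L,
               classification = rep("Undetermined", 5)))
  expect_identical(all_undet$table$pct_undetermined, 100)
  expect_identical(all_undet$error_rate_pct, 0)
})
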