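test_that("genotype enumeration counts and contents are exhaustive", {
  g1 <- enumerate_genotypes("a", allow_dropout = TRUE)
  expect_length(g1, 3L)   # aa, aQ, QQ
  expect_setequal(vapply(g1, paste, "", collapse = "/"),
                  c("a/a", "a/Q", "Q/Q"))

  g2 <- enumerate_genotypes(c("a", "b"), allow_dropout = TRUE)
  expect_length(g2, 6L)
  joint <- expand.grid(seq_along(g2), seq_along(g2))
  expect_identical(nrow(joint), 36L)

  g2n <- enumerate_genotypes(c("a", "b"), allow_dropout = FALSE)
  expect_length(g2n, 3L)
  expect_setequal(vapply(g2n, paste, "", collapse = "/"),
                  c("a/a", "a/b", "b/b"))

  # general count: (A+1)(A+2)/2 with dropout
  for (A in 1:5) {
    expect_length(enumerate_genotypes(letters[seq_len(A)], TRUE),
                  (A + 1) * (A + 2) / 2)
  }
  expect_error(enumerate_genotypes(character(0), FALSE), "nothing")
})

test_that("locus likelihood is symmetric under joint contributor/omega swap", {
  calib <- manual_calib("L1")
  freqs <- manual_freqs("L1", c("AA", "CC", "GG"), c(0.5, 0.3, 0.2))
  y <- c(AA = 900L, CC = 280L, GG = 120L)
  g1 <- list(c("AA", "CC"), c("GG", "GG"))
  ll_a <- locus_log_likelihood(y, g1, c(0.8, 0.2), 1300, 0.02, calib,
                               "L1", freqs)
  ll_b <- locus_log_likelihood(y, rev(g1), c(0.2, 0.8), 1300, 0.02, calib,
                               "L1", freqs)
  expect_equal(ll_a, ll_b, tolerance = 1e-12)
})

test_that("the dispersion->0 limit agrees with an independent Poisson likelihood", {
  calib <- manual_calib("L1", noise_rate = 0.3, noise_geom_p = 0.2)
  freqs <- manual_freqs("L1", c("AA", "CC"), c(0.6, 0.4))
  y <- c(AA = 700L, CC = 300L)
  g <- list(c("AA", "AA"), c("CC", "Q"))
  omega <- c(0.7, 0.3); mu <- 1100
  ll <- locus_log_likelihood(y, g, omega, mu, 1e-9, calib, "L1", freqs)

  # independent Poisson implementation
  e_aa <- mu * (0.7 * 2 / 2)
  e_cc <- mu * (0.3 * 1 / 2)
  e_q <- mu * (0.3 * 1 / 2)
  ll_pois <- dpois(700, e_aa, log = TRUE) + dpois(300, e_cc, log = TRUE) +
    ppois(10, e_q, log.p = TRUE) + dpois(0, 0.3, log = TRUE)
  expect_equal(ll, ll_pois, tolerance = 1e-4)
})

test_that("all-dropout genotypes with empty evidence give the pure baseline", {
  calib <- manual_calib("L1", noise_rate = 0.3)
  freqs <- manual_freqs("L1", "AA", 1)
  ll <- locus_log_likelihood(setNames(integer(0), character(0)),
                             list(c("Q", "Q"), c("Q", "Q")),
                             c(0.5, 0.5), 1000, 0.02, calib, "L1", freqs)
  baseline <- pnbinom(10, size = 50, mu = 1000, log.p = TRUE) +
    dpois(0, 0.3, log = TRUE)
  expect_equal(ll, baseline, tolerance = 1e-10)
})

test_that("unexplained alleles are impossible under a zero-noise model", {
  calib <- manual_calib("L1", noise_rate = 0)
  freqs <- manual_freqs("L1", c("AA", "CC"), c(0.6, 0.4))
  y <- c(AA = 900L, CC = 100L)
  ll <- locus_log_likelihood(y, list(c("AA", "AA"), c("AA", "AA")),
                             c(0.6, 0.4), 1000, 0.02, calib, "L1", freqs)
  expect_identical(ll, -Inf)
})

test_that("marginalised likelihood and posteriors match brute-force enumeration", {
  # 20 random two-contributor cases with <= 3 observed alleles, compared
  # with the scalar oracle at 1e-6 relative precision
  set.seed(314)
  for (case in 1:20) {
    n_al <- sample(1:3, 1)
    als <- paste0("H", seq_len(n_al))
    f <- as.numeric(rmultinom(1, 60, rep(1, n_al + 1)) + 1)
    f <- f / sum(f)
    f_obs <- f[seq_len(n_al)]
    f_q <- max(1 - sum(f_obs), 5 / 200)
    y <- setNames(11L + rpois(n_al, sample(c(50, 300, 1500), n_al,
                                           replace = TRUE)), als)
    omega <- as.numeric(rmultinom(1, 18, c(1, 1)) + 1)
    omega <- omega / sum(omega)
    mu <- runif(1, 500, 3000)
    theta <- runif(1, 0.005, 0.08)
    calib <- manual_calib("L1", noise_rate = 0.25, noise_geom_p = 0.15)
    freqs <- manual_freqs("L1", als, f_obs)

    orc <- oracle_marginal_2p(y, omega, mu, theta, eff = 1, at = 11,
                              noise_rate = 0.25, noise_geom_p = 0.15,
                              f = setNames(f_obs, als), f_q = f_q)
    ctx <- mixdeconv:::build_locus_context("L1", y, list(), 2L, calib, freqs)
    got_ll <- mixdeconv:::context_loglik(ctx, omega, mu, theta)
    expect_equal(got_ll, orc$loglik, tolerance = 1e-6)

    calls <- mixdeconv:::deconv_calls(fake_fit_2p(ctx, omega, mu, theta), 0.9)
    for (k in 1:2) {
      post <- if (fake_fit_2p(ctx, omega, mu, theta)$order[k] == 1)
        orc$post1 else orc$post2
      # oracle genotypes enumerate in the same (i <= j) order
      want_top <- max(if (k == 1) orc$post1 else orc$post2)
      got <- calls[calls$contributor == fake_fit_2p(ctx, omega, mu,
                                                    theta)$order[k], ]
      expect_equal(got$posterior, want_top, tolerance = 1e-6)
    }
  }
})
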