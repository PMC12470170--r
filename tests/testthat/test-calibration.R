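test_that("dose assignment follows the 0/1/2 rule", {
  panel <- build_panel("MH", 2, seed = 51)
  pop <- sample_population(panel, 4, 6, seed = 52)
  # find a profile with one het and pick alleles from it
  prof <- pop$profiles[[which(vapply(pop$profiles, function(p) {
    g <- p$genotypes[[1]]
    g[1] != g[2] && p$genotypes[[2]][1] == p$genotypes[[2]][2]
  }, TRUE))[1]]]
  l1 <- names(panel$loci)[1]; l2 <- names(panel$loci)[2]
  noise_al <- setdiff(pop$freqs$allele[pop$freqs$locus == l1],
                      prof$genotypes[[l1]])[1]
  counts <- structure(list(
    sample_id = prof$sample_id,
    counts = data.frame(
      locus = c(l1, l1, l1, l2),
      allele = c(prof$genotypes[[l1]], noise_al, prof$genotypes[[l2]][1]),
      count = c(500L, 450L, 20L, 900L),
      status = "retained", stringsAsFactors = FALSE),
    unassigned_reads = 0L, analytical_threshold = 11L,
    total_reads = 1870L), class = "allele_counts")
  d <- assign_dose(prof, counts, panel)
  expect_identical(d$dose, c(1L, 1L, 0L, 2L))
  # dose bookkeeping: non-noise doses sum to 2 per called locus
  by_locus <- tapply(d$dose[d$dose > 0], d$locus[d$dose > 0], sum)
  expect_true(all(by_locus == 2L))

  counts$counts$locus[4] <- "MHXXX"
  expect_error(assign_dose(prof, counts, panel), "no truth genotype")
})

test_that("calibration recovers equal efficiencies within 5% and is order-invariant", {
  w <- tiny_world("MH", n_loci = 6, depth = 30000, n_people = 30, n_cal = 25,
                  seed = 53, equal_efficiency = TRUE)
  expect_true(all(abs(w$calib$locus_efficiency - 1) < 0.05))

  perm <- rev(seq_along(w$cal_samples))
  calib2 <- calibrate_model(w$cal_samples[perm], w$panel)
  expect_equal(calib2$locus_efficiency, w$calib$locus_efficiency,
               tolerance = 1e-12)
  expect_equal(calib2$dispersion, w$calib$dispersion, tolerance = 1e-12)

  expect_error(calibrate_model(w$cal_samples[1], w$panel), "at least 2")
})

test_that("a zero-noise cohort calibrates to a degenerate noise model", {
  w <- tiny_world("MH", n_loci = 4, depth = 10000, n_cal = 6, seed = 54,
                  read_opts = list(noise_rate = 0))
  expect_identical(w$calib$noise_rate, 0)
  expect_identical(w$calib$noise_geom_p, 1)
})

test_that("constant STR stutter is recovered: intercept near 0.05, slope near 0", {
  panel <- build_panel("STR", 8, seed = 55)
  for (nm in names(panel$loci)) panel$loci[[nm]]$stutter_truth <- 0.05
  pop <- sample_population(panel, 5, 30, seed = 56)
  cal <- lapply(pop$profiles, function(p) {
    r <- generate_reads(p, panel,
                        read_params(40000, noise_rate = 0.2,
                                    seed = 570 + match(p$sample_id,
                                      vapply(pop$profiles, `[[`, "",
                                             "sample_id"))))
    list(profile = p, counts = call_alleles(r, panel))
  })
  calib <- calibrate_model(cal, panel)
  ints <- vapply(calib$stutter_model, `[[`, 0, "intercept")
  slopes <- vapply(calib$stutter_model, `[[`, 0, "slope")
  npts <- vapply(calib$stutter_model, `[[`, 0, "n_points")
  informative <- npts >= 10
  expect_gt(sum(informative), 0)
  mid <- vapply(names(panel$loci)[informative], function(nm) {
    mixdeconv:::stutter_expected(calib, nm,
                                 panel$loci[[nm]]$reference_repeats)
  }, 0)
  expect_true(all(abs(mid - 0.05) < 0.01))
  expect_true(all(abs(slopes[informative]) < 0.005))
})

test_that("calibration JSON round-trips and enforces invariants", {
  w <- tiny_world("MH", n_loci = 4, depth = 8000, n_cal = 5, seed = 58)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(w$calib, path)
  back <- load_model(path)
  expect_equal(back$locus_efficiency, w$calib$locus_efficiency,
               tolerance = 1e-12)
  expect_equal(back$dispersion, w$calib$dispersion, tolerance = 1e-12)
  expect_equal(back$noise_rate, w$calib$noise_rate, tolerance = 1e-12)
  expect_equal(back$noise_geom_p, w$calib$noise_geom_p, tolerance = 1e-12)

  bad <- w$calib
  bad$locus_efficiency[1] <- -1
  expect_error(save_model(bad, path), "positive")

  writeLines('{"schema": "something-else"}', path)
  expect_error(load_model(path), "schema")
  writeLines('{"schema": "mixdeconv-calib', path)
  expect_error(load_model(path))
})
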