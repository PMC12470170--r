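test_that("bracketing matches the regex oracle and round-trips", {
  b <- bracket_str_sequence("ATCTATCTATCT", "ATCT")
  expect_identical(b$bracketed, "[ATCT]3")
  expect_identical(b$repeat_number, 3L)

  b2 <- bracket_str_sequence("ATCTATCTATGTATCT", "ATCT")
  expect_identical(b2$bracketed, "[ATCT]2 ATGT [ATCT]1")
  expect_identical(b2$repeat_number, 3L)

  expect_error(bracket_str_sequence("", "ATCT"), "empty")
  expect_error(bracket_str_sequence("GGGG", "ATCT"), "no complete copy")

  set.seed(99)
  for (i in 1:30) {
    motif <- c("ATC", "ATCT", "AGGTC")[[sample(3, 1)]]
    region <- paste0(
      strrep(motif, sample(1:6, 1)),
      if (runif(1) < 0.5) paste(sample(c("A", "C", "G", "T"),
                                       sample(1:2, 1)), collapse = "") else "",
      strrep(motif, sample(0:6, 1)))
    got <- bracket_str_sequence(region, motif)
    want <- oracle_bracket(region, motif)
    expect_identical(got$bracketed, want$bracketed)
    expect_identical(got$repeat_number, want$repeat_number)
    expect_identical(expand_bracketed(got$bracketed), region)
  }
})

test_that("MH calling masks ignored positions and rejects mismatches", {
  panel <- build_panel("MH", 1, seed = 41)
  l <- panel$loci[[1]]
  l$ignored_positions <- setdiff(0:9, l$variant_positions)[1:2]

  ref_allele <- mh_allele_from_read(l$reference, l)
  expect_identical(ref_allele,
                   mixdeconv:::chars_at(l$reference, l$variant_positions))

  # substitution at a variant position changes the allele
  vp <- l$variant_positions[1]
  old <- substr(l$reference, vp + 1, vp + 1)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  mut <- mixdeconv:::subst_chars(l$reference, vp, new)
  expect_identical(substr(mh_allele_from_read(mut, l), 1, 1), new)

  # substitution at an ignored position is invisible
  ip <- l$ignored_positions[1]
  oldi <- substr(l$reference, ip + 1, ip + 1)
  muti <- mixdeconv:::subst_chars(l$reference, ip,
                                  setdiff(c("A", "C", "G", "T"), oldi)[1])
  expect_identical(mh_allele_from_read(muti, l), ref_allele)

  # substitution elsewhere makes the read unassignable
  op <- setdiff(seq_len(l$amplicon_length) - 1L,
                c(l$variant_positions, l$ignored_positions))[5]
  oldo <- substr(l$reference, op + 1, op + 1)
  muto <- mixdeconv:::subst_chars(l$reference, op,
                                  setdiff(c("A", "C", "G", "T"), oldo)[1])
  expect_true(is.na(mh_allele_from_read(muto, l)))
})

test_that("calling conserves reads and applies the analytical threshold at >= 11", {
  panel <- build_panel("MH", 2, seed = 42)
  l1 <- panel$loci[[1]]
  pop <- sample_population(panel, 3, 1, seed = 43)
  hap_a <- pop$freqs$allele[pop$freqs$locus == l1$name][1]
  hap_b <- pop$freqs$allele[pop$freqs$locus == l1$name][2]
  reads <- data.frame(
    id = sprintf("X:%03d", 1:31),
    seq = c(rep(allele_sequence(l1, hap_a), 20),
            rep(allele_sequence(l1, hap_b), 10),   # below AT=11
            strrep("A", 50)),                       # junk
    stringsAsFactors = FALSE)
  ct <- call_alleles(reads, panel, analytical_threshold = 11)
  ret <- ct$counts[ct$counts$status == "retained", ]
  bel <- ct$counts[ct$counts$status == "below_threshold", ]
  expect_identical(ret$allele, hap_a)
  expect_identical(ret$count, 20L)
  expect_identical(bel$allele, hap_b)
  expect_identical(bel$count, 10L)
  expect_identical(ct$unassigned_reads, 1L)
  expect_identical(sum(ct$counts$count) + ct$unassigned_reads, nrow(reads))

  # boundary: exactly 11 reads is retained
  reads11 <- data.frame(id = sprintf("X:%d", 1:11),
                        seq = rep(allele_sequence(l1, hap_b), 11),
                        stringsAsFactors = FALSE)
  ct11 <- call_alleles(reads11, panel)
  expect_identical(ct11$counts$status, "retained")

  # exclusion hook drops a locus entirely
  ct_ex <- call_alleles(reads, panel, exclude_loci = l1$name)
  expect_false(l1$name %in% ct_ex$counts$locus)
})

test_that("noise-free single-source calling recovers the generating genotype", {
  for (kind in c("MH", "STR")) {
    world_panel <- build_panel(kind, 3, seed = 44)
    pop <- sample_population(world_panel, 4, 2, seed = 45)
    prof <- pop$profiles[[1]]
    r <- generate_reads(prof, world_panel,
                        read_params(6000, noise_rate = 0, seed = 46))
    ct <- call_alleles(r, world_panel)
    for (l in world_panel$loci) {
      ret <- ct$counts[ct$counts$locus == l$name &
                         ct$counts$status == "retained", ]
      truth <- unique(prof$genotypes[[l$name]])
      if (kind == "MH") {
        expect_setequal(ret$allele, truth)
      } else {
        # stutter products may be retained; true alleles must dominate
        expect_true(all(truth %in% ret$allele))
        top <- ret$allele[order(-ret$count)][seq_along(truth)]
        expect_setequal(top, truth)
      }
    }
  }
})

test_that("count tables round-trip through TSV", {
  panel <- build_panel("MH", 2, seed = 47)
  pop <- sample_population(panel, 3, 1, seed = 48)
  r <- generate_reads(pop$profiles[[1]], panel, read_params(3000, seed = 49))
  ct <- call_alleles(r, panel)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(ct, path)
  back <- read_counts_tsv(path)
  expect_identical(back$counts$count, ct$counts$count)
  expect_identical(back$counts$allele, ct$counts$allele)
  expect_identical(back$unassigned_reads, ct$unassigned_reads)
  expect_identical(back$analytical_threshold, ct$analytical_threshold)
})
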