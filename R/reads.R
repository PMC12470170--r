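#' Read-generation parameters
#'
#' Bundles the knobs of the single-source read simulator. Defaults emulate
#' well-behaved amplicon sequencing: mild heterozygote imbalance, mild
#' length-dependent attenuation of long STR alleles, and sparse low-level
#' noise whose read counts follow a geometric law (so that the noise
#' surviving any analytical threshold is still geometric, by memorylessness).
#'
#' @param total_reads reads in the output FASTQ (exact), e.g. 370000 for a
#'   74-locus MH assay, 220000 for a 26-locus STR kit.
#' @param heterozygote_imbalance_sd sd of the per-allele log-normal read
#'   multiplier (log scale).
#' @param length_attenuation STR-only: expected reads scaled by
#'   `exp(-length_attenuation * repeat_number)`, so long alleles yield fewer
#'   reads.
#' @param noise_rate expected number of noise alleles per locus (Poisson).
#' @param noise_geom_p geometric parameter of noise read counts
#'   (count = 1 + Geom(p)).
#' @param seed integer seed.
#' @return list of class `read_params`.
#' @export
read_params <- function(total_reads, heterozygote_imbalance_sd = 0.15,
                        length_attenuation = 0.015, noise_rate = 0.5,
                        noise_geom_p = 0.1, seed = 1L) {
  total_reads <- check_count(total_reads, "total_reads")
  stopifnot(heterozygote_imbalance_sd >= 0, length_attenuation >= 0,
            noise_rate >= 0, noise_geom_p > 0, noise_geom_p <= 1)
  structure(list(total_reads = total_reads,
                 heterozygote_imbalance_sd = heterozygote_imbalance_sd,
                 length_attenuation = length_attenuation,
                 noise_rate = noise_rate, noise_geom_p = noise_geom_p,
                 seed = as.integer(seed)),
            class = "read_params")
}

#' Simulate single-source amplicon reads
#'
#' Produces an error-free FASTQ-style read set for one individual. Expected
#' per-allele read counts are proportional to locus efficiency times allele
#' copy number (1 for each heterozygous allele, 2 for a homozygote) times a
#' log-normal heterozygote-imbalance multiplier; STR alleles are further
#' attenuated with repeat length, and each STR parent allele sheds its
#' locus's stutter fraction to the one-repeat-shorter sequence. Noise
#' alleles (sequences not in the genotype) are injected per locus at a
#' Poisson rate with geometric read counts. The realised counts are a single
#' multinomial draw, so the output has exactly `params$total_reads` records.
#'
#' Read headers carry the sample id and a serial number only -- nothing the
#' allele caller could use as truth.
#'
#' @param profile a `genotype_profile` covering the panel.
#' @param panel a `locus_panel`.
#' @param params a [read_params()] object.
#' @return A `read_set`: data frame with columns `id`, `seq`.
#' @export
generate_reads <- function(profile, panel, params) {
  stopifnot(inherits(profile, "genotype_profile"),
            inherits(panel, "locus_panel"),
            inherits(params, "read_params"))
  missing <- setdiff(names(panel$loci), names(profile$genotypes))
  if (length(missing)) {
    stopf("profile %s lacks genotypes for loci: %s", profile$sample_id,
          paste(head(missing, 3L), collapse = ", "))
  }
  with_seed(params$seed, {
    cats <- do.call(rbind, lapply(panel$loci, function(locus) {
      locus_read_categories(locus, profile$genotypes[[locus$name]], params)
    }))
    ## noise weights are in read units already; scale true-allele weights so
    ## the full multinomial has the requested total in expectation
    noise <- cats$noise
    n_noise_target <- sum(cats$weight[noise])
    true_budget <- max(params$total_reads - n_noise_target, 1)
    w <- cats$weight
    w[!noise] <- w[!noise] / sum(w[!noise]) * true_budget
    counts <- as.vector(rmultinom(1L, params$total_reads, w))
    seqs <- rep(cats$seq, counts)
    ord <- sample.int(length(seqs))
    data.frame(
      id = sprintf("%s:%06d", profile$sample_id, seq_along(seqs)),
      seq = seqs[ord], stringsAsFactors = FALSE)
  })
}

## One row per distinct read sequence a locus can emit: true alleles,
## stutter products, and sampled noise alleles.
locus_read_categories <- function(locus, genotype, params) {
  alleles <- unique(genotype)
  copies <- vapply(alleles, function(a) sum(genotype == a), 1)
  w <- locus$efficiency_truth * (copies / 2) *
    exp(stats::rnorm(length(alleles), 0, params$heterozygote_imbalance_sd))
  if (locus$kind == "STR") {
    reps <- vapply(alleles, bracketed_repeat_number, 1L)
    w <- w * exp(-params$length_attenuation * reps)
    s <- locus$stutter_truth
    stut_id <- sprintf("[%s]%d", locus$repeat_motif, reps - 1L)
    keep <- reps > 1L
    ids <- c(alleles, stut_id[keep])
    wts <- c(w * ifelse(keep, 1 - s, 1), w[keep] * s)
    agg <- tapply(wts, ids, sum)
    alleles <- names(agg)
    w <- as.vector(agg)
  }
  n_noise <- rpois(1L, params$noise_rate)
  noise_ids <- character(0)
  noise_w <- numeric(0)
  if (n_noise > 0L) {
    for (i in seq_len(n_noise)) {
      nid <- sample_noise_allele(locus, genotype, exclude = c(alleles, noise_ids))
      if (is.na(nid)) next
      noise_ids <- c(noise_ids, nid)
      noise_w <- c(noise_w, 1 + rgeom(1L, params$noise_geom_p))
    }
  }
  ids <- c(alleles, noise_ids)
  data.frame(
    seq = vapply(ids, function(a) allele_sequence(locus, a), ""),
    weight = c(w, noise_w),
    noise = c(rep(FALSE, length(alleles)), rep(TRUE, length(noise_ids))),
    stringsAsFactors = FALSE)
}

## A noise allele is a callable sequence absent from the genotype: a one-base
## haplotype variant (MH) or an off-ladder repeat count (STR). STR noise
## avoids the n-1 positions of true alleles so it is not confounded with
## stutter.
sample_noise_allele <- function(locus, genotype, exclude) {
  if (locus$kind == "MH") {
    for (i in 1:10) {
      base_hap <- sample(genotype, 1L)
      p <- sample.int(nchar(base_hap), 1L)
      b <- sample(setdiff(DNA_BASES, substr(base_hap, p, p)), 1L)
      hap <- subst_chars(base_hap, p - 1L, b)
      if (!hap %in% exclude) return(hap)
    }
  } else {
    reps <- vapply(genotype, bracketed_repeat_number, 1L)
    cand <- setdiff(seq.int(max(2L, min(reps) - 3L), max(reps) + 3L),
                    c(reps, reps - 1L))
    cand_ids <- sprintf("[%s]%d", locus$repeat_motif, cand)
    cand_ids <- setdiff(cand_ids, exclude)
    if (length(cand_ids)) return(sample(cand_ids, 1L))
  }
  NA_character_
}

## ---- FASTQ input/output -----------------------------------------------

#' Write / read a read set as FASTQ
#'
#' Standard 4-line FASTQ with a constant Phred+33 quality string (`I`);
#' base-call qualities are not modelled. Writing is deterministic, so equal
#' read sets give byte-identical files.
#'
#' @param reads a `read_set` data frame (`id`, `seq`).
#' @param path file path.
#' @name fastq_io
#' @export
write_fastq <- function(reads, path) {
  recs <- paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                 strrep("I", nchar(reads$seq)))
  writeLines(recs, path)
  invisible(path)
}

#' @rdname fastq_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(unname(x)),
             stringsAsFactors = FALSE)
}
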