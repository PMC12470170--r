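#' Sample a synthetic population for a panel
#'
#' Draws per-locus allele frequencies from a symmetric Dirichlet prior and
#' samples unrelated individuals under Hardy-Weinberg equilibrium. MH allele
#' universes are distinct haplotypes over the locus's variant positions
#' (always including the reference haplotype); STR universes are runs of
#' whole motif copies centred on the reference repeat number. The returned
#' frequency table covers the full allele universe, so every allele carried
#' by a sampled individual has nonzero frequency.
#'
#' @param panel a `locus_panel`.
#' @param n_alleles_per_locus target allele count per locus (capped at the
#'   number of realisable haplotypes for MH loci).
#' @param n_individuals number of HWE genotype profiles to draw.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration (default 1: flat over the
#'   simplex, giving realistically uneven spectra).
#' @return list with `freqs` (an `allele_freqs` data frame: locus, allele,
#'   frequency; attribute `population_size`) and `profiles` (list of
#'   `genotype_profile` objects).
#' @export
sample_population <- function(panel, n_alleles_per_locus, n_individuals, seed,
                              concentration = 1) {
  stopifnot(inherits(panel, "locus_panel"))
  n_alleles_per_locus <- check_count(n_alleles_per_locus, "n_alleles_per_locus")
  n_individuals <- check_count(n_individuals, "n_individuals")
  with_seed(seed, {
    universe <- lapply(panel$loci, locus_allele_universe, n = n_alleles_per_locus)
    freqs_by_locus <- lapply(universe, function(al) {
      w <- stats::rgamma(length(al), shape = concentration)
      if (all(w == 0)) w <- rep(1, length(al))
      setNames(w / sum(w), al)
    })
    profiles <- lapply(seq_len(n_individuals), function(i) {
      g <- lapply(freqs_by_locus, function(fr) {
        sort(sample(names(fr), 2L, replace = TRUE, prob = fr))
      })
      structure(list(sample_id = sprintf("S%03d", i), genotypes = g),
                class = "genotype_profile")
    })
    freqs <- data.frame(
      locus = rep(names(freqs_by_locus),
                  vapply(freqs_by_locus, length, 1L)),
      allele = unlist(lapply(freqs_by_locus, names), use.names = FALSE),
      frequency = unlist(freqs_by_locus, use.names = FALSE),
      stringsAsFactors = FALSE)
    rownames(freqs) <- NULL
    attr(freqs, "population_size") <- n_individuals
    class(freqs) <- c("allele_freqs", "data.frame")
    list(freqs = freqs, profiles = profiles)
  })
}

locus_allele_universe <- function(locus, n) {
  if (locus$kind == "MH") {
    n_var <- length(locus$variant_positions)
    n <- min(n, 4^n_var)
    ref_hap <- chars_at(locus$reference, locus$variant_positions)
    haps <- ref_hap
    while (length(haps) < n) {
      h <- paste(sample(DNA_BASES, n_var, replace = TRUE), collapse = "")
      if (!h %in% haps) haps <- c(haps, h)
    }
    sort(haps)
  } else {
    lo <- max(4L, locus$reference_repeats - (n - 1L) %/% 2L)
    counts <- seq.int(lo, lo + n - 1L)
    sprintf("[%s]%d", locus$repeat_motif, counts)
  }
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf("<genotype_profile> %s, %d loci\n",
              x$sample_id, length(x$genotypes)))
  invisible(x)
}

#' Look up allele frequencies with a rare-allele floor
#'
#' Alleles absent from the table (or recorded at zero) get the
#' minimum-allele-count frequency 5/(2N), where N is the population size the
#' table was estimated from.
#'
#' @param freqs an `allele_freqs` table.
#' @param locus locus name.
#' @param alleles character vector of allele ids.
#' @return numeric vector of frequencies.
#' @export
allele_frequency <- function(freqs, locus, alleles) {
  n <- attr(freqs, "population_size") %||% 100L
  floor_f <- 5 / (2 * n)
  sub <- freqs[freqs$locus == locus, , drop = FALSE]
  f <- sub$frequency[match(alleles, sub$allele)]
  f[is.na(f) | f <= 0] <- floor_f
  f
}

## ---- TSV persistence ---------------------------------------------------

#' Frequency-table and truth-profile TSV input/output
#'
#' Frequency tables are TSV with columns `locus`, `allele`, `frequency` (a
#' `# population_size=N` header comment carries N). Truth tables are TSV with
#' columns `sample`, `locus`, `allele1`, `allele2`; truth files are the only
#' place the simulator records genotypes, and the caller never reads them.
#'
#' @param freqs,profiles objects to write.
#' @param path file path.
#' @name freq_tsv
#' @export
write_freq_tsv <- function(freqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# population_size=%d",
                     attr(freqs, "population_size") %||% 100L), con)
  write.table(freqs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname freq_tsv
#' @export
read_freq_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  n <- if (grepl("^# population_size=", first)) {
    as.integer(sub("^# population_size=", "", first))
  } else 100L
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  attr(df, "population_size") <- n
  class(df) <- c("allele_freqs", "data.frame")
  df
}

#' @rdname freq_tsv
#' @export
write_truth_tsv <- function(profiles, path) {
  if (inherits(profiles, "genotype_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample = p$sample_id, locus = names(p$genotypes),
               allele1 = vapply(p$genotypes, `[`, "", 1L),
               allele2 = vapply(p$genotypes, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname freq_tsv
#' @export
read_truth_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  lapply(split(df, df$sample), function(sub) {
    g <- lapply(seq_len(nrow(sub)), function(i) {
      sort(c(sub$allele1[i], sub$allele2[i]))
    })
    names(g) <- sub$locus
    structure(list(sample_id = sub$sample[1L], genotypes = g),
              class = "genotype_profile")
  })
}
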