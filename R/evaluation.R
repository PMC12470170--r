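#' Score a deconvolution against known contributor profiles
#'
#' Each (locus, contributor) call is classified `Correct` when the call is
#' determinate and equals the truth genotype, `Wrong` when determinate with
#' at least one wrongly predicted allele, and `Undetermined` otherwise
#' (posterior below the threshold or proposed drop-out). Truth contributors
#' are matched to fitted contributors by proportion rank; within groups of
#' equal truth proportions every pairing is tried and the one minimising
#' the number of Wrong calls is kept.
#'
#' @param deconv an `mps_deconv`.
#' @param truth list of `genotype_profile`s, one per contributor.
#' @param truth_proportions contributor proportions the mixture was built
#'   with (same order as `truth`).
#' @return data frame of evaluation records: `locus`, `contributor`
#'   (fitted index), `truth_sample`, `called`, `truth`, `classification`.
#' @export
classify_deconvolution <- function(deconv, truth, truth_proportions) {
  stopifnot(inherits(deconv, "mps_deconv"))
  if (length(truth) != deconv$noc) {
    stopf("%d truth profiles supplied for a %d-contributor deconvolution",
          length(truth), deconv$noc)
  }
  calls <- deconv$calls
  ## candidate truth->fitted assignments: rank by proportion, permute ties
  groups <- split(seq_along(truth),
                  match(truth_proportions, sort(unique(truth_proportions),
                                                decreasing = TRUE)))
  perms <- tie_permutations(groups, length(truth))
  best <- NULL
  for (assign in perms) {
    rec <- score_assignment(calls, truth, assign)
    nw <- sum(rec$classification == "Wrong")
    if (is.null(best) || nw < best$nw) best <- list(rec = rec, nw = nw)
  }
  best$rec
}

## all assignments truth index -> fitted contributor slot that respect the
## proportion ranking but permute equal-proportion groups
tie_permutations <- function(groups, n) {
  slot_groups <- list()
  slot <- 1L
  out <- list(integer(n))
  for (g in groups) {
    slots <- seq.int(slot, slot + length(g) - 1L)
    slot <- slot + length(g)
    perms <- permutations_of(slots)
    out <- unlist(lapply(out, function(a) {
      lapply(perms, function(p) { a[g] <- p; a })
    }), recursive = FALSE)
  }
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  unlist(lapply(seq_along(x), function(i) {
    lapply(permutations_of(x[-i]), function(p) c(x[i], p))
  }), recursive = FALSE)
}

score_assignment <- function(calls, truth, assign) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    k <- calls$contributor[i]
    t_idx <- which(assign == k)
    tg <- truth[[t_idx]]$genotypes[[calls$locus[i]]]
    tg <- sort(tg)
    if (!calls$determinate[i]) {
      cls <- "Undetermined"
    } else {
      cg <- sort(c(calls$allele1[i], calls$allele2[i]))
      cls <- if (identical(cg, tg)) "Correct" else "Wrong"
    }
    data.frame(locus = calls$locus[i], contributor = k,
               truth_sample = truth[[t_idx]]$sample_id,
               called = if (calls$determinate[i])
                 paste(calls$allele1[i], calls$allele2[i], sep = "/")
               else "Undetermined",
               truth = paste(tg, collapse = "/"),
               classification = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus of duplicate deconvolutions
#'
#' Merges two independent deconvolutions of the same mixture: a consensus
#' genotype exists only where both replicates made identical determinate
#' calls; any disagreement, or an Undetermined call on either side, yields
#' Undetermined.
#'
#' @param r1,r2 `mps_deconv` objects for duplicate typings.
#' @return data frame of class `consensus_profile`: `locus`, `contributor`,
#'   `allele1`, `allele2`, `determinate`.
#' @export
consensus <- function(r1, r2) {
  stopifnot(inherits(r1, "mps_deconv"), inherits(r2, "mps_deconv"))
  key <- function(x) paste(x$calls$locus, x$calls$contributor)
  if (!setequal(key(r1), key(r2)) || r1$noc != r2$noc) {
    stopf("duplicate deconvolutions cover different loci or contributors")
  }
  c2 <- r2$calls[match(key(r1), key(r2)), , drop = FALSE]
  c1 <- r1$calls
  agree <- c1$determinate & c2$determinate &
    c1$allele1 == c2$allele1 & c1$allele2 == c2$allele2
  out <- data.frame(locus = c1$locus, contributor = c1$contributor,
                    allele1 = ifelse(agree, c1$allele1, NA_character_),
                    allele2 = ifelse(agree, c1$allele2, NA_character_),
                    determinate = agree, stringsAsFactors = FALSE)
  class(out) <- c("consensus_profile", "data.frame")
  out
}

#' Random match probability of a (partial) profile
#'
#' Product over determinate loci of the HWE genotype frequency: p^2 for a
#' homozygote, 2pq for a heterozygote, with the rare-allele floor for
#' alleles missing from the table. Undetermined loci contribute a factor 1,
#' so an empty profile has RMP 1.
#'
#' @param profile a `consensus_profile` (or any data frame with `locus`,
#'   `allele1`, `allele2`, `determinate`).
#' @param freqs an `allele_freqs` table.
#' @param contributor restrict to one contributor index (default: all rows).
#' @return probability in (0, 1].
#' @export
random_match_probability <- function(profile, freqs, contributor = NULL) {
  df <- as.data.frame(profile)
  if (!is.null(contributor)) df <- df[df$contributor == contributor, ,
                                      drop = FALSE]
  df <- df[df$determinate, , drop = FALSE]
  if (!nrow(df)) return(1)
  rmp <- 1
  for (i in seq_len(nrow(df))) {
    p <- allele_frequency(freqs, df$locus[i], df$allele1[i])
    q <- allele_frequency(freqs, df$locus[i], df$allele2[i])
    rmp <- rmp * if (df$allele1[i] == df$allele2[i]) p * p else 2 * p * q
  }
  rmp
}

#' Compare MH and STR contributor-proportion estimates
#'
#' Tests whether one assay estimates mixture proportions more accurately
#' than the other: per-group Shapiro-Wilk normality p-values are reported
#' (not used for gating), and a two-sided Wilcoxon rank sum test is run on
#' the absolute deviations of the estimated major/minor ratios from the
#' expected ratio.
#'
#' @param mh_ratios,str_ratios estimated major/minor ratios per mixture.
#' @param expected_ratio the designed ratio (e.g. 1 for 1:1 mixtures).
#' @return list with `shapiro_p` (named vector, `NA` for degenerate
#'   constant groups), `wilcoxon_p`, and the group deviations.
#' @export
compare_proportion_estimates <- function(mh_ratios, str_ratios,
                                         expected_ratio = 1) {
  if (length(mh_ratios) < 3L || length(str_ratios) < 3L) {
    stopf("need at least 3 ratios per group")
  }
  dev_mh <- abs(mh_ratios - expected_ratio)
  dev_str <- abs(str_ratios - expected_ratio)
  sw <- function(x) {
    if (length(unique(x)) < 3L) return(NA_real_)  # degenerate for Shapiro-Wilk
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  w <- suppressWarnings(wilcox.test(dev_mh, dev_str, exact = FALSE))
  list(shapiro_p = c(mh = sw(mh_ratios), str = sw(str_ratios)),
       wilcoxon_p = w$p.value,
       deviations = list(mh = dev_mh, str = dev_str))
}

#' Summarise evaluation records into success-rate tables
#'
#' Produces the per-(ratio, contributor) percentages of Correct, Wrong and
#' Undetermined genotype calls (rows sum to 100), plus the overall error
#' rate wrong/total.
#'
#' @param records evaluation records from [classify_deconvolution()], with a
#'   `ratio` column added by the caller.
#' @return list with `table` (data frame; percentages to one decimal),
#'   `wrong`, `total`, `error_rate_pct`.
#' @export
summarize_records <- function(records) {
  stopifnot(all(c("ratio", "contributor", "classification") %in%
                  names(records)))
  cells <- split(records, list(records$ratio, records$contributor),
                 drop = TRUE)
  tab <- do.call(rbind, lapply(cells, function(sub) {
    n <- nrow(sub)
    data.frame(ratio = sub$ratio[1L], contributor = sub$contributor[1L],
               n = n,
               pct_correct = round(100 * mean(sub$classification == "Correct"), 1),
               pct_wrong = round(100 * mean(sub$classification == "Wrong"), 1),
               pct_undetermined = round(100 * mean(sub$classification ==
                                                     "Undetermined"), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab <- tab[order(tab$ratio, tab$contributor), , drop = FALSE]
  wrong <- sum(records$classification == "Wrong")
  total <- nrow(records)
  list(table = tab, wrong = wrong, total = total,
       error_rate_pct = round(100 * wrong / total, 1))
}
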