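#' Deconvolute a mixture into per-contributor genotypes
#'
#' Fits the all-unknown hypothesis ("the sample consists of DNA from
#' `noc` unknown individuals") by maximum likelihood and, at the fitted
#' parameters, computes for every locus the posterior probability of each
#' contributor's genotype, marginalised over the other contributors, with
#' Hardy-Weinberg priors. The top genotype per (locus, contributor) is
#' reported with its posterior; a call is determinate only if the posterior
#' is not below `p_threshold` (default 0.9 -- a posterior of exactly 0.9 is
#' reported) and the genotype proposes no drop-out.
#'
#' @param counts an `allele_counts` table for the mixture.
#' @param noc number of contributors (2 or 3).
#' @param calib an `mps_calibration`.
#' @param freqs an `allele_freqs` table.
#' @param p_threshold posterior probability threshold (default 0.9).
#' @param ... passed to [fit_mixture()].
#' @return object of class `mps_deconv`: the `fit` plus a `calls` data frame
#'   (locus, contributor, allele1, allele2, posterior, dropout, determinate),
#'   contributors indexed in descending fitted-proportion order.
#' @export
deconvolute <- function(counts, noc, calib, freqs, p_threshold = 0.9, ...) {
  if (!noc %in% c(1L, 2L, 3L)) stopf("noc must be 1, 2 or 3")
  hyp <- hypothesis(noc)
  fit <- fit_mixture(counts, hyp, calib, freqs, ...)
  calls <- deconv_calls(fit, p_threshold)
  structure(list(fit = fit, calls = calls, p_threshold = p_threshold,
                 noc = noc, sample_id = counts$sample_id),
            class = "mps_deconv")
}

## A call is reported only when its posterior is not below the threshold
## (exactly 0.9 is reported) and no drop-out is proposed.
is_determinate <- function(posterior, dropout, p_threshold) {
  posterior >= p_threshold & !dropout
}

deconv_calls <- function(fit, p_threshold) {
  noc <- fit$hypothesis$noc
  rows <- list()
  for (ctx in fit$contexts) {
    w <- fit$omega_raw
    ll <- ctx$logprior + context_row_loglik(ctx, w, fit$mu, fit$theta)
    post <- exp(ll - log_sum_exp(ll))
    for (u in seq_len(ctx$n_unknown)) {
      orig_k <- ctx$n_known + u
      marg <- tapply(post, ctx$joint_idx[, u], sum)
      top <- which.max(marg)
      gt <- ctx$gts[[as.integer(names(marg)[top])]]
      rows[[length(rows) + 1L]] <- data.frame(
        locus = ctx$locus,
        contributor = fit$order[orig_k],
        allele1 = gt[1L], allele2 = gt[2L],
        posterior = unname(marg[top]),
        dropout = DROPOUT_SYMBOL %in% gt,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  calls$determinate <- is_determinate(calls$posterior, calls$dropout,
                                      p_threshold)
  calls <- calls[order(calls$locus, calls$contributor), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' @export
print.mps_deconv <- function(x, ...) {
  det <- sum(x$calls$determinate)
  cat(sprintf("<mps_deconv> %s: NOC=%d, omega=(%s)\n", x$sample_id, x$noc,
              paste(sprintf("%.3f", x$fit$omega), collapse = ", ")))
  cat(sprintf("  %d/%d (locus, contributor) calls determinate at p >= %.2f\n",
              det, nrow(x$calls), x$p_threshold))
  invisible(x)
}

#' Likelihood ratio for a suspect hypothesis
#'
#' Computes LR = P(E | Hp) / P(E | Hd) where Hp conditions on the suspect
#' plus `noc - 1` unknown contributors and Hd has `noc` unknowns, each
#' maximised separately over proportions, depth and dispersion. Reported on
#' the log10 scale; a numerator likelihood that underflows to zero yields
#' `-Inf` (LR = 0).
#'
#' @param counts an `allele_counts` table for the mixture.
#' @param suspect the suspect's `genotype_profile`.
#' @param noc number of contributors under both hypotheses.
#' @param calib an `mps_calibration`.
#' @param freqs an `allele_freqs` table.
#' @param hd_fit optional precomputed all-unknown `mps_fit` for this mixture
#'   (the Hd fit is suspect-independent, so it can be shared across a
#'   suspect panel).
#' @param ... passed to [fit_mixture()].
#' @return object of class `mps_lr`: `log10_lr`, `logL_hp`, `logL_hd`,
#'   `per_locus` (log10 LR terms summing to the total), fits.
#' @export
likelihood_ratio <- function(counts, suspect, noc, calib, freqs,
                             hd_fit = NULL, ...) {
  stopifnot(inherits(suspect, "genotype_profile"))
  missing_alleles <- unlist(lapply(names(calib$locus_efficiency), function(l) {
    g <- suspect$genotypes[[l]]
    known <- freqs$allele[freqs$locus == l & freqs$frequency > 0]
    setdiff(g, known)
  }))
  if (length(missing_alleles)) {
    warning(sprintf(
      "suspect %s carries %d allele(s) absent from the frequency table; rare-allele floor applied",
      suspect$sample_id, length(missing_alleles)), call. = FALSE)
  }
  if (is.null(hd_fit)) {
    hd_fit <- fit_mixture(counts, hypothesis(noc), calib, freqs, ...)
  }
  hp_fit <- fit_mixture(counts, hypothesis(noc, known = list(suspect)),
                        calib, freqs, ...)
  per_locus <- (hp_fit$locus_loglik - hd_fit$locus_loglik) / log(10)
  structure(list(log10_lr = (hp_fit$log_likelihood - hd_fit$log_likelihood) /
                   log(10),
                 logL_hp = hp_fit$log_likelihood,
                 logL_hd = hd_fit$log_likelihood,
                 per_locus = per_locus,
                 suspect_id = suspect$sample_id,
                 noc = noc, hp_fit = hp_fit, hd_fit = hd_fit),
            class = "mps_lr")
}

#' @export
print.mps_lr <- function(x, ...) {
  cat(sprintf("<mps_lr> suspect %s, NOC=%d: log10 LR = %s\n",
              x$suspect_id, x$noc,
              if (is.finite(x$log10_lr)) sprintf("%.2f", x$log10_lr)
              else as.character(x$log10_lr)))
  invisible(x)
}
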