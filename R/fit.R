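#' Mixture hypothesis
#'
#' A hypothesis fixes the number of contributors (NOC) and optionally
#' conditions on known contributor profiles, e.g. Hp "the sample consists of
#' DNA from an unknown contributor and the suspect" (one known, one unknown)
#' versus Hd "the sample consists of DNA from two unknown individuals".
#'
#' @param noc number of contributors.
#' @param known list of `genotype_profile` objects conditioned on (possibly
#'   empty).
#' @return list of class `mps_hypothesis`.
#' @export
hypothesis <- function(noc, known = list()) {
  noc <- check_count(noc, "noc", min = 1L)
  if (inherits(known, "genotype_profile")) known <- list(known)
  if (length(known) > noc) stopf("more known contributors than contributors")
  structure(list(noc = noc, known = known,
                 n_unknown = noc - length(known)),
            class = "mps_hypothesis")
}

## contexts for every calibrated locus under a hypothesis
build_contexts <- function(counts, hyp, calib, freqs) {
  loci <- names(calib$locus_efficiency)
  lapply(setNames(loci, loci), function(l) {
    y <- retained_counts(counts, l)
    known_genos <- lapply(hyp$known, function(p) {
      g <- p$genotypes[[l]]
      if (is.null(g)) stopf("known contributor %s lacks locus %s",
                            p$sample_id, l)
      g
    })
    build_locus_context(l, y, known_genos, hyp$n_unknown, calib, freqs)
  })
}

total_loglik <- function(contexts, omega, mu, theta) {
  vapply(contexts, context_loglik, 0, omega = omega, mu = mu, theta = theta)
}

## deterministic simplex grid (10% steps) of starting proportions, sorted
## descending so contributor 1 is the major
omega_grid <- function(noc, step = 0.1) {
  if (noc == 1L) return(list(1))
  grid <- seq(step, 1 - step, by = step)
  pts <- list()
  if (noc == 2L) {
    for (w1 in grid[grid >= 0.5]) pts[[length(pts) + 1L]] <- c(w1, 1 - w1)
  } else {
    for (w1 in grid) for (w2 in grid) {
      w3 <- 1 - w1 - w2
      if (w3 >= step - 1e-9 && w1 >= w2 - 1e-9 && w2 >= w3 - 1e-9) {
        pts[[length(pts) + 1L]] <- c(w1, w2, max(w3, step / 2))
      }
    }
  }
  lapply(pts, function(p) p / sum(p))
}

## unconstrained <-> natural parameter maps (additive log-ratio for omega)
pack_params <- function(omega, mu, theta) {
  k <- length(omega)
  c(if (k > 1L) log(omega[-k] / omega[k]) else numeric(0), log(mu), log(theta))
}

unpack_params <- function(par, noc) {
  if (noc > 1L) {
    z <- c(exp(par[seq_len(noc - 1L)]), 1)
    omega <- z / sum(z)
  } else omega <- 1
  list(omega = omega, mu = exp(par[noc]), theta = exp(par[noc + 1L]))
}

#' Fit a mixture hypothesis by maximum likelihood
#'
#' Maximises, over contributor proportions `omega`, read-depth unit `mu` and
#' dispersion `theta`, the product over loci of the genotype-marginalised
#' read-count likelihood: unknown contributors are summed over all genotype
#' pairs of observed alleles plus drop-out with Hardy-Weinberg priors
#' (exact enumeration). Optimisation is deterministic: a fixed 10%-step grid
#' on the proportion simplex supplies starts, the best of which are refined
#' by Nelder-Mead on log-transformed parameters.
#'
#' @param counts an `allele_counts` table for one mixture.
#' @param hyp an [hypothesis()].
#' @param calib an `mps_calibration`.
#' @param freqs an `allele_freqs` table.
#' @param n_refine number of grid starts refined by Nelder-Mead.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return object of class `mps_fit` with elements `omega` (descending),
#'   `mu`, `theta`, `log_likelihood`, `locus_loglik`, `order` (fitted index
#'   of each original contributor: knowns first, then unknowns),
#'   `hypothesis`, and the per-locus contexts used.
#' @export
fit_mixture <- function(counts, hyp, calib, freqs, n_refine = 2L,
                        maxit = 400L) {
  stopifnot(inherits(counts, "allele_counts"),
            inherits(hyp, "mps_hypothesis"),
            inherits(calib, "mps_calibration"))
  contexts <- build_contexts(counts, hyp, calib, freqs)
  n_loci <- length(contexts)
  mu0 <- max(sum(vapply(contexts, function(c) sum(c$y), 0)) / n_loci, 1)
  theta0 <- max(calib$dispersion, 1e-4)
  noc <- hyp$noc

  objective <- function(par) {
    p <- unpack_params(par, noc)
    if (p$mu <= 0 || !is.finite(p$mu) || p$theta <= 0) return(1e10)
    ll <- sum(total_loglik(contexts, p$omega, p$mu, p$theta))
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- omega_grid(noc)
  start_val <- vapply(starts, function(w) {
    objective(pack_params(w, mu0, theta0))
  }, 0)
  ord <- order(start_val)
  best <- NULL
  for (i in ord[seq_len(min(n_refine, length(ord)))]) {
    fit <- optim(pack_params(starts[[i]], mu0, theta0), objective,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stopf("mixture fit failed to converge from any start")
  }
  p <- unpack_params(best$par, noc)
  ## report contributors in descending omega order (ties: original order)
  perm <- order(-p$omega, seq_along(p$omega))
  omega <- p$omega[perm]
  locus_ll <- total_loglik(contexts, p$omega, p$mu, p$theta)
  structure(list(omega = omega, mu = p$mu, theta = p$theta,
                 log_likelihood = sum(locus_ll),
                 locus_loglik = locus_ll,
                 order = match(seq_along(p$omega), perm),
                 omega_raw = p$omega,
                 hypothesis = hyp, contexts = contexts,
                 sample_id = counts$sample_id,
                 convergence = best$convergence),
            class = "mps_fit")
}

#' @export
print.mps_fit <- function(x, ...) {
  cat(sprintf("<mps_fit> %s: NOC=%d (%d known), logL=%.2f\n",
              x$sample_id, x$hypothesis$noc, length(x$hypothesis$known),
              x$log_likelihood))
  cat("  omega:", paste(sprintf("%.3f", x$omega), collapse = " "), "\n")
  cat(sprintf("  mu=%.1f reads/locus-unit, theta=%.4g\n", x$mu, x$theta))
  invisible(x)
}

#' @export
coef.mps_fit <- function(object, ...) {
  c(setNames(object$omega, paste0("omega", seq_along(object$omega))),
    mu = object$mu, theta = object$theta)
}

#' @export
logLik.mps_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$omega) - 1L + 2L, class = "logLik")
}

#' @export
summary.mps_fit <- function(object, ...) {
  cat(sprintf("Mixture fit for %s\n", object$sample_id))
  print(object)
  cat("Per-locus log-likelihood quartiles:\n")
  print(stats::quantile(object$locus_loglik))
  invisible(object)
}
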