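## Internal machinery for the mixture likelihood.
##
## Per locus, observed retained read counts are modelled as negative
## binomial with mean
##   E[a] = mu * efficiency(locus) * sum_k omega_k * copies_k(a) / 2
## (mu = expected reads per locus unit, omega the contributor proportions),
## redistributed by the calibrated stutter proportions for STR loci. Alleles
## proposed by a genotype but not observed contribute the probability of
## falling below the analytical threshold (drop-out); the symbol Q stands
## for any unobserved allele of an unknown contributor, and all Q copies at
## a locus are pooled into one drop-out category. Retained alleles that no
## genotype or stutter explains are treated as noise: their number per locus
## is Poisson(noise_rate) and their counts geometric above the threshold.

DROPOUT_SYMBOL <- "Q"

#' Enumerate unordered genotypes over observed alleles
#'
#' All unordered pairs over the observed alleles, optionally extended with
#' the drop-out symbol `Q`: A alleles give A(A+1)/2 genotypes, or
#' (A+1)(A+2)/2 with drop-out.
#'
#' @param observed_alleles character vector of allele ids.
#' @param allow_dropout include the drop-out symbol `Q`.
#' @return list of sorted character pairs (Q sorts last).
#' @export
enumerate_genotypes <- function(observed_alleles, allow_dropout = TRUE) {
  alleles <- unique(as.character(observed_alleles))
  if (allow_dropout) alleles <- c(alleles, DROPOUT_SYMBOL)
  if (length(alleles) == 0L) {
    stopf("no observed alleles and drop-out not allowed: nothing to enumerate")
  }
  out <- list()
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
    }
  }
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

str_parent_id <- function(allele) {
  m <- regmatches(allele, regexec("^\\[([ACGT]+)\\]([0-9]+)$", allele))[[1]]
  if (length(m) != 3L) return(NA_character_)
  sprintf("[%s]%d", m[2], as.integer(m[3]) + 1L)
}

## Build the fixed per-locus structures used by every likelihood evaluation:
## category table (observed + known-contributor alleles, plus a pooled Q
## column), copy matrices per contributor over all joint unknown-genotype
## assignments, HWE log-priors, and stutter redistribution edges.
build_locus_context <- function(locus, y, known_genos, n_unknown, calib,
                                freqs, max_alleles = 8L) {
  obs <- names(y)
  if (length(obs) > max_alleles) {          # documented enumeration cap
    keep <- names(sort(y, decreasing = TRUE))[seq_len(max_alleles)]
    y <- y[keep]
    obs <- keep
  }
  known_alleles <- setdiff(unique(unlist(known_genos)), DROPOUT_SYMBOL)
  cats <- unique(c(obs, known_alleles))
  ncat <- length(cats)
  ycat <- setNames(numeric(ncat), cats)
  ycat[obs] <- y

  gts <- enumerate_genotypes(obs, allow_dropout = TRUE)
  n_gt <- length(gts)
  joint_idx <- if (n_unknown > 0L) {
    as.matrix(expand.grid(rep(list(seq_len(n_gt)), n_unknown)))
  } else {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  }
  n_joint <- nrow(joint_idx)

  ## copies of each category (+Q last column) per genotype
  gt_copies <- matrix(0, nrow = n_gt, ncol = ncat + 1L,
                      dimnames = list(NULL, c(cats, DROPOUT_SYMBOL)))
  for (g in seq_len(n_gt)) {
    for (a in gts[[g]]) gt_copies[g, a] <- gt_copies[g, a] + 1
  }

  noc <- length(known_genos) + n_unknown
  copies <- vector("list", noc)
  for (k in seq_along(known_genos)) {
    row <- setNames(numeric(ncat + 1L), c(cats, DROPOUT_SYMBOL))
    for (a in known_genos[[k]]) row[a] <- row[a] + 1
    copies[[k]] <- matrix(rep(row, each = n_joint), nrow = n_joint,
                          dimnames = list(NULL, names(row)))
  }
  for (u in seq_len(n_unknown)) {
    copies[[length(known_genos) + u]] <- gt_copies[joint_idx[, u], ,
                                                   drop = FALSE]
  }

  ## HWE log-prior of each unknown genotype; Q carries the residual frequency
  f <- allele_frequency(freqs, locus, cats)
  f_q <- max(1 - sum(f), 5 / (2 * (attr(freqs, "population_size") %||% 100L)))
  fr <- setNames(c(f, f_q), c(cats, DROPOUT_SYMBOL))
  gt_logprior <- vapply(gts, function(g) {
    if (g[1L] == g[2L]) 2 * log(fr[g[1L]]) else
      log(2) + log(fr[g[1L]]) + log(fr[g[2L]])
  }, 0)
  logprior <- if (n_unknown > 0L) {
    rowSums(matrix(gt_logprior[joint_idx], nrow = n_joint))
  } else rep(0, n_joint)

  ## stutter edges: parent category -> one-repeat-shorter category
  stutter_from <- integer(0); stutter_to <- integer(0); stutter_s <- numeric(0)
  if (identical(calib$panel_kind, "STR")) {
    for (i in seq_len(ncat)) {
      r <- bracketed_repeat_number(cats[i])
      if (r < 2L) next
      s <- stutter_expected(calib, locus, r)
      if (s <= 0) next
      child <- sub(sprintf("\\]%d$", r), sprintf("]%d", r - 1L), cats[i])
      j <- match(child, cats)
      stutter_from <- c(stutter_from, i)
      stutter_to <- c(stutter_to, ifelse(is.na(j), NA_integer_, j))
      stutter_s <- c(stutter_s, s)
    }
  }

  list(locus = locus, cats = cats, y = ycat,
       eff = unname(calib$locus_efficiency[locus]),
       at = calib$analytical_threshold,
       noise_rate = calib$noise_rate, noise_geom_p = calib$noise_geom_p,
       gts = gts, joint_idx = joint_idx, copies = copies,
       logprior = logprior,
       stutter_from = stutter_from, stutter_to = stutter_to,
       stutter_s = stutter_s,
       n_unknown = n_unknown, n_known = length(known_genos))
}

## Expected-count matrix (n_joint x ncat+Q) at given parameters, with
## stutter redistribution applied.
context_expected <- function(ctx, omega, mu) {
  E <- ctx$copies[[1L]] * omega[1L]
  if (length(ctx$copies) > 1L) {
    for (k in 2L:length(ctx$copies)) E <- E + ctx$copies[[k]] * omega[k]
  }
  E <- E * (mu * ctx$eff / 2)
  if (length(ctx$stutter_from)) {
    for (i in seq_along(ctx$stutter_from)) {
      p <- ctx$stutter_from[i]; ch <- ctx$stutter_to[i]; s <- ctx$stutter_s[i]
      shed <- E[, p] * s
      E[, p] <- E[, p] - shed
      if (!is.na(ch)) E[, ch] <- E[, ch] + shed
    }
  }
  E
}

## Log-likelihood of every joint genotype assignment (vector over rows of
## ctx$joint_idx), excluding the genotype prior.
context_row_loglik <- function(ctx, omega, mu, theta) {
  E <- context_expected(ctx, omega, mu)
  size <- 1 / theta
  n_joint <- nrow(E)
  ll <- numeric(n_joint)
  n_unexplained <- integer(n_joint)
  at <- ctx$at
  for (j in seq_len(ncol(E))) {
    a <- colnames(E)[j]
    yj <- if (a == DROPOUT_SYMBOL) 0 else ctx$y[a]
    e <- E[, j]
    pos <- e > 0
    if (yj > 0) {
      contrib <- numeric(n_joint)
      contrib[pos] <- dnbinom(yj, size = size, mu = e[pos], log = TRUE)
      if (any(!pos)) {   # unexplained allele: noise candidate
        contrib[!pos] <- dgeom(max(yj - at, 0), ctx$noise_geom_p, log = TRUE)
        n_unexplained[!pos] <- n_unexplained[!pos] + 1L
      }
      ll <- ll + contrib
    } else {
      if (any(pos)) {    # proposed allele not observed: drop-out
        contrib <- numeric(n_joint)
        contrib[pos] <- pnbinom(at - 1, size = size, mu = e[pos],
                                log.p = TRUE)
        ll <- ll + contrib
      }
    }
  }
  ll + dpois(n_unexplained, ctx$noise_rate, log = TRUE)
}

context_loglik <- function(ctx, omega, mu, theta) {
  log_sum_exp(ctx$logprior + context_row_loglik(ctx, omega, mu, theta))
}

#' Per-locus log-likelihood of a full genotype set
#'
#' Evaluates the read-count model for one locus given a concrete genotype
#' for every contributor (drop-out symbol `Q` allowed for unknowns): the
#' expected count of each allele is proportional to locus efficiency and the
#' omega-weighted allele copies, STR stutter mass is moved to the
#' one-repeat-shorter sequence, observed counts are negative binomial with
#' dispersion `theta`, proposed-but-unseen alleles contribute the
#' probability of falling below the analytical threshold, and unexplained
#' observed alleles contribute the calibrated noise likelihood.
#'
#' @param counts named integer vector of retained read counts at the locus.
#' @param genotypes list of character pairs, one per contributor.
#' @param omega contributor proportions (simplex, one per contributor).
#' @param mu expected reads per locus unit (> 0).
#' @param theta negative binomial overdispersion (> 0).
#' @param calib an `mps_calibration`.
#' @param locus locus name.
#' @param freqs an `allele_freqs` table (used only to define the allele
#'   universe; the genotype prior is not included).
#' @return log-likelihood (natural log).
#' @export
locus_log_likelihood <- function(counts, genotypes, omega, mu, theta,
                                 calib, locus, freqs) {
  stopifnot(abs(sum(omega) - 1) < 1e-9, mu > 0, theta > 0,
            length(genotypes) == length(omega))
  known <- !vapply(genotypes, function(g) DROPOUT_SYMBOL %in% g, TRUE)
  universe <- c(names(counts), DROPOUT_SYMBOL)
  bad <- setdiff(unlist(genotypes), universe)
  if (length(bad)) {
    known_al <- freqs$allele[freqs$locus == locus]
    if (!all(bad %in% known_al)) {
      stopf("allele '%s' unknown at locus %s", setdiff(bad, known_al)[1L],
            locus)
    }
  }
  ## treat every contributor as "known" with the stated genotype; Q-carrying
  ## genotypes are routed through a single unknown enumeration row
  ctx <- build_locus_context(locus, counts, genotypes, n_unknown = 0L,
                             calib = calib, freqs = freqs)
  context_row_loglik(ctx, omega, mu, theta)[1L]
}
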