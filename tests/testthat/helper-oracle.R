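# Independent oracles: small, slow, loop-based implementations used to
# freeze expected values. They share no code with the package internals.

# Exact-rational largest-remainder apportionment over integer ratio parts.
oracle_apportion <- function(total, parts) {
  den <- sum(parts)
  num <- total * parts
  base <- num %/% den
  rem <- num %% den
  left <- total - sum(base)
  ord <- order(-rem, seq_along(parts))
  if (left > 0) base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  as.integer(base)
}

# Regex-based run-length bracketing of a repeat region.
oracle_bracket <- function(region, motif) {
  runs <- gregexpr(sprintf("(?:%s)+", motif), region)[[1]]
  if (runs[1] == -1) return(NULL)
  lens <- attr(runs, "match.length")
  toks <- character(0)
  pos <- 1L
  total <- 0L
  for (i in seq_along(runs)) {
    if (runs[i] > pos) {
      toks <- c(toks, substr(region, pos, runs[i] - 1L))
    }
    k <- lens[i] %/% nchar(motif)
    toks <- c(toks, sprintf("[%s]%d", motif, k))
    total <- total + k
    pos <- runs[i] + lens[i]
  }
  if (pos <= nchar(region)) toks <- c(toks, substr(region, pos, nchar(region)))
  list(bracketed = paste(toks, collapse = " "), repeat_number = total)
}

# Scalar-loop log-likelihood of one locus for a concrete genotype set
# (no stutter; MH-style locus). Mirrors the model definition, not the code.
oracle_set_loglik <- function(y, genotypes, omega, mu, theta, eff, at,
                              noise_rate, noise_geom_p) {
  cats <- unique(c(names(y), setdiff(unlist(genotypes), "Q")))
  e <- setNames(rep(0, length(cats)), cats)
  e_q <- 0
  for (k in seq_along(genotypes)) {
    for (a in genotypes[[k]]) {
      if (a == "Q") e_q <- e_q + omega[k] * mu * eff / 2
      else e[a] <- e[a] + omega[k] * mu * eff / 2
    }
  }
  ll <- 0
  n_noise <- 0L
  for (a in cats) {
    ya <- if (a %in% names(y)) y[[a]] else 0
    if (ya > 0 && e[a] > 0) {
      ll <- ll + dnbinom(ya, size = 1 / theta, mu = e[a], log = TRUE)
    } else if (ya > 0) {
      ll <- ll + dgeom(max(ya - at, 0), noise_geom_p, log = TRUE)
      n_noise <- n_noise + 1L
    } else if (e[a] > 0) {
      ll <- ll + pnbinom(at - 1, size = 1 / theta, mu = e[a], log.p = TRUE)
    }
  }
  if (e_q > 0) ll <- ll + pnbinom(at - 1, size = 1 / theta, mu = e_q,
                                  log.p = TRUE)
  ll + dpois(n_noise, noise_rate, log = TRUE)
}

# Brute-force two-contributor marginalisation: enumerates every genotype
# pair over observed alleles plus Q with HWE priors, returns the marginal
# log-likelihood and each contributor's per-genotype posterior.
oracle_marginal_2p <- function(y, omega, mu, theta, eff, at, noise_rate,
                               noise_geom_p, f, f_q) {
  syms <- c(names(y), "Q")
  fr <- c(f, Q = f_q)
  gts <- list()
  for (i in seq_along(syms)) for (j in i:length(syms)) {
    gts[[length(gts) + 1L]] <- c(syms[i], syms[j])
  }
  prior <- vapply(gts, function(g) {
    if (g[1] == g[2]) fr[[g[1]]]^2 else 2 * fr[[g[1]]] * fr[[g[2]]]
  }, 0)
  n <- length(gts)
  logw <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    logw[i, j] <- log(prior[i]) + log(prior[j]) +
      oracle_set_loglik(y, list(gts[[i]], gts[[j]]), omega, mu, theta,
                        eff, at, noise_rate, noise_geom_p)
  }
  m <- max(logw)
  w <- exp(logw - m)
  z <- sum(w)
  list(gts = gts,
       loglik = m + log(z),
       post1 = rowSums(w) / z,
       post2 = colSums(w) / z)
}

# Minimal fit-shaped object for evaluating posteriors at fixed parameters.
fake_fit_2p <- function(ctx, omega, mu, theta) {
  perm <- order(-omega, seq_along(omega))
  structure(list(omega = omega[perm],
                 omega_raw = omega, mu = mu, theta = theta,
                 order = match(seq_along(omega), perm),
                 hypothesis = hypothesis(length(omega)),
                 contexts = list(ctx), sample_id = "fake"),
            class = "mps_fit")
}
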