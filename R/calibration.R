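#' Assign calibration dose values to called alleles
#'
#' Labels every retained allele of a single-source sample with its "dose":
#' 0 for alleles absent from the known genotype (noise or stutter), 1 for
#' each allele of a heterozygous locus, and 2 for the allele of a
#' homozygous locus. STR dose-0 alleles exactly one repeat below a genotype
#' allele are flagged as stutter candidates so the noise and stutter models
#' are fitted on disjoint data.
#'
#' @param profile the sample's known `genotype_profile`.
#' @param counts the sample's `allele_counts`.
#' @param panel the `locus_panel` (used to recognise stutter positions).
#' @return data frame with columns `sample`, `locus`, `allele`, `count`,
#'   `dose`, `stutter_candidate`.
#' @export
assign_dose <- function(profile, counts, panel) {
  stopifnot(inherits(profile, "genotype_profile"),
            inherits(counts, "allele_counts"))
  ret <- counts$counts[counts$counts$status == "retained", , drop = FALSE]
  missing <- setdiff(unique(ret$locus), names(profile$genotypes))
  if (length(missing)) {
    stopf("no truth genotype for called locus %s (sample %s)",
          missing[1L], counts$sample_id)
  }
  dose <- integer(nrow(ret))
  stut <- logical(nrow(ret))
  for (i in seq_len(nrow(ret))) {
    g <- profile$genotypes[[ret$locus[i]]]
    hits <- sum(g == ret$allele[i])
    dose[i] <- if (hits == 0L) 0L else if (g[1L] == g[2L]) 2L else 1L
    if (dose[i] == 0L && panel$loci[[ret$locus[i]]]$kind == "STR") {
      r <- bracketed_repeat_number(ret$allele[i])
      motif <- panel$loci[[ret$locus[i]]]$repeat_motif
      stut[i] <- sprintf("[%s]%d", motif, r + 1L) %in% g
    }
  }
  data.frame(sample = counts$sample_id, locus = ret$locus,
             allele = ret$allele, count = ret$count, dose = dose,
             stutter_candidate = stut, stringsAsFactors = FALSE)
}

#' Calibrate the per-panel read-count model
#'
#' Estimates, from single-source samples with known genotypes, the
#' quantities the deconvolution likelihood needs:
#' \itemize{
#'   \item locus efficiency: each locus's mean share of a sample's assigned
#'     reads, normalised to mean 1 across loci;
#'   \item dispersion: method-of-moments negative binomial overdispersion of
#'     genotype-allele counts about their efficiency-scaled expectation;
#'   \item noise: rate of dose-0 (non-stutter) alleles per locus-sample, and
#'     a geometric law for their read counts above the analytical threshold;
#'   \item STR stutter: per locus, a linear model of the stutter proportion
#'     `stutter/(stutter+parent)` against parent repeat number, falling back
#'     to the panel-wide pooled proportion when a locus has fewer than three
#'     informative points.
#' }
#'
#' @param samples list of `list(profile=, counts=)` pairs, all from the same
#'   panel (at least 2).
#' @param panel the `locus_panel`.
#' @param analytical_threshold threshold used at calling time (default 11).
#' @return object of class `mps_calibration`.
#' @export
calibrate_model <- function(samples, panel, analytical_threshold = 11L) {
  if (length(samples) < 2L) stopf("calibration needs at least 2 samples")
  stopifnot(inherits(panel, "locus_panel"))
  loci <- names(panel$loci)
  n_loci <- length(loci)

  dosed <- lapply(samples, function(s) {
    assign_dose(s$profile, s$counts, panel)
  })

  ## locus efficiency: mean per-sample share of retained reads, scaled to
  ## mean 1 over loci
  share <- sapply(dosed, function(d) {
    tot <- tapply(d$count, factor(d$locus, levels = loci), sum)
    tot[is.na(tot)] <- 0
    tot / sum(tot)
  })
  eff <- rowMeans(share) * n_loci
  eff <- setNames(as.numeric(eff / mean(eff)), loci)

  ## dispersion from genotype-allele counts vs their expectation
  num <- 0; den <- 0
  for (d in dosed) {
    gen <- d[d$dose > 0L, , drop = FALSE]
    if (!nrow(gen)) next
    mu_s <- sum(d$count) / n_loci
    e <- mu_s * eff[gen$locus] * gen$dose / 2
    num <- num + sum((gen$count - e)^2 - e)
    den <- den + sum(e^2)
  }
  dispersion <- max(num / max(den, 1e-12), 1e-6)

  ## noise model
  noise <- do.call(rbind, lapply(dosed, function(d) {
    d[d$dose == 0L & !d$stutter_candidate, , drop = FALSE]
  }))
  n_cells <- length(samples) * n_loci
  noise_rate <- nrow(noise) / n_cells
  noise_geom_p <- if (nrow(noise) == 0L) 1 else
    1 / (1 + mean(noise$count - analytical_threshold))

  ## STR stutter regression
  stutter_model <- NULL
  if (panel$kind == "STR") {
    pts <- do.call(rbind, lapply(seq_along(samples), function(i) {
      stutter_points(dosed[[i]], samples[[i]]$profile,
                     samples[[i]]$counts, panel)
    }))
    stutter_model <- fit_stutter_model(pts, loci)
  }

  model <- structure(list(panel_kind = panel$kind,
                          analytical_threshold = as.integer(analytical_threshold),
                          locus_efficiency = eff,
                          dispersion = dispersion,
                          noise_rate = noise_rate,
                          noise_geom_p = noise_geom_p,
                          stutter_model = stutter_model,
                          n_samples = length(samples)),
                     class = "mps_calibration")
  validate_calibration(model)
  model
}

## (parent repeat, stutter proportion) observations for one sample. The
## stutter product of a retained genotype allele is read from the full count
## table including below-threshold rows: restricting to retained stutter
## counts would censor small stutters and bias the proportion upwards.
stutter_points <- function(dosed, profile, counts, panel) {
  gen <- dosed[dosed$dose > 0L, , drop = FALSE]
  if (!nrow(gen)) return(NULL)
  out <- lapply(seq_len(nrow(gen)), function(i) {
    locus <- gen$locus[i]
    if (panel$loci[[locus]]$kind != "STR") return(NULL)
    motif <- panel$loci[[locus]]$repeat_motif
    r_par <- bracketed_repeat_number(gen$allele[i])
    if (r_par < 2L) return(NULL)
    stut_id <- sprintf("[%s]%d", motif, r_par - 1L)
    if (stut_id %in% profile$genotypes[[locus]]) return(NULL)  # composite
    srow <- counts$counts[counts$counts$locus == locus &
                            counts$counts$allele == stut_id, , drop = FALSE]
    s <- if (nrow(srow)) srow$count[1L] else 0L
    data.frame(locus = locus, parent_repeats = r_par,
               proportion = s / (s + gen$count[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

fit_stutter_model <- function(pts, loci) {
  pooled <- if (is.null(pts) || nrow(pts) == 0L) 0 else mean(pts$proportion)
  models <- lapply(loci, function(l) {
    sub <- if (is.null(pts)) NULL else pts[pts$locus == l, , drop = FALSE]
    if (is.null(sub) || nrow(sub) < 3L ||
        length(unique(sub$parent_repeats)) < 2L) {
      rate <- if (is.null(sub) || nrow(sub) == 0L) pooled else
        mean(sub$proportion)
      list(intercept = rate, slope = 0, n_points = NROW(sub))
    } else {
      co <- coef(lm(proportion ~ parent_repeats, data = sub))
      list(intercept = unname(co[1L]), slope = unname(co[2L]),
           n_points = nrow(sub))
    }
  })
  names(models) <- loci
  models
}

## expected stutter proportion for a parent with r repeats, clamped to [0, 0.5)
stutter_expected <- function(model, locus, r) {
  sm <- model$stutter_model[[locus]]
  if (is.null(sm)) return(0)
  min(max(sm$intercept + sm$slope * r, 0), 0.499)
}

validate_calibration <- function(model) {
  if (any(!is.finite(model$locus_efficiency)) ||
      any(model$locus_efficiency <= 0)) {
    stopf("calibration invalid: efficiencies must be positive")
  }
  if (abs(mean(model$locus_efficiency) - 1) > 1e-6) {
    stopf("calibration invalid: efficiencies must have mean 1")
  }
  if (model$noise_geom_p <= 0 || model$noise_geom_p > 1) {
    stopf("calibration invalid: noise_geom_p must be in (0, 1]")
  }
  if (model$dispersion <= 0) stopf("calibration invalid: dispersion <= 0")
  invisible(model)
}

#' @export
print.mps_calibration <- function(x, ...) {
  cat(sprintf("<mps_calibration> %s panel, %d loci, %d samples\n",
              x$panel_kind, length(x$locus_efficiency), x$n_samples))
  cat(sprintf("  AT=%d  dispersion=%.4g  noise rate=%.3g/locus (geom p=%.3g)\n",
              x$analytical_threshold, x$dispersion, x$noise_rate,
              x$noise_geom_p))
  invisible(x)
}

#' Persist a calibration model as JSON
#'
#' Round-trips all real-valued fields losslessly (full double precision);
#' loading refuses files with a different schema version or missing fields.
#'
#' @param model an `mps_calibration`.
#' @param path file path.
#' @name calibration_io
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mps_calibration"))
  validate_calibration(model)
  obj <- unclass(model)
  obj$schema <- "mixdeconv-calibration/1"
  obj$locus_efficiency <- as.list(obj$locus_efficiency)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_io
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stopf("cannot read calibration: %s",
                                            conditionMessage(e)))
  if (!identical(obj$schema, "mixdeconv-calibration/1")) {
    stopf("unrecognised calibration schema in %s", path)
  }
  model <- structure(list(
    panel_kind = obj$panel_kind,
    analytical_threshold = as.integer(obj$analytical_threshold),
    locus_efficiency = unlist(obj$locus_efficiency),
    dispersion = obj$dispersion,
    noise_rate = obj$noise_rate,
    noise_geom_p = obj$noise_geom_p,
    stutter_model = obj$stutter_model,
    n_samples = obj$n_samples), class = "mps_calibration")
  validate_calibration(model)
  model
}
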