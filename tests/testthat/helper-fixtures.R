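# Shared in-code fixtures: tiny panels and cohorts built at test time.

tiny_world <- function(kind = "MH", n_loci = 4L, depth = 8000L,
                       n_alleles = 4L, n_people = 20L, n_cal = 8L,
                       seed = 42L, equal_efficiency = FALSE,
                       read_opts = list()) {
  panel <- build_panel(kind, n_loci, seed = seed,
                       equal_efficiency = equal_efficiency)
  pop <- sample_population(panel, n_alleles, n_people, seed = seed + 1L)
  pars <- function(s) {
    do.call(read_params, c(list(total_reads = depth, seed = s), read_opts))
  }
  cal <- lapply(pop$profiles[seq_len(n_cal)], function(p) {
    r <- generate_reads(p, panel, pars(seed + 100L + match(p$sample_id,
      vapply(pop$profiles, `[[`, "", "sample_id"))))
    list(profile = p, counts = call_alleles(r, panel))
  })
  calib <- calibrate_model(cal, panel)
  list(panel = panel, pop = pop, calib = calib, pars = pars,
       cal_samples = cal)
}

## mixture counts from two donor profiles at given proportions
mix_counts <- function(world, donors, props, depth, seed, label = "mix") {
  rs <- lapply(seq_along(donors), function(i) {
    generate_reads(donors[[i]], world$panel, world$pars(seed + i))
  })
  sp <- mixture_spec(vapply(donors, `[[`, "", "sample_id"), props, depth,
                     seed = seed, label = label)
  mx <- mix_reads(rs, sp)
  call_alleles(mx, world$panel, sample_id = label)
}

## hand-built calibration and frequency objects for likelihood-level tests
manual_calib <- function(loci, kind = "MH", at = 11L, dispersion = 0.02,
                         noise_rate = 0.3, noise_geom_p = 0.2,
                         stutter = NULL) {
  structure(list(panel_kind = kind, analytical_threshold = as.integer(at),
                 locus_efficiency = setNames(rep(1, length(loci)), loci),
                 dispersion = dispersion, noise_rate = noise_rate,
                 noise_geom_p = noise_geom_p,
                 stutter_model = stutter, n_samples = 2L),
            class = "mps_calibration")
}

manual_freqs <- function(locus, alleles, freqs, n = 100L) {
  df <- data.frame(locus = locus, allele = alleles, frequency = freqs,
                   stringsAsFactors = FALSE)
  attr(df, "population_size") <- n
  class(df) <- c("allele_freqs", "data.frame")
  df
}
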