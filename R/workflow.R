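#' Experiment configuration
#'
#' Bundles every setting of the simulation study: panel sizes, cohort
#' sizes, read depths, mixture design scale and the suspect panels for the
#' likelihood-ratio experiments. The full-scale defaults reproduce the
#' design arithmetic of the complete study (45 pairs x 4 ratios and 56
#' triples x 3 ratios per panel, 50 suspects per mixture with exactly one
#' true contributor); the `*_per_ratio` and `suspects_per_mixture` knobs
#' scale the executed study down without changing its structure.
#'
#' @param panels panel kinds to run (`"MH"`, `"STR"` or both).
#' @param n_loci named loci counts per panel kind.
#' @param alleles_per_locus named allele counts per panel kind.
#' @param depth named mixture read depths per panel kind.
#' @param calibration_n single-source samples used for calibration.
#' @param n_donors mixture donors per panel (the design grids need 10).
#' @param two_person_ratios,three_person_ratios design ratio labels.
#' @param pairs_per_ratio,triples_per_ratio executed mixtures per ratio
#'   (full scale: 45 and 56).
#' @param suspects_per_mixture LR jobs per mixture, exactly one of which is
#'   a true contributor (full scale: 50).
#' @param run_three_person execute the three-person arm (the plan always
#'   covers it).
#' @param seed master seed; all stage seeds derive from it.
#' @param read_opts list of overrides passed to [read_params()].
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(panels = c("MH", "STR"),
                              n_loci = c(MH = 74L, STR = 26L),
                              alleles_per_locus = c(MH = 6L, STR = 8L),
                              depth = c(MH = 370000L, STR = 220000L),
                              calibration_n = 50L,
                              n_donors = 10L,
                              two_person_ratios = c("19:1", "9:1", "3:1", "1:1"),
                              three_person_ratios = c("14:5:1", "14:3:3", "9:9:2"),
                              pairs_per_ratio = 45L,
                              triples_per_ratio = 56L,
                              suspects_per_mixture = 50L,
                              run_three_person = FALSE,
                              seed = 1L,
                              read_opts = list()) {
  cfg <- structure(list(panels = panels, n_loci = n_loci,
                        alleles_per_locus = alleles_per_locus, depth = depth,
                        calibration_n = calibration_n, n_donors = n_donors,
                        two_person_ratios = two_person_ratios,
                        three_person_ratios = three_person_ratios,
                        pairs_per_ratio = pairs_per_ratio,
                        triples_per_ratio = triples_per_ratio,
                        suspects_per_mixture = suspects_per_mixture,
                        run_three_person = run_three_person,
                        seed = as.integer(seed), read_opts = read_opts),
                   class = "experiment_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  problems <- character(0)
  if (!all(cfg$panels %in% c("MH", "STR"))) {
    problems <- c(problems, "panels must be MH and/or STR")
  }
  for (fld in c("n_loci", "alleles_per_locus", "depth")) {
    if (!all(cfg$panels %in% names(cfg[[fld]]))) {
      problems <- c(problems, sprintf("%s must name every panel", fld))
    }
  }
  if (cfg$suspects_per_mixture < 1L) {
    problems <- c(problems, "suspects_per_mixture must be >= 1")
  }
  if (cfg$pairs_per_ratio > choose(cfg$n_donors, 2L)) {
    problems <- c(problems, "pairs_per_ratio exceeds available pairs")
  }
  if (cfg$triples_per_ratio > choose(cfg$n_donors, 3L)) {
    problems <- c(problems, "triples_per_ratio exceeds available triples")
  }
  if (length(problems)) {
    stopf("invalid experiment config: %s", paste(problems, collapse = "; "))
  }
  invisible(cfg)
}

#' Plan an experiment: closed-form job accounting
#'
#' Enumerates the study a configuration implies without running it: mixture
#' counts per ratio and panel, LR job counts (one true contributor and
#' `suspects_per_mixture - 1` non-contributors per mixture), the
#' true-contributor role per three-person ratio (minor in 9:9:2, major in
#' 14:3:3, intermediate in 14:5:1), and the genotype-evaluation
#' denominators (two-person mixtures x loci x 2 contributors).
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_manifest`.
#' @export
plan_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  validate_config(config)
  n_panels <- length(config$panels)
  two_per_panel <- config$pairs_per_ratio * length(config$two_person_ratios)
  three_per_panel <- config$triples_per_ratio *
    length(config$three_person_ratios)
  two_total <- two_per_panel * n_panels
  three_total <- three_per_panel * n_panels
  s <- config$suspects_per_mixture
  role_by_ratio <- c("14:5:1" = "intermediate", "14:3:3" = "major",
                     "9:9:2" = "minor")
  genotype_denominators <- setNames(
    vapply(config$panels, function(p) {
      two_per_panel * config$n_loci[[p]] * 2L
    }, 0), config$panels)
  structure(list(
    config = config,
    panels = config$panels,
    two_person = list(
      per_ratio = config$pairs_per_ratio,
      ratios = config$two_person_ratios,
      per_panel = two_per_panel,
      total = two_total,
      lr_jobs = two_total * s,
      true_contributor_jobs = two_total,
      non_contributor_jobs = two_total * (s - 1L),
      genotype_denominators = genotype_denominators),
    three_person = list(
      per_ratio = config$triples_per_ratio,
      ratios = config$three_person_ratios,
      per_panel = three_per_panel,
      total = three_total,
      lr_jobs = three_total * s,
      true_contributor_jobs = three_total,
      non_contributor_jobs = three_total * (s - 1L),
      true_contributor_role = role_by_ratio[config$three_person_ratios]),
    total_deconvolutions = (two_total + three_total) * s),
    class = "experiment_manifest")
}

#' @export
print.experiment_manifest <- function(x, ...) {
  cat(sprintf("<experiment_manifest> %s\n", paste(x$panels, collapse = "+")))
  cat(sprintf("  two-person: %d mixtures (%d/ratio), %d LR jobs (%d non-contributor)\n",
              x$two_person$total, x$two_person$per_ratio,
              x$two_person$lr_jobs, x$two_person$non_contributor_jobs))
  cat(sprintf("  three-person: %d mixtures (%d/ratio), %d LR jobs (%d non-contributor)\n",
              x$three_person$total, x$three_person$per_ratio,
              x$three_person$lr_jobs, x$three_person$non_contributor_jobs))
  cat(sprintf("  total LR deconvolutions: %d\n", x$total_deconvolutions))
  invisible(x)
}

## per-panel world: panel, frequencies, calibration model and profile pools
build_panel_world <- function(config, kind) {
  seed <- derive_seed(config$seed, "world", kind)
  panel <- build_panel(kind, config$n_loci[[kind]], seed = seed)
  n_suspect_pool <- max(config$suspects_per_mixture * 2L, 20L)
  pop <- sample_population(panel, config$alleles_per_locus[[kind]],
                           config$calibration_n + config$n_donors +
                             n_suspect_pool,
                           seed = derive_seed(seed, "pop"))
  idx_cal <- seq_len(config$calibration_n)
  idx_don <- config$calibration_n + seq_len(config$n_donors)
  idx_sus <- (config$calibration_n + config$n_donors + 1L):
    length(pop$profiles)
  rp <- function(sample_seed) {
    do.call(read_params, c(list(total_reads = config$depth[[kind]],
                                seed = sample_seed), config$read_opts))
  }
  cal_samples <- lapply(pop$profiles[idx_cal], function(pr) {
    reads <- generate_reads(pr, panel, rp(derive_seed(seed, "cal",
                                                      pr$sample_id)))
    list(profile = pr, counts = call_alleles(reads, panel))
  })
  calib <- calibrate_model(cal_samples, panel)
  donor_reads <- lapply(pop$profiles[idx_don], function(pr) {
    generate_reads(pr, panel, rp(derive_seed(seed, "donor", pr$sample_id)))
  })
  names(donor_reads) <- vapply(pop$profiles[idx_don], `[[`, "", "sample_id")
  list(kind = kind, panel = panel, freqs = pop$freqs, calib = calib,
       donors = pop$profiles[idx_don], donor_reads = donor_reads,
       suspect_pool = pop$profiles[idx_sus], seed = seed)
}

run_design_arm <- function(world, design, noc, config, progress = FALSE) {
  profiles_by_id <- c(world$donors, world$suspect_pool)
  names(profiles_by_id) <- vapply(profiles_by_id, `[[`, "", "sample_id")
  records <- list(); ratios <- list(); lrs <- list()
  role_of_true <- c("14:5:1" = 2L, "14:3:3" = 1L, "9:9:2" = 3L)
  for (sp in design$specs) {
    if (progress) message("  mixture ", sp$label)
    mix <- mix_reads(world$donor_reads[sp$contributors], sp)
    counts <- call_alleles(mix, world$panel, sample_id = sp$label)
    dec <- deconvolute(counts, noc, world$calib, world$freqs)
    ratio_lab <- sub("^[A-Z]+_", "", sub("_[^_]*\\+.*$", "", sp$label))
    ratio_lab <- gsub("-", ":", ratio_lab)
    truth <- profiles_by_id[sp$contributors]
    rec <- classify_deconvolution(dec, unname(truth), sp$proportions)
    rec$ratio <- ratio_lab
    rec$mixture <- sp$label
    records[[sp$label]] <- rec
    ratios[[sp$label]] <- data.frame(
      mixture = sp$label, ratio = ratio_lab,
      expected = max(sp$proportions) / min(sp$proportions),
      estimated = max(dec$fit$omega) / min(dec$fit$omega),
      stringsAsFactors = FALSE)
    ## LR experiment: one true contributor + non-contributor suspects
    n_sus <- config$suspects_per_mixture
    if (n_sus >= 1L) {
      true_id <- if (noc == 2L) {
        sp$contributors[which.min(sp$proportions)]     # the minor
      } else {
        sp$contributors[role_of_true[[ratio_lab]]]
      }
      pool_ids <- setdiff(vapply(world$suspect_pool, `[[`, "", "sample_id"),
                          sp$contributors)
      non_ids <- pool_ids[seq_len(min(n_sus - 1L, length(pool_ids)))]
      hd <- dec$fit
      for (sid in c(true_id, non_ids)) {
        lr <- likelihood_ratio(counts, profiles_by_id[[sid]], noc,
                               world$calib, world$freqs, hd_fit = hd)
        lrs[[paste(sp$label, sid)]] <- data.frame(
          mixture = sp$label, ratio = ratio_lab, suspect = sid,
          true_contributor = sid == true_id,
          log10_lr = lr$log10_lr, stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, records),
       ratios = do.call(rbind, ratios),
       lrs = do.call(rbind, lrs))
}

#' Run the simulation study end to end
#'
#' For each configured panel: builds the panel and population, generates
#' and calls calibration samples, fits the calibration model, generates the
#' donor read sets, constructs the mixture designs, deconvolutes every
#' mixture, and runs the suspect LR jobs. When `out_dir` is given, each
#' panel arm's results are written as JSON and an arm whose result file
#' already exists is loaded instead of recomputed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for per-arm result JSON.
#' @param progress emit progress messages.
#' @return list of class `experiment_results`: per panel kind, the
#'   evaluation `records`, proportion `ratios` and `lrs` tables, plus the
#'   `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  manifest <- plan_experiment(config)
  arms <- list()
  for (kind in config$panels) {
    res_path <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("arm_%s.json", kind))
    } else NULL
    if (!is.null(res_path) && file.exists(res_path)) {
      arms[[kind]] <- arm_from_json(res_path)
      next
    }
    if (progress) message("panel ", kind)
    world <- build_panel_world(config, kind)
    design2 <- build_two_person_design(
      kind, names(world$donor_reads), config$depth[[kind]],
      base_seed = derive_seed(world$seed, "design2"),
      ratios = config$two_person_ratios,
      n_per_ratio = config$pairs_per_ratio)
    arm <- run_design_arm(world, design2, 2L, config, progress)
    if (config$run_three_person) {
      design3 <- build_three_person_design(
        kind, names(world$donor_reads), config$depth[[kind]],
        base_seed = derive_seed(world$seed, "design3"),
        ratios = config$three_person_ratios,
        n_per_ratio = config$triples_per_ratio)
      arm3 <- run_design_arm(world, design3, 3L, config, progress)
      arm <- list(records = rbind(arm$records, arm3$records),
                  ratios = rbind(arm$ratios, arm3$ratios),
                  lrs = rbind(arm$lrs, arm3$lrs))
    }
    rownames(arm$records) <- rownames(arm$ratios) <- NULL
    if (!is.null(arm$lrs)) rownames(arm$lrs) <- NULL
    arms[[kind]] <- arm
    if (!is.null(res_path)) {
      dir.create(dirname(res_path), showWarnings = FALSE, recursive = TRUE)
      arm_to_json(arm, res_path)
    }
  }
  structure(c(arms, list(manifest = manifest)),
            class = "experiment_results")
}

arm_to_json <- function(arm, path) {
  ## -Inf is not valid JSON; serialise it as the string "-inf"
  out <- lapply(arm, function(df) {
    if (!is.null(df) && "log10_lr" %in% names(df)) {
      df$log10_lr <- ifelse(is.finite(df$log10_lr),
                            as.character(df$log10_lr), "-inf")
    }
    df
  })
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA,
                       na = "null")
  invisible(path)
}

arm_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arm <- lapply(obj, as.data.frame, stringsAsFactors = FALSE)
  if (!is.null(arm$lrs) && is.character(arm$lrs$log10_lr)) {
    arm$lrs$log10_lr <- ifelse(arm$lrs$log10_lr == "-inf", -Inf,
                               as.numeric(arm$lrs$log10_lr))
  }
  arm
}

#' Summarise an executed experiment
#'
#' Builds the study report: per-panel success-rate tables, per-ratio log10
#' LR distributions split by true contributor versus non-contributor
#' (with counts of LR = 0, i.e. log10 LR = -Inf), proportion-accuracy
#' summaries, and a reconciliation of executed against planned job counts.
#'
#' @param results an `experiment_results` from [run_experiment()].
#' @return list of class `experiment_report`.
#' @export
report_experiment <- function(results) {
  manifest <- results$manifest
  panels <- manifest$panels
  report <- list()
  for (kind in panels) {
    arm <- results[[kind]]
    if (is.null(arm) || is.null(arm$records)) next
    summ <- summarize_records(arm$records)
    lr_summary <- NULL
    separation <- NA
    if (!is.null(arm$lrs) && nrow(arm$lrs)) {
      lr_summary <- do.call(rbind, lapply(
        split(arm$lrs, list(arm$lrs$ratio, arm$lrs$true_contributor),
              drop = TRUE),
        function(sub) data.frame(
          ratio = sub$ratio[1L], true_contributor = sub$true_contributor[1L],
          n = nrow(sub),
          min_log10_lr = min(sub$log10_lr), max_log10_lr = max(sub$log10_lr),
          n_minus_inf = sum(is.infinite(sub$log10_lr) & sub$log10_lr < 0),
          stringsAsFactors = FALSE)))
      rownames(lr_summary) <- NULL
      tc <- arm$lrs$log10_lr[arm$lrs$true_contributor]
      nc <- arm$lrs$log10_lr[!arm$lrs$true_contributor]
      separation <- length(tc) > 0 && length(nc) > 0 &&
        min(tc) > max(nc)
    }
    report[[kind]] <- list(
      success = summ, lr_summary = lr_summary,
      complete_separation = separation,
      proportion_accuracy = if (!is.null(arm$ratios)) {
        do.call(rbind, lapply(split(arm$ratios, arm$ratios$ratio),
                              function(sub) data.frame(
                                ratio = sub$ratio[1L], n = nrow(sub),
                                expected = sub$expected[1L],
                                median_estimated = stats::median(sub$estimated),
                                stringsAsFactors = FALSE)))
      } else NULL,
      n_mixtures = length(unique(arm$records$mixture)),
      n_lr_jobs = if (is.null(arm$lrs)) 0L else nrow(arm$lrs))
  }
  structure(list(panels = report, manifest = manifest),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  for (kind in names(x$panels)) {
    p <- x$panels[[kind]]
    cat(sprintf("== %s: %d mixtures, %d LR jobs, error rate %.1f%%\n",
                kind, p$n_mixtures, p$n_lr_jobs, p$success$error_rate_pct))
    print(p$success$table, row.names = FALSE)
    if (isTRUE(p$complete_separation)) {
      cat("  complete LR separation: every true contributor above every non-contributor\n")
    }
  }
  invisible(x)
}
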