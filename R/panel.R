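#' Build a synthetic locus panel
#'
#' Generates a marker panel of the kind used in forensic MPS assays: either
#' microhaplotype (MH) loci -- fixed-length amplicons carrying 2-5 variant
#' positions whose phased bases define the alleles -- or short tandem repeat
#' (STR) loci -- amplicons with a central repeat region of a 3-5 bp motif
#' whose alleles differ by whole motif units. Each locus carries "truth"
#' parameters used only by the read simulator: a relative amplification
#' efficiency, and for STRs a stutter proportion (the fraction of a parent
#' allele's reads shed to the one-repeat-shorter sequence).
#'
#' All coordinates are 0-based, intervals half-open. A small number of MH
#' loci receive "ignored positions": offsets masked during allele calling,
#' mirroring configuration-level masking of unreliable bases.
#'
#' @param kind `"MH"` or `"STR"`.
#' @param n_loci number of loci (>= 1).
#' @param seed integer seed; the panel is a deterministic function of
#'   `(kind, n_loci, seed)`.
#' @param equal_efficiency if `TRUE`, all loci get efficiency 1 (useful for
#'   calibration checks); otherwise efficiencies are log-normal with mean 1.
#' @return An object of class `locus_panel`: a list with elements `kind` and
#'   `loci` (named list of locus definitions).
#' @export
build_panel <- function(kind, n_loci, seed, equal_efficiency = FALSE) {
  if (!kind %in% c("MH", "STR")) stopf("unknown panel kind '%s'", kind)
  n_loci <- check_count(n_loci, "n_loci", min = 1L)
  loci <- with_seed(seed, {
    eff <- if (equal_efficiency) rep(1, n_loci) else rlnorm(n_loci, 0, 0.35)
    eff <- eff / mean(eff)
    lapply(seq_len(n_loci), function(i) {
      if (kind == "MH") make_mh_locus(sprintf("MH%03d", i), eff[i])
      else make_str_locus(sprintf("STR%02d", i), eff[i])
    })
  })
  names(loci) <- vapply(loci, `[[`, "", "name")
  structure(list(kind = kind, loci = loci), class = "locus_panel")
}

make_mh_locus <- function(name, eff) {
  len <- sample(200:300, 1L)
  ref <- random_dna(len)
  n_var <- sample(2:5, 1L)
  pos <- sort(sample(seq_len(len - 20L) + 9L, n_var)) - 1L  # keep off the ends
  ign <- integer(0)
  if (runif(1) < 0.1) {  # a few loci carry masked, unreliable positions
    cand <- setdiff(seq_len(len) - 1L, pos)
    ign <- sort(sample(cand, sample(1:2, 1L)))
  }
  list(name = name, kind = "MH", amplicon_length = len, reference = ref,
       variant_positions = pos, ignored_positions = ign,
       efficiency_truth = eff)
}

make_str_locus <- function(name, eff) {
  motif_len <- sample(3:5, 1L)
  repeat {
    motif <- random_dna(motif_len)
    # motif must not itself be a run of one base or a shorter repeat
    if (length(unique(strsplit(motif, "")[[1]])) > 1L &&
        !is_periodic(motif)) break
  }
  n_ref <- sample(5:30, 1L)
  fl_len <- 80L
  repeat {
    flank_l <- random_dna(fl_len)
    if (substr(flank_l, fl_len - motif_len + 1L, fl_len) != motif) break
  }
  repeat {
    flank_r <- random_dna(fl_len)
    if (substr(flank_r, 1L, motif_len) != motif) break
  }
  ref <- paste0(flank_l, strrep(motif, n_ref), flank_r)
  list(name = name, kind = "STR", reference = ref,
       repeat_motif = motif,
       repeat_region = c(fl_len, fl_len + motif_len * n_ref),
       flank_left = flank_l, flank_right = flank_r,
       reference_repeats = n_ref,
       efficiency_truth = eff,
       stutter_truth = runif(1, 0.02, 0.10))
}

# TRUE if s is an integer number of copies of a shorter prefix
is_periodic <- function(s) {
  n <- nchar(s)
  for (k in seq_len(n - 1L)) {
    if (n %% k == 0L && strrep(substr(s, 1L, k), n %/% k) == s) return(TRUE)
  }
  FALSE
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf("<locus_panel> %s, %d loci\n", x$kind, length(x$loci)))
  invisible(x)
}

#' Full amplicon sequence of an allele
#'
#' Reconstructs the amplicon a sequencer would read for a given allele id:
#' for MH loci the reference with the haplotype's bases substituted at the
#' variant positions; for STR loci the flanks around the expanded bracketed
#' repeat string.
#'
#' @param locus a locus definition from a [build_panel()] panel.
#' @param allele_id haplotype string (MH) or bracketed repeat string (STR),
#'   e.g. `"[ATCT]11"`.
#' @return DNA string.
#' @export
allele_sequence <- function(locus, allele_id) {
  if (locus$kind == "MH") {
    stopifnot(nchar(allele_id) == length(locus$variant_positions))
    subst_chars(locus$reference, locus$variant_positions,
                strsplit(allele_id, "")[[1]])
  } else {
    paste0(locus$flank_left, expand_bracketed(allele_id), locus$flank_right)
  }
}

#' Expand a bracketed STR string to its DNA sequence
#'
#' Inverse of [bracket_str_sequence()]: `"[ATCT]2 ATGT [ATCT]8"` becomes the
#' concatenation of two ATCT copies, the literal ATGT, and eight ATCT copies.
#'
#' @param bracketed bracketed repeat string.
#' @return DNA string.
#' @export
expand_bracketed <- function(bracketed) {
  toks <- strsplit(trimws(bracketed), " +")[[1]]
  out <- vapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^\\[([ACGT]+)\\]([0-9]+)$", tk))[[1]]
    if (length(m) == 3L) strrep(m[2], as.integer(m[3])) else tk
  }, "")
  paste(out, collapse = "")
}

## total motif copies encoded in a bracketed allele id
bracketed_repeat_number <- function(bracketed) {
  m <- regmatches(bracketed, gregexpr("\\]([0-9]+)", bracketed))[[1]]
  if (length(m) == 0L) return(0L)
  sum(as.integer(sub("\\]", "", m)))
}

## ---- panel JSON persistence -------------------------------------------

#' Write / read a panel definition as JSON
#'
#' @param panel a `locus_panel`.
#' @param path file path.
#' @return `read_panel_json` returns the `locus_panel`; loading fails if two
#'   loci are indistinguishable to the caller (identical masked references or
#'   identical flank pairs).
#' @export
write_panel_json <- function(panel, path) {
  stopifnot(inherits(panel, "locus_panel"))
  obj <- list(schema = "mixdeconv-panel/1", kind = panel$kind,
              loci = unname(panel$loci))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "mixdeconv-panel/1")) {
    stopf("unrecognised panel schema in %s", path)
  }
  loci <- lapply(obj$loci, function(l) {
    l$variant_positions <- as.integer(l$variant_positions %||% integer(0))
    l$ignored_positions <- as.integer(l$ignored_positions %||% integer(0))
    if (!is.null(l$repeat_region)) l$repeat_region <- as.integer(l$repeat_region)
    l
  })
  names(loci) <- vapply(loci, `[[`, "", "name")
  panel <- structure(list(kind = obj$kind, loci = loci), class = "locus_panel")
  check_panel_unambiguous(panel)
  panel
}

## Two loci with identical calling signatures would make read assignment
## ambiguous; refuse such panels at load time.
check_panel_unambiguous <- function(panel) {
  sig <- vapply(panel$loci, function(l) {
    if (l$kind == "MH") {
      mask <- sort(c(l$variant_positions, l$ignored_positions))
      subst_chars(l$reference, mask, rep("N", length(mask)))
    } else {
      paste(l$flank_left, l$flank_right, sep = "|")
    }
  }, "")
  if (anyDuplicated(sig)) {
    stopf("ambiguous panel: loci %s share a calling signature",
          paste(names(panel$loci)[duplicated(sig)], collapse = ", "))
  }
  invisible(panel)
}
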