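#' Integer apportionment of mixture reads
#'
#' Splits a total read count over contributor proportions by
#' largest-remainder rounding: each contributor gets the floor of its exact
#' share, and leftover reads go to the largest fractional remainders, ties
#' broken by contributor order. The result always sums exactly to
#' `total_reads`; for a 9:1 mixture of 370,000 reads it gives
#' 333,000 + 37,000.
#'
#' @param total_reads positive integer.
#' @param proportions numeric vector in (0, 1] summing to 1 (within 1e-9).
#' @return integer vector of per-contributor read counts.
#' @export
apportion_reads <- function(total_reads, proportions) {
  total_reads <- check_count(total_reads, "total_reads")
  if (any(proportions < 0)) stopf("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stopf("proportions must sum to 1 (got %.12f)", sum(proportions))
  }
  exact <- total_reads * proportions
  base <- floor(exact + 1e-9)          # guard float error on exact shares
  left <- total_reads - sum(base)
  if (left > 0) {
    rem <- round(exact - base, 9)       # float-noise-free tie detection
    ord <- order(-rem, seq_along(rem))  # ties: earlier contributor first
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Mixture specification
#'
#' @param contributors ordered character vector of source sample ids.
#' @param proportions matching contributor proportions, summing to 1.
#' @param total_reads reads in the mixture FASTQ.
#' @param seed integer seed for read selection and shuffling.
#' @param label identifier for the mixture.
#' @return list of class `mixture_spec`.
#' @export
mixture_spec <- function(contributors, proportions, total_reads, seed,
                         label = paste(contributors, collapse = "+")) {
  stopifnot(length(contributors) == length(proportions),
            length(contributors) >= 1L)
  if (abs(sum(proportions) - 1) > 1e-9) stopf("proportions must sum to 1")
  structure(list(contributors = as.character(contributors),
                 proportions = as.numeric(proportions),
                 total_reads = check_count(total_reads, "total_reads"),
                 seed = as.integer(seed), label = label),
            class = "mixture_spec")
}

#' Mix single-source read sets into one mixture read set
#'
#' Reimplements the shuffle-and-subsample construction of simulated
#' mixtures: from each source, its apportioned number of reads is drawn
#' without replacement (seeded per source), and the union is shuffled into
#' the final order. Identical inputs and spec give byte-identical output.
#'
#' @param readsets list of `read_set` data frames, one per contributor, in
#'   `spec$contributors` order.
#' @param spec a [mixture_spec()].
#' @return a `read_set` with exactly `spec$total_reads` rows.
#' @export
mix_reads <- function(readsets, spec) {
  stopifnot(inherits(spec, "mixture_spec"),
            length(readsets) == length(spec$contributors))
  n_take <- apportion_reads(spec$total_reads, spec$proportions)
  parts <- lapply(seq_along(readsets), function(k) {
    rs <- readsets[[k]]
    if (nrow(rs) < n_take[k]) {
      stopf("source '%s' has %d reads but %d requested",
            spec$contributors[k], nrow(rs), n_take[k])
    }
    idx <- with_seed(derive_seed(spec$seed, spec$label, k),
                     sample.int(nrow(rs), n_take[k]))
    rs[idx, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  ord <- with_seed(derive_seed(spec$seed, spec$label, "shuffle"),
                   sample.int(nrow(out)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_ratio <- function(ratio) {
  parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  parts / sum(parts)
}

#' Two- and three-person mixture design grids
#'
#' `build_two_person_design()` enumerates all C(10,2) = 45 unordered pairs of
#' a 10-donor cohort for each mixture ratio (default 19:1, 9:1, 3:1, 1:1 --
#' 180 mixtures); the lexicographically smaller sample id takes the major
#' role. `build_three_person_design()` takes the first 56 of the C(10,3) =
#' 120 sorted triples for each ratio (default 14:5:1, 14:3:3, 9:9:2 -- 168
#' mixtures), roles assigned lexicographically within the triple.
#'
#' @param panel_kind `"MH"` or `"STR"`.
#' @param sample_ids exactly 10 sample ids.
#' @param total_reads mixture read depth.
#' @param base_seed integer; per-mixture seeds are derived from it, so a
#'   rebuild is identical.
#' @param ratios ratio labels to include.
#' @param n_per_ratio number of contributor groups per ratio (default: all
#'   45 pairs, or the first 56 sorted triples).
#' @return list of class `mixture_design` with elements `panel_kind`,
#'   `ratio_labels`, `specs` (list of [mixture_spec()]).
#' @name mixture_design
#' @export
build_two_person_design <- function(panel_kind, sample_ids, total_reads,
                                    base_seed,
                                    ratios = c("19:1", "9:1", "3:1", "1:1"),
                                    n_per_ratio = NULL) {
  if (length(sample_ids) != 10L) stopf("need exactly 10 sample ids")
  ids <- sort(as.character(sample_ids))
  pairs <- utils::combn(ids, 2L, simplify = FALSE)
  if (!is.null(n_per_ratio)) pairs <- pairs[seq_len(n_per_ratio)]
  build_design(panel_kind, pairs, ratios, total_reads, base_seed)
}

#' @rdname mixture_design
#' @export
build_three_person_design <- function(panel_kind, sample_ids, total_reads,
                                      base_seed,
                                      ratios = c("14:5:1", "14:3:3", "9:9:2"),
                                      n_per_ratio = 56L) {
  if (length(sample_ids) != 10L) stopf("need exactly 10 sample ids")
  ids <- sort(as.character(sample_ids))
  triples <- utils::combn(ids, 3L, simplify = FALSE)
  build_design(panel_kind, triples[seq_len(n_per_ratio)], ratios,
               total_reads, base_seed)
}

build_design <- function(panel_kind, groups, ratios, total_reads, base_seed) {
  specs <- list()
  for (ratio in ratios) {
    props <- parse_ratio(ratio)
    for (grp in groups) {
      label <- paste0(panel_kind, "_", gsub(":", "-", ratio), "_",
                      paste(grp, collapse = "+"))
      specs[[label]] <- mixture_spec(
        contributors = grp, proportions = props, total_reads = total_reads,
        seed = derive_seed(base_seed, label), label = label)
    }
  }
  structure(list(panel_kind = panel_kind, ratio_labels = ratios,
                 specs = specs),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %s: %d mixtures (%s)\n", x$panel_kind,
              length(x$specs), paste(x$ratio_labels, collapse = ", ")))
  invisible(x)
}

#' Write a design manifest as JSON
#'
#' Records every mixture spec with its resolved per-contributor read counts,
#' so a design can be rebuilt and audited.
#'
#' @param design a `mixture_design`.
#' @param path file path.
#' @export
write_design_manifest <- function(design, path) {
  entries <- lapply(design$specs, function(sp) {
    list(label = sp$label, contributors = sp$contributors,
         proportions = sp$proportions,
         reads_per_contributor = apportion_reads(sp$total_reads,
                                                 sp$proportions),
         total_reads = sp$total_reads, seed = sp$seed)
  })
  jsonlite::write_json(
    list(schema = "mixdeconv-design/1", panel_kind = design$panel_kind,
         ratio_labels = design$ratio_labels, mixtures = unname(entries)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
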