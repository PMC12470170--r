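#' Convert an STR repeat region to bracketed nomenclature
#'
#' Greedy left-to-right run-length encoding of motif copies: maximal motif
#' runs become `[MOTIF]n` tokens and interrupting bases are emitted
#' literally, e.g. `ATCTATCTATGTATCT` with motif `ATCT` gives
#' `"[ATCT]2 ATGT [ATCT]1"`. The repeat number is the total count of
#' bracketed motif copies.
#'
#' @param repeat_region DNA string (nonempty).
#' @param motif repeat motif, 3-5 bases.
#' @return list with `bracketed` (string) and `repeat_number` (integer).
#'   Errors if the region contains no complete motif copy.
#' @export
bracket_str_sequence <- function(repeat_region, motif) {
  if (!nzchar(repeat_region)) stopf("empty repeat region: no repeat found")
  m <- nchar(motif)
  if (m < 3L || m > 5L) stopf("motif must be 3-5 bases")
  n <- nchar(repeat_region)
  toks <- character(0)
  lit <- ""
  total <- 0L
  i <- 1L
  while (i <= n) {
    run <- 0L
    while (i + m - 1L <= n && substr(repeat_region, i, i + m - 1L) == motif) {
      run <- run + 1L
      i <- i + m
    }
    if (run > 0L) {
      if (nzchar(lit)) { toks <- c(toks, lit); lit <- "" }
      toks <- c(toks, sprintf("[%s]%d", motif, run))
      total <- total + run
    } else {
      lit <- paste0(lit, substr(repeat_region, i, i))
      i <- i + 1L
    }
  }
  if (nzchar(lit)) toks <- c(toks, lit)
  if (total == 0L) stopf("no complete copy of motif %s in repeat region", motif)
  list(bracketed = paste(toks, collapse = " "), repeat_number = total)
}

#' Microhaplotype allele of a single read
#'
#' A read is accepted for an MH locus when it has the locus's amplicon
#' length and matches the reference at every position outside the variant
#' and ignored positions; the allele id is then the concatenated bases at
#' the variant positions. Reads differing only at ignored positions yield
#' the same allele.
#'
#' @param read_sequence DNA string.
#' @param locus an MH locus definition.
#' @return allele id string, or `NA` if the read does not match.
#' @export
mh_allele_from_read <- function(read_sequence, locus) {
  if (nchar(read_sequence) != locus$amplicon_length) return(NA_character_)
  skip <- c(locus$variant_positions, locus$ignored_positions)
  keep <- setdiff(seq_len(locus$amplicon_length) - 1L, skip)
  if (chars_at(read_sequence, keep) != chars_at(locus$reference, keep)) {
    return(NA_character_)
  }
  chars_at(read_sequence, locus$variant_positions)
}

#' Call alleles from a read set by exact amplicon matching
#'
#' Assigns every read to the unique locus whose amplicon signature it
#' matches exactly -- full-length masked match for MH loci, exact flank
#' match with a variable repeat region for STR loci -- and aggregates
#' per-allele read counts. STR alleles are named in bracketed nomenclature.
#' Alleles with fewer reads than the analytical threshold are retained only
#' in the below-threshold audit slot; unmatched reads are counted as
#' unassigned. Read totals are conserved:
#' retained + below-threshold + unassigned equals the input count.
#'
#' @param reads a `read_set`.
#' @param panel a `locus_panel`.
#' @param analytical_threshold minimum read count for an allele to be
#'   treated as signal (default 11).
#' @param exclude_loci locus names to drop from the result (configuration
#'   hook for imbalanced loci that a laboratory excludes from typing).
#' @param sample_id id recorded on the table; by default taken from the
#'   read headers.
#' @return object of class `allele_counts`: list with `sample_id`, `counts`
#'   (data frame locus/allele/count/status), `unassigned_reads`,
#'   `analytical_threshold`, `total_reads`.
#' @export
call_alleles <- function(reads, panel, analytical_threshold = 11L,
                         exclude_loci = character(0), sample_id = NULL) {
  stopifnot(inherits(panel, "locus_panel"))
  if (length(panel$loci) == 0L) stopf("panel is empty")
  analytical_threshold <- check_count(analytical_threshold,
                                      "analytical_threshold", min = 1L)
  check_panel_unambiguous(panel)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(reads)) sub(":.*$", "", reads$id[1L]) else "sample"
  }
  tab <- table(reads$seq)
  uniq <- names(tab)
  cnt <- as.integer(tab)

  rows <- list()
  assigned_mask <- logical(length(uniq))
  for (locus in panel$loci) {
    if (locus$kind == "MH") {
      cand <- which(!assigned_mask & nchar(uniq) == locus$amplicon_length)
      if (!length(cand)) next
      al <- vapply(uniq[cand], mh_allele_from_read, "", locus = locus)
      hit <- !is.na(al)
    } else {
      cand <- which(!assigned_mask &
                      startsWith(uniq, locus$flank_left) &
                      endsWith(uniq, locus$flank_right) &
                      nchar(uniq) > nchar(locus$flank_left) +
                        nchar(locus$flank_right))
      if (!length(cand)) next
      al <- vapply(uniq[cand], function(s) {
        mid <- substr(s, nchar(locus$flank_left) + 1L,
                      nchar(s) - nchar(locus$flank_right))
        br <- tryCatch(bracket_str_sequence(mid, locus$repeat_motif),
                       error = function(e) NULL)
        if (is.null(br)) NA_character_ else br$bracketed
      }, "")
      hit <- !is.na(al)
    }
    if (!any(hit)) next
    idx <- cand[hit]
    assigned_mask[idx] <- TRUE
    agg <- tapply(cnt[idx], al[hit], sum)
    rows[[locus$name]] <- data.frame(
      locus = locus$name, allele = names(agg), count = as.integer(agg),
      stringsAsFactors = FALSE)
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), allele = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  counts <- counts[!counts$locus %in% exclude_loci, , drop = FALSE]
  counts$status <- ifelse(counts$count >= analytical_threshold,
                          "retained", "below_threshold")
  counts <- counts[order(counts$locus, -counts$count, counts$allele), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  structure(list(sample_id = sample_id, counts = counts,
                 unassigned_reads = sum(cnt[!assigned_mask]),
                 analytical_threshold = analytical_threshold,
                 total_reads = nrow(reads)),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  ret <- x$counts[x$counts$status == "retained", , drop = FALSE]
  cat(sprintf(
    "<allele_counts> %s: %d retained alleles at %d loci (AT=%d), %d unassigned reads\n",
    x$sample_id, nrow(ret), length(unique(ret$locus)),
    x$analytical_threshold, x$unassigned_reads))
  invisible(x)
}

## retained alleles of one locus as a named count vector
retained_counts <- function(counts, locus) {
  sub <- counts$counts
  sub <- sub[sub$locus == locus & sub$status == "retained", , drop = FALSE]
  setNames(sub$count, sub$allele)
}

#' Allele-count TSV input/output
#'
#' Columns `sample`, `locus`, `allele`, `count`, `status`
#' (retained/below_threshold); one file per sample.
#'
#' @param counts an `allele_counts` object.
#' @param path file path.
#' @name counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  df <- counts$counts
  df <- cbind(sample = counts$sample_id, df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# analytical_threshold=%d unassigned=%d total=%d",
                     counts$analytical_threshold, counts$unassigned_reads,
                     counts$total_reads), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts_tsv
#' @export
read_counts_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  structure(list(sample_id = as.character(df$sample[1L] %||% "sample"),
                 counts = df[, c("locus", "allele", "count", "status")],
                 analytical_threshold = meta[1],
                 unassigned_reads = meta[2], total_reads = meta[3]),
            class = "allele_counts")
}
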