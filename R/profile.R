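# Classification of assembly differences, homopolymer attribution, and
# the consensus-quality (QV) arithmetic relating error counts to
# Phred-scaled accuracy and error spacing.

#' Attribute difference records to homopolymer context
#'
#' For a substitution, the context is the maximal identical-base run
#' containing the locus. For an indel, it is the maximal adjacent run
#' whose base equals the indel base (insertions sit between two runs;
#' the matching one counts). Records outside any matching run get
#' `hp_len = 1`. A record is "in a homopolymer" iff `hp_len >= min_run`.
#'
#' @param seq Reference `circular_sequence` (or nucleotide string).
#' @param records Difference-record `data.frame`.
#' @param min_run Run length defining a homopolymer region (default 3;
#'   runs of 2 are so frequent in random sequence that counting them
#'   would make the attribution uninformative).
#' @return `records` with `hp_base`, `hp_len` and logical
#'   `in_homopolymer` filled in.
#' @export
attribute_homopolymer <- function(seq, records, min_run = 3L) {
  chars <- if (is.character(seq) && length(seq) > 1L) seq else seq_chars(seq)
  runs <- run_info(chars)
  n <- length(chars)
  if (nrow(records) && (min(records$ref_pos) < 0L ||
                        max(records$ref_pos) > n))
    mq_domain_error("record positions fall outside the sequence")
  for (i in seq_len(nrow(records))) {
    p <- records$ref_pos[i]  # 0-based
    if (records$kind[i] == "substitution") {
      records$hp_base[i] <- chars[p + 1L]
      records$hp_len[i] <- runs$len[p + 1L]
    } else if (records$kind[i] == "deletion") {
      b <- substr(records$ref_bases[i], 1L, 1L)
      records$hp_base[i] <- b
      records$hp_len[i] <- runs$len[p + 1L]
    } else {
      b <- substr(records$query_bases[i], 1L, 1L)
      left <- if (p > 0L && chars[p] == b) runs$len[p] else 0L
      right <- if (p < n && chars[p + 1L] == b) runs$len[p + 1L] else 0L
      records$hp_base[i] <- b
      records$hp_len[i] <- max(left, right, 1L)
    }
  }
  records$in_homopolymer <- !is.na(records$hp_len) &
    records$hp_len >= min_run
  records
}

#' Consensus QV and error spacing from an error count
#'
#' `qv = -10 log10(n_errors / assembly_length)`;
#' `bases_per_error = assembly_length / n_errors = 10^(qv/10)`. With zero
#' errors the QV is capped at the value corresponding to a single error
#' (`-10 log10(1/L)`) and flagged as a lower bound.
#'
#' @param n_errors Number of consensus errors.
#' @param assembly_length Assembly length in bp.
#' @return List with `qv`, `bases_per_error`, `is_lower_bound`.
#' @export
qv_from_errors <- function(n_errors, assembly_length) {
  if (assembly_length <= 0) mq_domain_error("assembly_length must be > 0")
  if (n_errors < 0) mq_domain_error("n_errors must be >= 0")
  if (n_errors == 0)
    return(list(qv = -10 * log10(1 / assembly_length),
                bases_per_error = as.numeric(assembly_length),
                is_lower_bound = TRUE))
  list(qv = -10 * log10(n_errors / assembly_length),
       bases_per_error = assembly_length / n_errors,
       is_lower_bound = FALSE)
}

#' Error spacing implied by a QV
#' @param qv Phred-scaled consensus quality.
#' @return Expected bases per error, `10^(qv/10)`.
#' @export
bases_per_error <- function(qv) 10^(qv / 10)

#' Summarize a set of difference records into an error profile
#'
#' Computes, over *all* records: counts per type label (`+A`, `-T`,
#' `*CT`, ...), the fraction of single-base indels, the fraction of
#' single T/A indels, the fraction of errors in homopolymer runs, a
#' single-base indel count table by run length and base, and the
#' consensus QV. A plotting view additionally drops labels rarer than
#' `min_count_filter`; the filter never affects the fractions.
#'
#' @param records Difference-record `data.frame`, ideally after
#'   [attribute_homopolymer()].
#' @param assembly_length Assembly length in bp for the QV.
#' @param min_count_filter Minimum label count retained in the plotting
#'   view (default 3).
#' @param min_run Run length defining a homopolymer (default 3).
#' @return An object of class `error_profile`.
#' @export
summarize_profile <- function(records, assembly_length,
                              min_count_filter = 3L, min_run = 3L) {
  if (assembly_length <= 0) mq_domain_error("assembly_length must be > 0")
  n <- nrow(records)
  q <- qv_from_errors(n, assembly_length)
  counts <- if (n) table(records$type_label) else table(character(0))
  counts <- sort(as.table(counts), decreasing = TRUE)
  single_indel <- records$kind != "substitution" & records$size == 1L
  ta_single <- single_indel &
    (records$kind == "insertion" & records$query_bases %in% c("A", "T") |
     records$kind == "deletion" & records$ref_bases %in% c("A", "T"))
  in_hp <- if (n && !anyNA(records$hp_len))
    records$hp_len >= min_run else rep(NA, n)
  tab <- records[single_indel & !is.na(records$hp_len), , drop = FALSE]
  if (nrow(tab)) {
    indel_by_runlength <- as.data.frame(
      table(run_length = factor(tab$hp_len, levels = 1:max(tab$hp_len)),
            base = factor(tab$hp_base, levels = c("A", "C", "G", "T"))),
      responseName = "count")
    indel_by_runlength$run_length <-
      as.integer(as.character(indel_by_runlength$run_length))
  } else {
    indel_by_runlength <- data.frame(run_length = integer(),
                                     base = character(), count = integer())
  }
  structure(list(
    n_total = n,
    counts_by_label = counts,
    plot_counts = counts[counts >= min_count_filter],
    fraction_single_base_indel = if (n) mean(single_indel) else NA_real_,
    fraction_TA_single_indel = if (n) mean(ta_single) else NA_real_,
    fraction_in_homopolymer = if (n) mean(in_hp) else NA_real_,
    indel_by_runlength = indel_by_runlength,
    qv = q$qv, qv_is_lower_bound = q$is_lower_bound,
    assembly_length = as.integer(assembly_length)),
    class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> %d error(s) over %d bp\n", x$n_total,
              x$assembly_length))
  cat(sprintf("  QV %s%.1f (one error per %.1f bp)\n",
              if (x$qv_is_lower_bound) ">= " else "", x$qv,
              bases_per_error(x$qv)))
  if (x$n_total > 0) {
    cat(sprintf("  single-base indels: %.1f%%  T/A single indels: %.1f%%\n",
                100 * x$fraction_single_base_indel,
                100 * x$fraction_TA_single_indel))
    if (!is.na(x$fraction_in_homopolymer))
      cat(sprintf("  in homopolymer runs: %.1f%%\n",
                  100 * x$fraction_in_homopolymer))
  }
  invisible(x)
}

#' Count modified sites between a draft and a polished assembly
#'
#' Each difference record counts once regardless of size, mirroring the
#' "modified sites" bookkeeping of polishing pipelines. Both sequences
#' must have been normalized to the same rotation and strand first.
#'
#' @param draft,polished Normalized `circular_sequence` objects.
#' @param ... Passed to [align_assemblies()].
#' @return Integer count of modified sites.
#' @export
compare_before_after <- function(draft, polished, ...) {
  if (!isTRUE(draft$normalized) || !isTRUE(polished$normalized))
    mq_config_error("sequences are not normalized; run canonical_rotation ",
                    "on both (same anchor) before comparing")
  d <- align_assemblies(polished, draft, ...)
  nrow(d$records)
}

#' Convert an error profile to a plain list for JSON serialization
#' @param profile An `error_profile`.
#' @return Nested list of plain vectors.
#' @export
profile_to_list <- function(profile) {
  list(n_total = profile$n_total,
       assembly_length = profile$assembly_length,
       qv = profile$qv,
       qv_is_lower_bound = profile$qv_is_lower_bound,
       bases_per_error = bases_per_error(profile$qv),
       fraction_single_base_indel = profile$fraction_single_base_indel,
       fraction_TA_single_indel = profile$fraction_TA_single_indel,
       fraction_in_homopolymer = profile$fraction_in_homopolymer,
       counts_by_label = as.list(profile$counts_by_label))
}
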