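# Readers and writers for the standard formats the pipeline touches
# (FASTA, PAF + cs tag, BED/GFF-like annotation tables) and the package's
# own TSV report tables. Internal coordinates are uniformly 0-based
# half-open; files keep their native conventions.

#' Read a FASTA file of assemblies
#'
#' Sequences are uppercased; circularity is parsed from a `circular=true`
#' token in the header (kept in-band so fixtures stay single-file).
#'
#' @param path Path to a FASTA file.
#' @return List of `circular_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) mq_format_error("no such file: ", path)
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e)
               mq_format_error("cannot parse FASTA '", path, "': ",
                               conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        mq_format_error("FASTA '", path,
                        "' contains non-nucleotide characters")
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L)
    mq_format_error("FASTA file '", path, "' contains no records")
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    fields <- strsplit(headers[i], "\\s+")[[1L]]
    circ <- any(tolower(fields) == "circular=true")
    bases <- toupper(as.character(set[[i]]))
    if (nchar(bases) == 0L)
      mq_format_error("record '", fields[1L], "' in '", path, "' is empty")
    circular_sequence(fields[1L], bases, circular = circ)
  })
}

#' Write sequences to FASTA
#'
#' Wraps at 70 columns and encodes circularity as a `circular=true`
#' header token.
#'
#' @param seqs A `circular_sequence` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "circular_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$bases, ""))
  names(set) <- vapply(seqs, function(s)
    paste0(s$name, if (s$circular) " circular=true" else ""), "")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory columns plus any `cs:Z` difference-string tag.
#' Coordinates are kept 0-based half-open as in the PAF standard.
#'
#' @param path Path to a PAF file.
#' @return `data.frame` with one row per alignment record; column `cs` is
#'   `NA` for records without a difference string and `has_cs` flags
#'   their presence.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) mq_format_error("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) mq_format_error("PAF file '", path, "' is empty")
  rows <- lapply(seq_along(lines), function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      mq_format_error("PAF line ", ln, " has ", length(f),
                      " columns (12 required)")
    num <- suppressWarnings(as.integer(f[c(2, 3, 4, 7, 8, 9, 10, 11, 12)]))
    if (anyNA(num))
      mq_format_error("PAF line ", ln, " has non-numeric coordinate fields")
    if (!f[5] %in% c("+", "-"))
      mq_format_error("PAF line ", ln, " has invalid strand '", f[5], "'")
    cs <- NA_character_
    if (length(f) > 12L) {
      tag <- grep("^cs:Z:", f[-(1:12)], value = TRUE)
      if (length(tag)) cs <- substring(tag[1L], 6L)
    }
    out <- data.frame(
      query_name = f[1], query_length = num[1], query_start = num[2],
      query_end = num[3], strand = f[5], target_name = f[6],
      target_length = num[4], target_start = num[5], target_end = num[6],
      n_match = num[7], block_length = num[8], mapping_quality = num[9],
      cs = cs, stringsAsFactors = FALSE)
    with(out, {
      if (query_start < 0 || query_start >= query_end ||
          query_end > query_length ||
          target_start < 0 || target_start >= target_end ||
          target_end > target_length)
        mq_format_error("PAF line ", ln, " violates 0 <= start < end <= length")
    })
    out
  })
  out <- do.call(rbind, rows)
  out$has_cs <- !is.na(out$cs)
  out
}

#' Read a gene annotation table
#'
#' Accepts a BED-like tab-separated table (`name`, `class`, `start`,
#' `end`, `strand`, with or without a header line) whose coordinate
#' convention is declared explicitly; coordinates are normalized to the
#' internal 0-based half-open convention. Features wrapping the origin
#' (`end <= start` after conversion) are allowed only when
#' `genome_length` is supplied for a circular sequence.
#'
#' @param path Path to the table.
#' @param coords `"one_based_inclusive"` (GFF-like, the package's own
#'   table format) or `"zero_based_half_open"` (BED-like).
#' @param genome_length Circular genome length, enabling origin-wrapping
#'   features.
#' @return `data.frame` with `name`, `class`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_annotations <- function(path,
                             coords = c("one_based_inclusive",
                                        "zero_based_half_open"),
                             genome_length = NULL) {
  coords <- match.arg(coords)
  if (!file.exists(path)) mq_format_error("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) mq_format_error("annotation file '", path, "' is empty")
  if (grepl("^name\tclass", lines[1L])) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col != 5L))
    mq_format_error("annotation line ", which(n_col != 5L)[1L],
                    " does not have 5 tab-separated fields ",
                    "(name, class, start, end, strand)")
  df <- data.frame(name = vapply(fields, `[[`, "", 1L),
                   class = vapply(fields, `[[`, "", 2L),
                   start = suppressWarnings(
                     as.integer(vapply(fields, `[[`, "", 3L))),
                   end = suppressWarnings(
                     as.integer(vapply(fields, `[[`, "", 4L))),
                   strand = vapply(fields, `[[`, "", 5L),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    mq_format_error("non-numeric coordinates in '", path, "'")
  if (!all(df$strand %in% c("+", "-")))
    mq_format_error("strand must be '+' or '-' in '", path, "'")
  if (!all(df$class %in% c("PCG", "tRNA", "rRNA", "other")))
    mq_format_error("feature class must be PCG, tRNA, rRNA or other")
  if (coords == "one_based_inclusive") df$start <- df$start - 1L
  wrap <- df$end <= df$start
  if (any(wrap) && is.null(genome_length))
    mq_format_error("feature '", df$name[which(wrap)[1L]],
                    "' wraps the origin; supply genome_length for a ",
                    "circular sequence")
  df
}

#' Write a gene annotation table (1-based inclusive)
#'
#' @param ann Annotation `data.frame` (internal 0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  out <- ann
  out$start <- out$start + 1L
  utils::write.table(out[, c("name", "class", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write difference records to TSV
#' @param records Difference-record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_difference_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read difference records from TSV
#' @param path Path written by [write_difference_tsv()].
#' @return Difference-record `data.frame`.
#' @export
read_difference_tsv <- function(path) {
  if (!file.exists(path)) mq_format_error("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(
                            ref_pos = "integer", kind = "character",
                            ref_bases = "character",
                            query_bases = "character", size = "integer",
                            type_label = "character",
                            hp_base = "character", hp_len = "integer"),
                          na.strings = "NA")
  df$ref_bases[is.na(df$ref_bases)] <- ""
  df$query_bases[is.na(df$query_bases)] <- ""
  difference_records(df$ref_pos, df$kind, df$ref_bases, df$query_bases,
                     df$hp_base, df$hp_len)
}

#' Write a window track as BED-like TSV
#' @param track Window-track `data.frame` from [window_stats()] or
#'   [simulate_coverage()].
#' @param name Sequence name for the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(track, name, path) {
  out <- cbind(data.frame(chrom = name), track)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
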