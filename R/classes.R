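# Core containers and small sequence utilities shared by all modules.

#' Construct a circular (or linear) nucleotide sequence
#'
#' The basic container used throughout the package: a named nucleotide
#' string plus a circularity flag and a record of any rotation /
#' strand-flip applied during canonical normalization, so that the
#' normalization can be inverted exactly.
#'
#' @param name Sequence name (FASTA identifier).
#' @param bases Nucleotide string (IUPAC alphabet); stored uppercased.
#' @param circular Logical; is the molecule circular?
#' @param applied_rotation Integer; bases rotated off the front during
#'   normalization, in `[0, length)`.
#' @param applied_strand_flip Logical; was the sequence reverse
#'   complemented during normalization?
#' @return An object of class `circular_sequence`.
#' @export
circular_sequence <- function(name, bases, circular = FALSE,
                              applied_rotation = 0L,
                              applied_strand_flip = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  if (nchar(bases) == 0L)
    mq_config_error("sequence '", name, "' is empty")
  if (grepl("[^ACGTRYSWKMBDHVN]", bases))
    mq_format_error("sequence '", name,
                    "' contains non-IUPAC nucleotide characters")
  applied_rotation <- as.integer(applied_rotation)
  if (applied_rotation < 0L || applied_rotation >= nchar(bases))
    mq_config_error("applied_rotation must lie in [0, length)")
  structure(list(name = name, bases = bases,
                 circular = isTRUE(circular),
                 applied_rotation = applied_rotation,
                 applied_strand_flip = isTRUE(applied_strand_flip),
                 normalized = FALSE),
            class = "circular_sequence")
}

#' @export
print.circular_sequence <- function(x, ...) {
  cat(sprintf("<circular_sequence> %s: %d bp, %s%s\n", x$name,
              seq_length(x), if (x$circular) "circular" else "linear",
              if (x$normalized)
                sprintf(" (normalized: rot=%d, flip=%s)",
                        x$applied_rotation, x$applied_strand_flip)
              else ""))
  invisible(x)
}

#' Sequence length in bp
#' @param seq A `circular_sequence`.
#' @return Integer length.
#' @export
seq_length <- function(seq) nchar(seq$bases)

# Split into a character vector of single bases.
seq_chars <- function(x) {
  if (inherits(x, "circular_sequence")) x <- x$bases
  strsplit(x, "", fixed = TRUE)[[1L]]
}

#' Rotate a circular sequence
#'
#' Moves the first `offset` bases to the end, i.e. the base at position
#' `offset` (0-based) becomes the new origin.
#'
#' @param seq A circular `circular_sequence`.
#' @param offset Integer rotation in bp; interpreted modulo the length.
#' @return The rotated sequence (rotation is not recorded; see
#'   [canonical_rotation()] for the recorded form).
#' @export
rotate_sequence <- function(seq, offset) {
  if (!seq$circular)
    mq_config_error("cannot rotate a linear sequence")
  n <- seq_length(seq)
  offset <- ((as.integer(offset) %% n) + n) %% n
  if (offset == 0L) return(seq)
  seq$bases <- paste0(substr(seq$bases, offset + 1L, n),
                      substr(seq$bases, 1L, offset))
  seq
}

#' Reverse complement of a sequence
#' @param seq A `circular_sequence` or bare nucleotide string.
#' @return Same type as the input.
#' @export
reverse_complement <- function(seq) {
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (inherits(seq, "circular_sequence")) {
    seq$bases <- rc(seq$bases)
    seq
  } else rc(seq)
}

# Per-position homopolymer run lengths and run ids for a base vector.
run_info <- function(chars) {
  r <- rle(chars)
  list(len = rep.int(r$lengths, r$lengths),
       id = rep.int(seq_along(r$lengths), r$lengths),
       start = rep.int(cumsum(c(1L, r$lengths[-length(r$lengths)])),
                       r$lengths))
}

# ---- condition classes -----------------------------------------------------
# Distinct classes so the CLI can map failures onto its exit-code contract.

mq_error <- function(class, ...) {
  stop(structure(class = c(class, "mitoqc_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}
mq_config_error    <- function(...) mq_error("mitoqc_config_error", ...)
mq_format_error    <- function(...) mq_error("mitoqc_format_error", ...)
mq_alignment_error <- function(...) mq_error("mitoqc_alignment_error", ...)
mq_domain_error    <- function(...) mq_error("mitoqc_domain_error", ...)

# ---- difference records ----------------------------------------------------

diff_cols <- c("ref_pos", "kind", "ref_bases", "query_bases",
               "size", "type_label", "hp_base", "hp_len")

#' Construct a table of assembly-difference records
#'
#' Each row is one classified difference between a reference and a query
#' assembly, in 0-based reference coordinates. Insertions sit *before*
#' `ref_pos`; deletions and substitutions consume reference bases starting
#' at `ref_pos`. `type_label` follows the `+A` / `-T` / `*CT` convention
#' (insertion / deletion / substitution ref,query).
#'
#' @param ref_pos Integer vector of 0-based reference positions.
#' @param kind Character vector: `"insertion"`, `"deletion"` or
#'   `"substitution"`.
#' @param ref_bases,query_bases Bases on each side (`""` where absent).
#' @param hp_base,hp_len Homopolymer context (filled by
#'   [attribute_homopolymer()]; `NA` / `NA_integer_` until then).
#' @return A `data.frame` with one row per difference.
#' @export
difference_records <- function(ref_pos = integer(), kind = character(),
                               ref_bases = character(),
                               query_bases = character(),
                               hp_base = NA_character_,
                               hp_len = NA_integer_) {
  n <- length(ref_pos)
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), c("insertion", "deletion", "substitution"))
  if (length(bad))
    mq_config_error("unknown difference kind(s): ", paste(bad, collapse = ", "))
  size <- ifelse(kind == "insertion", nchar(query_bases), nchar(ref_bases))
  sub_bad <- kind == "substitution" & nchar(ref_bases) != nchar(query_bases)
  if (any(sub_bad))
    mq_config_error("substitution records must have equal-length bases")
  lab <- character(n)
  lab[kind == "insertion"] <- paste0("+", query_bases[kind == "insertion"])
  lab[kind == "deletion"] <- paste0("-", ref_bases[kind == "deletion"])
  lab[kind == "substitution"] <- paste0("*", ref_bases[kind == "substitution"],
                                        query_bases[kind == "substitution"])
  data.frame(ref_pos = as.integer(ref_pos), kind = kind,
             ref_bases = as.character(ref_bases),
             query_bases = as.character(query_bases),
             size = as.integer(size), type_label = lab,
             hp_base = rep_len(as.character(hp_base), n),
             hp_len = rep_len(as.integer(hp_len), n),
             stringsAsFactors = FALSE)
}

# Canonical sort used whenever two record sets are compared.
sort_records <- function(rec) {
  if (nrow(rec) == 0L) return(rec)
  ord <- order(rec$ref_pos, rec$kind, rec$ref_bases, rec$query_bases)
  out <- rec[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a difference set
#'
#' Bundles the aligned blocks, difference records and unaligned segments
#' produced by comparing two assemblies.
#'
#' @param reference_name,query_name Sequence names.
#' @param blocks `data.frame` with `ref_start`, `ref_end`, `query_start`,
#'   `query_end` (0-based half-open), non-overlapping and sorted on the
#'   reference.
#' @param records Difference-record table (see [difference_records()]).
#' @param unaligned `data.frame` with `owner` (`"ref"` or `"query"`),
#'   `start`, `end` — sequence present in only one assembly.
#' @return An object of class `difference_set`.
#' @export
difference_set <- function(reference_name, query_name,
                           blocks = NULL, records = NULL, unaligned = NULL) {
  if (is.null(blocks))
    blocks <- data.frame(ref_start = integer(), ref_end = integer(),
                         query_start = integer(), query_end = integer())
  if (is.null(records)) records <- difference_records()
  if (is.null(unaligned))
    unaligned <- data.frame(owner = character(), start = integer(),
                            end = integer())
  if (nrow(blocks) > 1L) {
    o <- order(blocks$ref_start)
    blocks <- blocks[o, , drop = FALSE]
    if (any(blocks$ref_start[-1L] < blocks$ref_end[-nrow(blocks)]))
      mq_config_error("aligned blocks overlap on the reference")
  }
  rownames(blocks) <- NULL
  structure(list(reference_name = reference_name, query_name = query_name,
                 blocks = blocks, records = sort_records(records),
                 unaligned = unaligned),
            class = "difference_set")
}

#' @export
print.difference_set <- function(x, ...) {
  cat(sprintf("<difference_set> %s vs %s: %d block(s), %d record(s), %d unaligned segment(s)\n",
              x$reference_name, x$query_name, nrow(x$blocks),
              nrow(x$records), nrow(x$unaligned)))
  invisible(x)
}
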