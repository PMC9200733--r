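# Windowed AT/coverage tracks, unique-segment detection, read-length
# N50, annotation completeness, premature-stop QC and circular
# gene-order comparison.

#' Per-window AT fraction (and mean depth) over a sequence
#'
#' Ambiguity codes are excluded from both the numerator and denominator
#' of the AT fraction so unknown bases cannot bias composition
#' statistics. The final partial window is included and flagged.
#'
#' @param seq A `circular_sequence` (or nucleotide string).
#' @param window Window size in bp (>= 1).
#' @param depth Optional per-base depth vector of the sequence length.
#' @return `data.frame` of class `window_track` with `start`, `end`
#'   (0-based half-open), `at_fraction`, `partial`, and `depth` when
#'   supplied.
#' @export
window_stats <- function(seq, window, depth = NULL) {
  window <- as.integer(window)
  if (window < 1L) mq_config_error("window must be >= 1")
  chars <- if (is.character(seq) && length(seq) > 1L) seq else seq_chars(seq)
  n <- length(chars)
  if (!is.null(depth) && length(depth) != n)
    mq_config_error("depth array length (", length(depth),
                    ") does not match sequence length (", n, ")")
  cum_at <- cumsum(chars %in% c("A", "T"))
  cum_acgt <- cumsum(chars %in% c("A", "C", "G", "T"))
  start <- seq.int(0L, n - 1L, by = window)
  end <- pmin(start + window, n)
  at_num <- cum_at[end] - c(0L, cum_at[start[-1L]])
  at_den <- cum_acgt[end] - c(0L, cum_acgt[start[-1L]])
  out <- data.frame(start = start, end = end,
                    at_fraction = ifelse(at_den > 0, at_num / at_den,
                                         NA_real_),
                    partial = (end - start) < window)
  if (!is.null(depth)) {
    cum_d <- cumsum(as.numeric(depth))
    out$depth <- (cum_d[end] - c(0, cum_d[start[-1L]])) / (end - start)
  }
  name <- if (inherits(seq, "circular_sequence")) seq$name else NA_character_
  structure(out, class = c("window_track", "data.frame"),
            sequence_name = name, window = as.integer(window))
}

#' AT fraction of a sequence
#' @param seq A `circular_sequence` or nucleotide string.
#' @return `(A+T) / (A+C+G+T)`, ambiguity codes excluded.
#' @export
at_content <- function(seq) {
  chars <- if (is.character(seq) && length(seq) > 1L) seq else seq_chars(seq)
  sum(chars %in% c("A", "T")) / sum(chars %in% c("A", "C", "G", "T"))
}

#' Detect assembly-specific (unique) segments
#'
#' Reports stretches of sequence present in only one of the two compared
#' assemblies: the unaligned segments of a `difference_set` plus any
#' indel records at least `min_length` long. Each segment carries its AT
#' fraction (when the owning sequence is supplied) and its flanking
#' annotated genes (when annotations are supplied). Segments touching
#' both ends of a circular sequence are merged across the origin.
#'
#' @param diffs A `difference_set` from [align_assemblies()] or
#'   [differences_from_paf()].
#' @param ref,query Optional `circular_sequence` objects for AT content.
#' @param annotations Optional reference annotation `data.frame` for
#'   flanking-gene lookup.
#' @param min_length Minimum reported segment length in bp (default 200,
#'   below typical tRNA size but above alignment-gap noise).
#' @return `data.frame` with `owner`, `start`, `end`, `length`,
#'   `at_fraction`, `flank_left`, `flank_right`.
#' @export
detect_unique_segments <- function(diffs, ref = NULL, query = NULL,
                                   annotations = NULL, min_length = 200L) {
  stopifnot(inherits(diffs, "difference_set"))
  segs <- diffs$unaligned
  if (nrow(segs)) segs$bases <- NA_character_
  else segs <- data.frame(owner = character(), start = integer(),
                          end = integer(), bases = character())
  big <- diffs$records[diffs$records$size >= min_length &
                       diffs$records$kind != "substitution", , drop = FALSE]
  if (nrow(big)) {
    # large indel records are equally "present in only one assembly";
    # insertions are reported at their reference attachment point with
    # the inserted bases carried along
    segs <- rbind(segs, data.frame(
      owner = ifelse(big$kind == "insertion", "query", "ref"),
      start = big$ref_pos, end = big$ref_pos + big$size,
      bases = ifelse(big$kind == "insertion", big$query_bases,
                     big$ref_bases)))
  }
  if (nrow(segs) == 0L)
    return(data.frame(owner = character(), start = integer(),
                      end = integer(), length = integer(),
                      at_fraction = numeric(), flank_left = character(),
                      flank_right = character()))
  # merge origin-bridging pairs on circular owners
  for (owner in c("ref", "query")) {
    s <- if (owner == "ref") ref else query
    if (is.null(s) || !s$circular) next
    L <- seq_length(s)
    idx <- which(segs$owner == owner)
    lo <- idx[segs$start[idx] == 0L]
    hi <- idx[segs$end[idx] == L]
    if (length(lo) == 1L && length(hi) == 1L && lo != hi) {
      segs$end[hi] <- L + segs$end[lo]  # wrapped end, modulo L downstream
      segs <- segs[-lo, , drop = FALSE]
    }
  }
  segs$length <- segs$end - segs$start
  segs <- segs[segs$length >= min_length, , drop = FALSE]
  segs$at_fraction <- NA_real_
  segs$flank_left <- NA_character_
  segs$flank_right <- NA_character_
  for (i in seq_len(nrow(segs))) {
    if (!is.na(segs$bases[i])) {
      segs$at_fraction[i] <- at_content(seq_chars(segs$bases[i]))
    } else {
      s <- if (segs$owner[i] == "ref") ref else query
      if (!is.null(s)) {
        L <- seq_length(s)
        pos <- ((segs$start[i]:(segs$end[i] - 1L)) %% L) + 1L
        segs$at_fraction[i] <- at_content(seq_chars(s)[pos])
      }
    }
    if (!is.null(annotations)) {
      p <- segs$start[i]
      before <- annotations[annotations$end <= p, , drop = FALSE]
      after <- annotations[annotations$start >= p, , drop = FALSE]
      if (nrow(before))
        segs$flank_left[i] <- before$name[which.max(before$end)]
      if (nrow(after))
        segs$flank_right[i] <- after$name[which.min(after$start)]
    }
  }
  segs$bases <- NULL
  rownames(segs) <- NULL
  segs
}

#' Read/contig N50
#'
#' The smallest length such that sequences at least that long together
#' contain at least half of all bases.
#'
#' @param lengths Vector of positive lengths.
#' @return The N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) mq_domain_error("empty length list")
  if (any(lengths <= 0)) mq_domain_error("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

# canonical metazoan mitochondrial complement
mito_complement <- function() {
  list(PCG = c("atp6", "atp8", "cob", "cox1", "cox2", "cox3", "nad1",
               "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6"),
       tRNA = paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                              "L1", "L2", "M", "N", "P", "Q", "R", "S1",
                              "S2", "T", "V", "W", "Y")),
       rRNA = c("rrnL", "rrnS"))
}

#' Check annotation completeness against the metazoan complement
#'
#' Compares annotated gene names against the canonical complement of 13
#' protein-coding genes, 22 tRNAs and 2 rRNAs.
#'
#' @param annotations Annotation `data.frame` (`name`, `class`, ...).
#' @return List with `missing`, `duplicated` (named copy counts),
#'   `extra` (unrecognized names), and logical `complete`.
#' @export
completeness_check <- function(annotations) {
  canon <- unlist(mito_complement(), use.names = FALSE)
  present <- annotations$name[annotations$class != "other"]
  counts <- table(present)
  missing <- setdiff(canon, present)
  dup <- counts[counts > 1L]
  extra <- setdiff(present, canon)
  list(missing = missing,
       duplicated = stats::setNames(as.integer(dup), names(dup)),
       extra = extra,
       complete = length(missing) == 0L && length(dup) == 0L)
}

#' Count premature stop codons in a coding sequence
#'
#' Translates the CDS in frame 0 under the named genetic code (default
#' NCBI table 5, invertebrate mitochondrial, where TGA encodes Trp) and
#' counts stop codons strictly before the final codon. Also reports the
#' longest stop-free codon stretch as a fraction of all codons — a
#' frameshifted gene shows both internal stops and a truncated ORF.
#'
#' @param cds Nucleotide string read 5'->3' on the coding strand from the
#'   annotated start.
#' @param code Genetic code id for [Biostrings::getGeneticCode()]
#'   (default `"5"`).
#' @return List with `internal_stop_count` and `longest_orf_fraction`.
#' @export
count_premature_stops <- function(cds, code = "5") {
  cds <- toupper(if (inherits(cds, "circular_sequence")) cds$bases else cds)
  if (nchar(cds) < 3L) mq_domain_error("CDS shorter than one codon")
  extra <- nchar(cds) %% 3L
  if (extra > 0L) {
    warning("dropping trailing partial codon (", extra, " base(s))")
    cds <- substr(cds, 1L, nchar(cds) - extra)
  }
  aa <- seq_chars(as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    genetic.code = Biostrings::getGeneticCode(code),
    if.fuzzy.codon = "X")))
  n <- length(aa)
  internal <- sum(aa[-n] == "*")
  runs <- rle(aa != "*")
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(internal_stop_count = internal,
       longest_orf_fraction = longest / n)
}

#' Extract the circular gene order of an annotation set
#'
#' @param annotations Annotation `data.frame`; class `"other"` features
#'   (control region) are dropped.
#' @return `data.frame` with `name` and `strand` in circular order.
#' @export
gene_order <- function(annotations) {
  ann <- annotations[annotations$class != "other", , drop = FALSE]
  ann <- ann[order(ann$start), c("name", "strand")]
  rownames(ann) <- NULL
  ann
}

#' Format a gene order as a one-line signed string
#' @param order `data.frame` from [gene_order()].
#' @return Single string like `"+cox1 -nad6 ..."`.
#' @export
format_gene_order <- function(order) {
  paste(paste0(ifelse(order$strand == "-", "-", "+"), order$name),
        collapse = " ")
}

# canonical reflection-invariant encoding of one circular adjacency
adjacency_set <- function(ord) {
  n <- nrow(ord)
  nxt <- c(2:n, 1L)
  vapply(seq_len(n), function(i) {
    a <- paste0(ord$strand[i], ord$name[i])
    b <- paste0(ord$strand[nxt[i]], ord$name[nxt[i]])
    flip <- function(x) paste0(if (startsWith(x, "-")) "+" else "-",
                               substring(x, 2L))
    min(paste(a, b), paste(flip(b), flip(a)))
  }, "")
}

#' Compare two circular gene orders
#'
#' Treats both annotation sets as signed circular permutations over
#' their shared gene names. Reports the breakpoint count (adjacencies of
#' `a` absent from `b`, orientation-aware and invariant to rotation and
#' full reflection of either input), the shared adjacencies, and the
#' maximal inverted blocks — runs of genes whose order is reversed and
#' strand flipped in `b` relative to `a`. Both orders are compared as
#' presented: rotation of either input never changes the result, and the
#' breakpoint count is additionally invariant to full reflection, but
#' inverted blocks are reported relative to the given orientations (a
#' fully reflected `b` is the same molecule read from the other strand,
#' which exchanges which genes count as "inverted").
#'
#' @param a,b Annotation `data.frame`s or [gene_order()] tables.
#' @return List with `breakpoint_count`, `shared_adjacencies` (character
#'   vector of canonical adjacency tokens), `inverted_blocks` (list of
#'   gene-name vectors).
#' @export
gene_order_breakpoints <- function(a, b) {
  as_order <- function(x)
    if (!is.null(x$start)) gene_order(x) else x[, c("name", "strand")]
  oa <- as_order(a); ob <- as_order(b)
  shared <- intersect(oa$name, ob$name)
  oa <- oa[oa$name %in% shared, , drop = FALSE]
  ob <- ob[ob$name %in% shared, , drop = FALSE]
  if (any(duplicated(oa$name)) || any(duplicated(ob$name)))
    mq_domain_error("duplicated gene names in a circular order")
  n <- nrow(oa)
  if (n < 2L) mq_domain_error("fewer than 2 shared genes")
  rownames(oa) <- NULL; rownames(ob) <- NULL
  adj_a <- adjacency_set(oa)
  adj_b <- adjacency_set(ob)
  bp <- length(setdiff(adj_a, adj_b))
  pos_b <- match(oa$name, ob$name)
  s_b <- ob$strand[pos_b]
  flipped <- s_b != oa$strand
  # an inverted block: consecutive flipped genes in a that are reverse-
  # consecutive in b
  link <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    flipped[i] && flipped[j] &&
      ((pos_b[i] - pos_b[j]) %% n) == 1L
  }, NA)
  blocks <- list()
  if (any(flipped)) {
    idx <- which(flipped)
    # walk circularly, splitting where the reverse-consecutive link breaks
    members <- rep(NA_integer_, n)
    bid <- 0L
    for (i in seq_len(n)) {
      if (!flipped[i]) next
      prev <- if (i == 1L) n else i - 1L
      if (is.na(members[prev]) || !link[prev]) bid <- bid + 1L
      members[i] <- bid
    }
    # merge across the origin
    if (flipped[1L] && flipped[n] && link[n] &&
        members[1L] != members[n]) {
      members[members == members[1L]] <- members[n]
    }
    blocks <- unname(lapply(split(seq_len(n)[!is.na(members)],
                                  members[!is.na(members)]),
                            function(ii) oa$name[ii]))
  }
  list(breakpoint_count = bp,
       shared_adjacencies = intersect(adj_a, adj_b),
       inverted_blocks = blocks)
}

#' Control-region length from annotations
#'
#' The circular gap between the annotated tRNA-Phe end and the cox3
#' start, the canonical position of the gastropod control region.
#'
#' @param annotations Annotation `data.frame`.
#' @param genome_length Circular genome length in bp.
#' @return Gap length in bp.
#' @export
control_region_span <- function(annotations, genome_length) {
  f <- annotations[annotations$name == "trnF", , drop = FALSE]
  c3 <- annotations[annotations$name == "cox3", , drop = FALSE]
  if (nrow(f) == 0L || nrow(c3) == 0L)
    mq_domain_error("trnF and cox3 must both be annotated")
  ((c3$start[1L] - f$end[1L]) %% genome_length)
}

#' Length and AT content of an assembly FASTA
#'
#' Convenience report for checking a deposited accession against its
#' published table values.
#'
#' @param path FASTA path (first record used).
#' @return List with `name`, `length_bp`, `at_percent`.
#' @export
accession_report <- function(path) {
  s <- read_fasta(path)[[1L]]
  list(name = s$name, length_bp = seq_length(s),
       at_percent = 100 * at_content(s))
}
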