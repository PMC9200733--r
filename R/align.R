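# Canonical rotation/strand normalization of circular assemblies and
# base-level difference calling between two assemblies, either natively
# (unique k-mer anchors + chained banded gap closure) or from an external
# PAF alignment carrying cs difference strings.

# Booth's O(n) least-rotation algorithm on an integer vector; returns the
# 0-based rotation index of the lexicographically minimal rotation.
least_rotation_index <- function(v) {
  n <- length(v)
  if (n <= 1L) return(0L)
  s <- c(v, v)
  f <- rep.int(-1L, 2L * n)  # failure function, 0-based x stored at f[x + 1]
  k <- 0L
  for (j in seq_len(2L * n - 1L)) {  # 0-based j
    sj <- s[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k
}

#' Canonically rotate (and orient) a circular assembly
#'
#' With an anchor: rotates the sequence so the anchor starts at position 0
#' on the plus strand, searching both strands and allowing up to
#' `max_mismatch` mismatches. Without an anchor: rotates to the
#' lexicographically minimal rotation of the lexicographically smaller
#' strand, a reproducible canonical form requiring no biological input.
#' The applied rotation and strand flip are recorded on the result so the
#' normalization can be inverted with [denormalize_rotation()].
#'
#' @param seq A circular `circular_sequence`.
#' @param anchor Optional nucleotide string (e.g. the cox1 start).
#' @param max_mismatch Mismatches tolerated when locating the anchor.
#' @param with_indels Treat `max_mismatch` as an edit distance so the
#'   anchor is still found across small indels (useful when anchoring an
#'   error-containing draft with a clean anchor).
#' @return The normalized `circular_sequence`.
#' @export
canonical_rotation <- function(seq, anchor = NULL, max_mismatch = 0L,
                               with_indels = FALSE) {
  stopifnot(inherits(seq, "circular_sequence"))
  if (!seq$circular)
    mq_config_error("canonical_rotation requires a circular sequence")
  n <- seq_length(seq)
  find_rot <- function(bases) {
    doubled <- paste0(bases, substr(bases, 1L, min(nchar(anchor), n) - 1L))
    hits <- Biostrings::matchPattern(anchor, Biostrings::DNAString(doubled),
                                     max.mismatch = max_mismatch,
                                     with.indels = with_indels)
    st <- BiocGenerics::start(hits)
    st <- st[st <= n]
    if (length(st)) min(st) - 1L else NA_integer_
  }
  if (!is.null(anchor)) {
    anchor <- toupper(anchor)
    if (nchar(anchor) > n)
      mq_config_error("anchor longer than the sequence")
    rot <- find_rot(seq$bases)
    flip <- FALSE
    if (is.na(rot)) {
      flipped <- reverse_complement(seq$bases)
      rot <- find_rot(flipped)
      if (is.na(rot))
        mq_error(c("mitoqc_anchor_error", "mitoqc_alignment_error"),
                 "anchor not found on either strand of '", seq$name, "'")
      flip <- TRUE
    }
  } else {
    fwd <- seq$bases
    rev <- reverse_complement(fwd)
    kf <- least_rotation_index(utf8ToInt(fwd))
    kr <- least_rotation_index(utf8ToInt(rev))
    rf <- paste0(substr(fwd, kf + 1L, n), substr(fwd, 1L, kf))
    rr <- paste0(substr(rev, kr + 1L, n), substr(rev, 1L, kr))
    if (rr < rf) { flip <- TRUE;  rot <- kr }
    else         { flip <- FALSE; rot <- kf }
  }
  out <- seq
  if (flip) out$bases <- reverse_complement(out$bases)
  if (rot > 0L)
    out$bases <- paste0(substr(out$bases, rot + 1L, n),
                        substr(out$bases, 1L, rot))
  out$applied_rotation <- as.integer(rot)
  out$applied_strand_flip <- flip
  out$normalized <- TRUE
  out
}

#' Invert a recorded canonical normalization
#'
#' @param seq A `circular_sequence` returned by [canonical_rotation()].
#' @return The sequence as it was before normalization.
#' @export
denormalize_rotation <- function(seq) {
  stopifnot(inherits(seq, "circular_sequence"))
  n <- seq_length(seq)
  rot <- seq$applied_rotation
  out <- seq
  if (rot > 0L)  # undo rotation: move last `rot` bases back to the front
    out$bases <- paste0(substr(out$bases, n - rot + 1L, n),
                        substr(out$bases, 1L, n - rot))
  if (seq$applied_strand_flip) out$bases <- reverse_complement(out$bases)
  out$applied_rotation <- 0L
  out$applied_strand_flip <- FALSE
  out$normalized <- FALSE
  out
}

#' Left-normalize indel records against a reference
#'
#' Shifts every insertion/deletion to the lowest reference coordinate at
#' which it describes the same edit (rotating the indel bases through the
#' containing repeat/homopolymer run), so difference counts are
#' comparable across aligners. Idempotent.
#'
#' @param ref Reference sequence (`circular_sequence`, string, or
#'   character vector of bases).
#' @param records Difference-record `data.frame`.
#' @return The records with indels shifted left and labels recomputed.
#' @export
left_normalize_records <- function(ref, records) {
  chars <- if (is.character(ref) && length(ref) > 1L) ref else seq_chars(ref)
  if (nrow(records) == 0L) return(records)
  for (i in seq_len(nrow(records))) {
    p <- records$ref_pos[i]
    if (records$kind[i] == "deletion") {
      s <- records$size[i]
      while (p > 0L && chars[p] == chars[p + s]) p <- p - 1L
      if (p != records$ref_pos[i]) {
        records$ref_pos[i] <- p
        records$ref_bases[i] <- paste(chars[(p + 1L):(p + s)], collapse = "")
      }
    } else if (records$kind[i] == "insertion") {
      q <- seq_chars(records$query_bases[i])
      len <- length(q)
      while (p > 0L && chars[p] == q[len]) {
        q <- c(chars[p], q[-len])
        p <- p - 1L
      }
      if (p != records$ref_pos[i]) {
        records$ref_pos[i] <- p
        records$query_bases[i] <- paste(q, collapse = "")
      }
    }
  }
  difference_records(records$ref_pos, records$kind, records$ref_bases,
                     records$query_bases, records$hp_base, records$hp_len)
}

#' Apply difference records to a reference sequence
#'
#' Reconstructs the query implied by a record set: insertions add bases
#' before `ref_pos`, deletions drop reference bases, substitutions
#' replace them. Records that were left-normalized into a homopolymer run
#' already consumed by an earlier record are applied at the next
#' equivalent position within the run.
#'
#' @param ref Reference (`circular_sequence` or nucleotide string).
#' @param records Difference-record `data.frame`.
#' @return The reconstructed sequence as a bare string.
#' @export
apply_differences <- function(ref, records) {
  reconstruct(ref, records)$bases
}

# Core reconstruction; also reports each record's 0-based query position,
# which invert_differences() uses.
reconstruct <- function(ref, records) {
  chars <- if (is.character(ref) && length(ref) > 1L) ref else seq_chars(ref)
  kind_rank <- c(insertion = 1L, substitution = 2L, deletion = 3L)
  o <- order(records$ref_pos, kind_rank[records$kind])
  rec <- records[o, , drop = FALSE]
  pieces <- character(0)
  cursor <- 0L  # 0-based next reference index not yet consumed
  qn <- 0L      # query length emitted so far
  qpos <- integer(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    p <- max(rec$ref_pos[i], cursor)
    if (p > cursor) {
      pieces <- c(pieces, paste(chars[(cursor + 1L):p], collapse = ""))
      qn <- qn + (p - cursor)
      cursor <- p
    }
    qpos[i] <- qn
    s <- rec$size[i]
    if (rec$kind[i] == "insertion") {
      pieces <- c(pieces, rec$query_bases[i])
      qn <- qn + s
    } else {
      have <- paste(chars[(p + 1L):(p + s)], collapse = "")
      if (!identical(have, rec$ref_bases[i]))
        mq_config_error("record at ref position ", rec$ref_pos[i],
                        " does not match the reference (", rec$ref_bases[i],
                        " vs ", have, ")")
      if (rec$kind[i] == "substitution") {
        pieces <- c(pieces, rec$query_bases[i])
        qn <- qn + s
      }
      cursor <- cursor + s
    }
  }
  if (cursor < length(chars))
    pieces <- c(pieces,
                paste(chars[(cursor + 1L):length(chars)], collapse = ""))
  list(bases = paste(pieces, collapse = ""),
       records = rec, query_pos = qpos)
}

#' Invert a difference-record set
#'
#' Re-expresses records in query coordinates with kinds swapped
#' (insertions become deletions and vice versa), so that applying the
#' result to the query reconstructs the reference.
#'
#' @inheritParams apply_differences
#' @return Difference-record `data.frame` in query coordinates.
#' @export
invert_differences <- function(ref, records) {
  r <- reconstruct(ref, records)
  rec <- r$records
  swapped <- ifelse(rec$kind == "insertion", "deletion",
                    ifelse(rec$kind == "deletion", "insertion", rec$kind))
  difference_records(ref_pos = r$query_pos, kind = swapped,
                     ref_bases = rec$query_bases,
                     query_bases = rec$ref_bases)
}

# ---- native assembly-to-assembly alignment ---------------------------------

# Longest strictly increasing subsequence (on q) of anchors sorted by r;
# ties already impossible (unique k-mers). Returns indices of the chain.
lis_chain <- function(q) {
  n <- length(q)
  if (n == 0L) return(integer(0))
  tails <- integer(0)   # q-values of chain tails
  tidx <- integer(0)    # anchor index holding each tail
  parent <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(q[i] - 1L, tails) + 1L  # first tail >= q[i]
    parent[i] <- if (pos > 1L) tidx[pos - 1L] else 0L
    tails[pos] <- q[i]
    tidx[pos] <- i
  }
  # backtrack
  chain <- integer(0)
  i <- tidx[length(tidx)]
  while (i != 0L) {
    chain <- c(i, chain)
    i <- parent[i]
  }
  chain
}

# Extract difference records from a global pairwise alignment of the two
# gap substrings; r0/q0 are the 0-based offsets of the gap.
records_from_alignment <- function(qsub, rsub, r0) {
  al <- Biostrings::pairwiseAlignment(
    qsub, rsub, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 2, gapExtension = 1)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  n <- length(pa)
  rpos <- r0 + c(0L, cumsum(sa != "-"))[seq_len(n)]  # ref pos per column
  state <- ifelse(pa == "-", "deletion",
                  ifelse(sa == "-", "insertion",
                         ifelse(pa == sa, "match", "substitution")))
  # merge contiguous same-state indel runs into one record; substitutions
  # are emitted per column
  recs <- list()
  i <- 1L
  while (i <= n) {
    st <- state[i]
    if (st == "match") { i <- i + 1L; next }
    if (st == "substitution") {
      recs[[length(recs) + 1L]] <-
        list(pos = rpos[i], kind = st, ref = sa[i], qry = pa[i])
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && state[j + 1L] == st) j <- j + 1L
    recs[[length(recs) + 1L]] <- list(
      pos = rpos[i], kind = st,
      ref = if (st == "deletion") paste(sa[i:j], collapse = "") else "",
      qry = if (st == "insertion") paste(pa[i:j], collapse = "") else "")
    i <- j + 1L
  }
  if (!length(recs)) return(difference_records())
  difference_records(
    ref_pos = vapply(recs, `[[`, integer(1), "pos"),
    kind = vapply(recs, `[[`, character(1), "kind"),
    ref_bases = vapply(recs, `[[`, character(1), "ref"),
    query_bases = vapply(recs, `[[`, character(1), "qry"))
}

#' Align two assemblies and compute their base-level differences
#'
#' Chains k-mers unique in both sequences (longest increasing
#' subsequence, ties broken leftmost), closes inter-anchor gaps by global
#' alignment banded to the gap-length difference, and emits
#' left-normalized difference records. Gaps requiring a band wider than
#' `max_band`, or whose length difference reaches `segment_threshold`,
#' are not forced into an alignment: the surplus sequence surfaces as an
#' unaligned segment owned by the assembly that carries it.
#'
#' Both inputs should be normalized to the same rotation and strand
#' (see [canonical_rotation()]) before calling.
#'
#' @param ref,query `circular_sequence` objects.
#' @param k Anchor k-mer size.
#' @param segment_threshold Minimum one-sided surplus (bp) reported as an
#'   unaligned segment rather than an indel record.
#' @param max_band Maximum alignment band width in bp.
#' @param band_margin Extra band width beyond the gap-length difference.
#' @return A `difference_set`.
#' @export
align_assemblies <- function(ref, query, k = 15L, segment_threshold = 200L,
                             max_band = 2500L, band_margin = 50L) {
  stopifnot(inherits(ref, "circular_sequence"),
            inherits(query, "circular_sequence"))
  lr <- seq_length(ref); lq <- seq_length(query)
  if (max(lr, lq) > 3L * min(lr, lq))
    mq_config_error("sequence lengths differ by more than 3x")
  kmers <- function(bases, L) substring(bases, 1:(L - k + 1L), k:L)
  kr <- kmers(ref$bases, lr)
  kq <- kmers(query$bases, lq)
  uniq <- function(x) !(duplicated(x) | duplicated(x, fromLast = TRUE))
  ur <- uniq(kr); uq <- uniq(kq)
  m <- match(kr, kq)
  keep <- which(ur & !is.na(m))
  keep <- keep[uq[m[keep]]]
  if (!length(keep))
    mq_alignment_error("alignment failed (empty): no shared unique ",
                       k, "-mers between '", ref$name, "' and '",
                       query$name, "'")
  r <- keep - 1L               # 0-based anchor starts
  q <- m[keep] - 1L
  chain <- lis_chain(q)
  r <- r[chain]; q <- q[chain]
  if ((length(r) - 1L + k) < 0.01 * min(lr, lq))
    mq_alignment_error("alignment failed (degenerate): anchor chain covers ",
                       "under 1% of the sequences")
  # merge chained anchors on the same diagonal into exact segments
  new_seg <- c(TRUE, !(diff(r) <= k & diff(q) == diff(r)))
  seg_id <- cumsum(new_seg)
  seg <- data.frame(
    r0 = tapply(r, seg_id, min), q0 = tapply(q, seg_id, min),
    r1 = tapply(r, seg_id, max) + k, q1 = tapply(q, seg_id, max) + k)
  # trim residual overlaps between consecutive segments
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      dr <- seg$r1[i - 1L] - seg$r0[i]
      dq <- seg$q1[i - 1L] - seg$q0[i]
      d <- max(0L, dr, dq)
      seg$r0[i] <- seg$r0[i] + d
      seg$q0[i] <- seg$q0[i] + d
    }
    seg <- seg[seg$r0 < seg$r1 & seg$q0 < seg$q1, , drop = FALSE]
  }
  records <- list()
  unaligned <- list()
  blocks <- list()
  blk_r <- 0L; blk_q <- 0L  # open block start
  close_gap <- function(r0, r1, q0, q1) {
    nr <- r1 - r0; nq <- q1 - q0
    if (nr == 0L && nq == 0L) return("aligned")
    if (abs(nr - nq) >= segment_threshold ||
        abs(nr - nq) + band_margin > max_band) {
      if (min(nr, nq) == 0L) {
        # pure surplus on one side: a unique segment, boundaries exact
        if (nr > 0L)
          unaligned[[length(unaligned) + 1L]] <<-
            data.frame(owner = "ref", start = r0, end = r1)
        else
          unaligned[[length(unaligned) + 1L]] <<-
            data.frame(owner = "query", start = q0, end = q1)
        return("refused")
      }
      unaligned[[length(unaligned) + 1L]] <<-
        data.frame(owner = "ref", start = r0, end = r1)
      unaligned[[length(unaligned) + 1L]] <<-
        data.frame(owner = "query", start = q0, end = q1)
      return("refused")
    }
    if (nr == 0L) {
      records[[length(records) + 1L]] <<- difference_records(
        r0, "insertion", "", substr(query$bases, q0 + 1L, q1))
    } else if (nq == 0L) {
      records[[length(records) + 1L]] <<- difference_records(
        r0, "deletion", substr(ref$bases, r0 + 1L, r1), "")
    } else {
      records[[length(records) + 1L]] <<- records_from_alignment(
        substr(query$bases, q0 + 1L, q1),
        substr(ref$bases, r0 + 1L, r1), r0)
    }
    "aligned"
  }
  prev_r <- 0L; prev_q <- 0L
  bounds <- rbind(seg[, c("r0", "q0", "r1", "q1")],
                  data.frame(r0 = lr, q0 = lq, r1 = lr, q1 = lq))
  for (i in seq_len(nrow(bounds))) {
    status <- close_gap(prev_r, bounds$r0[i], prev_q, bounds$q0[i])
    if (status == "refused") {
      if (bounds$r0[i] > blk_r || bounds$q0[i] > blk_q) {
        if (prev_r > blk_r || prev_q > blk_q)
          blocks[[length(blocks) + 1L]] <-
            data.frame(ref_start = blk_r, ref_end = prev_r,
                       query_start = blk_q, query_end = prev_q)
        blk_r <- bounds$r0[i]; blk_q <- bounds$q0[i]
      }
    }
    prev_r <- bounds$r1[i]; prev_q <- bounds$q1[i]
  }
  if (prev_r > blk_r || prev_q > blk_q)
    blocks[[length(blocks) + 1L]] <-
      data.frame(ref_start = blk_r, ref_end = prev_r,
                 query_start = blk_q, query_end = prev_q)
  records <- if (length(records)) do.call(rbind, records)
             else difference_records()
  records <- left_normalize_records(ref, records)
  difference_set(ref$name, query$name,
                 blocks = do.call(rbind, c(blocks, list(
                   data.frame(ref_start = integer(), ref_end = integer(),
                              query_start = integer(),
                              query_end = integer())))),
                 records = records,
                 unaligned = do.call(rbind, c(unaligned, list(
                   data.frame(owner = character(), start = integer(),
                              end = integer())))))
}

# ---- PAF + cs-string route -------------------------------------------------

# Tokenize a cs difference string; errors report the failing offset.
parse_cs <- function(cs) {
  toks <- regmatches(cs, gregexpr(
    ":[0-9]+|\\*[A-Za-z][A-Za-z]|\\+[A-Za-z]+|-[A-Za-z]+|=[A-Za-z]+",
    cs))[[1L]]
  if (sum(nchar(toks)) != nchar(cs))
    mq_format_error("malformed cs string near offset ",
                    sum(nchar(toks)) + 1L, ": ", cs)
  toks
}

#' Convert PAF alignment records with cs strings to a difference set
#'
#' Walks each record's cs tokens (`:len` match, `*rq` substitution,
#' `+seq` insertion, `-seq` deletion) into difference records in
#' reference (target) coordinates, validating that the walk reproduces
#' the stated coordinate spans exactly, then left-normalizes indels.
#'
#' @param paf `data.frame` from [read_paf()] (rows pairing one reference
#'   and one query).
#' @param ref,query The corresponding `circular_sequence` objects.
#' @return A `difference_set`.
#' @export
differences_from_paf <- function(paf, ref, query) {
  if (nrow(paf) == 0L) mq_config_error("no PAF records supplied")
  if (!all(paf$target_name == ref$name) ||
      !all(paf$query_name == query$name))
    mq_config_error("PAF records do not pair '", ref$name, "' with '",
                    query$name, "'")
  if (any(paf$strand != "+"))
    mq_config_error("minus-strand PAF records: normalize the query strand ",
                    "(canonical_rotation) before difference extraction")
  if (any(is.na(paf$cs)))
    mq_config_error("PAF records lack cs:Z difference strings")
  records <- list()
  blocks <- list()
  for (i in seq_len(nrow(paf))) {
    rpos <- paf$target_start[i]
    qlen <- 0L
    for (tok in parse_cs(paf$cs[i])) {
      op <- substr(tok, 1L, 1L)
      body <- substring(tok, 2L)
      if (op == ":") {
        adv <- as.integer(body)
        rpos <- rpos + adv; qlen <- qlen + adv
      } else if (op == "=") {
        rpos <- rpos + nchar(body); qlen <- qlen + nchar(body)
      } else if (op == "*") {
        records[[length(records) + 1L]] <- difference_records(
          rpos, "substitution", toupper(substr(body, 1L, 1L)),
          toupper(substr(body, 2L, 2L)))
        rpos <- rpos + 1L; qlen <- qlen + 1L
      } else if (op == "+") {
        records[[length(records) + 1L]] <- difference_records(
          rpos, "insertion", "", toupper(body))
        qlen <- qlen + nchar(body)
      } else {  # deletion
        records[[length(records) + 1L]] <- difference_records(
          rpos, "deletion", toupper(body), "")
        rpos <- rpos + nchar(body)
      }
    }
    if (rpos != paf$target_end[i] ||
        qlen != paf$query_end[i] - paf$query_start[i])
      mq_format_error("cs walk of PAF record ", i,
                      " is inconsistent with its coordinates (reached ",
                      rpos, ", expected ", paf$target_end[i], ")")
    blocks[[length(blocks) + 1L]] <- data.frame(
      ref_start = paf$target_start[i], ref_end = paf$target_end[i],
      query_start = paf$query_start[i], query_end = paf$query_end[i])
  }
  records <- if (length(records)) do.call(rbind, records)
             else difference_records()
  difference_set(ref$name, query$name,
                 blocks = do.call(rbind, blocks),
                 records = left_normalize_records(ref, records))
}
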