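# Fixtures are built in code at test time; nothing is stored on disk.

# Random linear sequence with an AT-biased composition.
random_seq <- function(n, at = 0.66, name = "rnd", circular = FALSE) {
  bases <- paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                        prob = c(at / 2, at / 2, (1 - at) / 2,
                                 (1 - at) / 2)),
                 collapse = "")
  circular_sequence(name, bases, circular = circular)
}

# A small complete annotation fixture (all 37 canonical genes laid
# head-to-tail, 0-based half-open).
full_annotation_fixture <- function() {
  genes <- mitoqc:::mito_complement()
  name <- c(genes$PCG, genes$tRNA, genes$rRNA)
  class <- rep(c("PCG", "tRNA", "rRNA"), c(13L, 22L, 2L))
  len <- rep(c(300L, 70L, 800L), c(13L, 22L, 2L))
  start <- cumsum(c(0L, len[-length(len)]))
  data.frame(name = name, class = class, start = start,
             end = start + len, strand = "+", stringsAsFactors = FALSE)
}

# Brute-force oracle: all per-window AT fractions by direct counting.
oracle_window_at <- function(chars, window) {
  n <- length(chars)
  starts <- seq.int(0L, n - 1L, by = window)
  vapply(starts, function(s) {
    w <- chars[(s + 1L):min(s + window, n)]
    sum(w %in% c("A", "T")) / sum(w %in% c("A", "C", "G", "T"))
  }, numeric(1))
}

# Brute-force oracle for N50: the largest observed length whose
# at-least-that-long reads still hold half of all bases.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  for (l in sort(unique(lengths), decreasing = TRUE))
    if (sum(lengths[lengths >= l]) >= total / 2) return(l)
}

# Brute-force minimal rotation over all rotations of both strands.
oracle_min_rotation <- function(bases) {
  n <- nchar(bases)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(bases)))
  rots <- function(s) vapply(0:(n - 1L), function(k)
    paste0(substr(s, k + 1L, n), substr(s, 1L, k)), "")
  min(c(rots(bases), rots(rc)))
}

# Brute-force homopolymer run length at a 0-based position.
oracle_run_length <- function(chars, pos0) {
  i <- pos0 + 1L
  b <- chars[i]
  l <- i; while (l > 1L && chars[l - 1L] == b) l <- l - 1L
  r <- i; while (r < length(chars) && chars[r + 1L] == b) r <- r + 1L
  r - l + 1L
}

# Brute-force circular adjacency multiset (orientation-aware canonical
# tokens), independent of the package's encoding order.
oracle_adjacencies <- function(ord) {
  n <- nrow(ord)
  sapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    a <- paste0(ord$strand[i], ord$name[i])
    b <- paste0(ord$strand[j], ord$name[j])
    flip <- function(x) paste0(if (startsWith(x, "-")) "+" else "-",
                               substring(x, 2L))
    min(paste(a, b), paste(flip(b), flip(a)))
  })
}
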