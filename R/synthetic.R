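# Seeded simulator of gastropod-like circular mitogenomes, nanopore-style
# corruption with known truth, and technology-specific coverage tracks.
# Every downstream stage of the package can be exercised against these
# known-truth fixtures without any external data.

#' Default mitogenome gene template
#'
#' An ordered, gastropod-like arrangement of the canonical metazoan
#' mitochondrial complement (13 protein-coding genes, 22 tRNAs, 2 rRNAs)
#' with tRNA-Phe immediately preceding the control region and cox3
#' following it. Lengths are typical (slightly compact) values so the
#' complement plus a 1-2 kb control region fits a 16 kb molecule.
#'
#' @return `data.frame` with columns `name`, `class`, `length`, `strand`.
#' @export
default_gene_template <- function() {
  tr <- function(name) data.frame(name = name, class = "tRNA",
                                  length = 65L, strand = "+")
  pc <- function(name, len, strand = "+")
    data.frame(name = name, class = "PCG", length = as.integer(len),
               strand = strand)
  rr <- function(name, len) data.frame(name = name, class = "rRNA",
                                       length = as.integer(len), strand = "+")
  out <- rbind(
    pc("cox1", 1500), tr("trnL2"), pc("cox2", 681), tr("trnD"),
    pc("atp8", 150), pc("atp6", 660), tr("trnM"), tr("trnY"), tr("trnC"),
    tr("trnW"), tr("trnQ"), tr("trnG"), tr("trnE"), rr("rrnS", 700),
    tr("trnV"), rr("rrnL", 1100), tr("trnL1"), pc("nad1", 900), tr("trnP"),
    pc("nad6", 480), pc("cob", 1101), tr("trnS2"), tr("trnT"),
    pc("nad4L", 279, "-"), pc("nad4", 1299, "-"), tr("trnH"),
    pc("nad5", 1500, "-"), tr("trnS1"), pc("nad2", 999), tr("trnI"),
    tr("trnK"), tr("trnA"), tr("trnR"), tr("trnN"), pc("nad3", 339),
    tr("trnF"), pc("cox3", 780))
  out$strand[out$name == "trnH"] <- "-"
  rownames(out) <- NULL
  out
}

#' Simulation configuration for a synthetic mitogenome
#'
#' @param genome_length Total molecule length in bp.
#' @param background_at AT fraction of coding/background sequence
#'   (gastropod mitogenomes run roughly 0.62-0.70).
#' @param control_region_length Length of the non-coding control region,
#'   placed between tRNA-Phe and cox3.
#' @param control_region_at AT fraction of the control region (highly
#'   AT-rich in the emulated genomes, ~0.987).
#' @param homopolymer_enrichment Probability that a base simply extends
#'   the previous base's run instead of being drawn fresh; raises run
#'   lengths above the i.i.d. baseline.
#' @param gene_template Ordered `data.frame` (`name`, `class`, `length`,
#'   `strand`) of features; see [default_gene_template()].
#' @param seed Mandatory integer seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 16000L,
                              background_at = 0.66,
                              control_region_length = 1000L,
                              control_region_at = 0.987,
                              homopolymer_enrichment = 0.15,
                              gene_template = default_gene_template(),
                              seed) {
  if (missing(seed)) mq_config_error("seed is mandatory")
  genome_length <- as.integer(genome_length)
  control_region_length <- as.integer(control_region_length)
  if (control_region_length >= genome_length)
    mq_config_error("control_region_length must be < genome_length")
  if (control_region_length < 1L && control_region_at > 0)
    mq_config_error("control region AT requested but region has zero length")
  for (f in c(background_at, control_region_at))
    if (f < 0 || f > 1) mq_config_error("AT fractions must lie in [0, 1]")
  if (homopolymer_enrichment < 0 || homopolymer_enrichment >= 1)
    mq_config_error("homopolymer_enrichment must lie in [0, 1)")
  need <- sum(gene_template$length) + control_region_length
  if (need > genome_length)
    mq_config_error("gene lengths + control region (", need,
                    " bp) exceed genome_length (", genome_length, " bp)")
  structure(list(genome_length = genome_length,
                 background_at = background_at,
                 control_region_length = control_region_length,
                 control_region_at = control_region_at,
                 homopolymer_enrichment = homopolymer_enrichment,
                 gene_template = gene_template,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Draw n bases with per-position AT probability `at` (scalar or vector)
# and run-length enrichment h (copy previous base with prob h).
draw_bases <- function(n, at, h) {
  at <- rep_len(at, n)
  fresh <- character(n)
  u <- stats::runif(n)
  fresh[u < at / 2] <- "A"
  fresh[u >= at / 2 & u < at] <- "T"
  fresh[u >= at & u < at + (1 - at) / 2] <- "G"
  fresh[u >= at + (1 - at) / 2] <- "C"
  if (h > 0 && n > 1L) {
    copy <- stats::runif(n) < h
    copy[1L] <- FALSE
    # value at i = fresh value of the most recent non-copy position <= i
    src <- cummax(ifelse(copy, 0L, seq_len(n)))
    fresh <- fresh[src]
  }
  fresh
}

# n_codon codons at the given AT fraction: ATG start, TAA stop, internal
# stop codons (TAA/TAG, invertebrate mitochondrial code) rejected.
draw_codons <- function(n_codon, at) {
  stopifnot(n_codon >= 2L)
  body <- matrix(draw_bases(3L * (n_codon - 2L), at, 0), ncol = 3L,
                 byrow = TRUE)
  repeat {
    codon <- paste0(body[, 1L], body[, 2L], body[, 3L])
    bad <- codon %in% c("TAA", "TAG")
    if (!any(bad)) break
    body[bad, ] <- matrix(draw_bases(3L * sum(bad), at, 0), ncol = 3L,
                          byrow = TRUE)
  }
  c("A", "T", "G", as.vector(t(body)), "T", "A", "A")
}

#' Simulate a circular mitogenome with annotations
#'
#' Lays the gene template around a circular molecule starting at the
#' cox1 start, inserts one contiguous AT-rich control region between
#' tRNA-Phe and cox3, distributes any remaining length as short
#' intergenic spacers, and draws sequence as an i.i.d. base process with
#' optional homopolymer (run-length) enrichment.
#'
#' @param config A [simulation_config()].
#' @return List with `sequence` (a `circular_sequence`) and `annotations`
#'   (`data.frame`: `name`, `class`, `start`, `end`, `strand`, 0-based
#'   half-open; the control region appears as class `"other"`).
#' @export
simulate_mitogenome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tmpl <- config$gene_template
  n_feat <- nrow(tmpl)
  cr_after <- match("trnF", tmpl$name)
  if (is.na(cr_after)) cr_after <- n_feat
  # assemble the feature layout, control region included
  layout <- data.frame(name = append(tmpl$name, "control_region", cr_after),
                       class = append(tmpl$class, "other", cr_after),
                       length = append(tmpl$length,
                                       config$control_region_length, cr_after),
                       strand = append(tmpl$strand, "+", cr_after),
                       stringsAsFactors = FALSE)
  slack <- config$genome_length - sum(layout$length)
  gaps <- rep.int(slack %/% nrow(layout), nrow(layout))
  extra <- slack %% nrow(layout)
  if (extra > 0L) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L
  starts <- cumsum(c(0L, (layout$length + gaps)[-nrow(layout)]))
  layout$start <- starts
  layout$end <- starts + layout$length
  withr::with_seed(config$seed, {
    at <- rep(config$background_at, config$genome_length)
    cr <- layout[layout$name == "control_region", ]
    if (cr$length > 0L)
      at[(cr$start + 1L):cr$end] <- config$control_region_at
    chars <- draw_bases(config$genome_length, at,
                        config$homopolymer_enrichment)
    # protein-coding genes are rewritten codon-wise, stop-free in frame
    # under the invertebrate mitochondrial code (internal TAA/TAG
    # rejected), with an ATG start and TAA stop, so a clean assembly
    # translates without premature stops
    pcg <- layout[layout$class == "PCG", , drop = FALSE]
    for (i in seq_len(nrow(pcg))) {
      n_codon <- pcg$length[i] %/% 3L
      cds <- draw_codons(n_codon, config$background_at)
      if (pcg$strand[i] == "-") cds <- seq_chars(reverse_complement(
        paste(cds, collapse = "")))
      chars[(pcg$start[i] + 1L):pcg$end[i]] <- cds
    }
  })
  ann <- layout[layout$length > 0L,
                c("name", "class", "start", "end", "strand")]
  rownames(ann) <- NULL
  list(sequence = circular_sequence("sim_mitogenome",
                                    paste(chars, collapse = ""),
                                    circular = TRUE),
       annotations = ann)
}

#' Nanopore-style error model
#'
#' Per-position Bernoulli corruption: indel probability at a position
#' scales multiplicatively with the homopolymer run length containing it
#' (`base_indel_rate * runlength_multiplier^(run_len - 1)`), reproducing
#' the positive indel-vs-run-length trend of nanopore consensus errors;
#' substitutions occur at a flat rate. Indels are single-base by default.
#'
#' @param base_substitution_rate Per-bp substitution probability.
#' @param base_indel_rate Per-bp indel probability at run length 1.
#' @param runlength_multiplier Multiplicative indel-rate increase per
#'   unit of run length; must be >= 1.
#' @param max_indel_size Maximum indel size (default 1; single-base
#'   indels dominate the emulated error spectrum).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `error_model`.
#' @export
error_model <- function(base_substitution_rate = 8e-4,
                        base_indel_rate = 2e-3,
                        runlength_multiplier = 1.35,
                        max_indel_size = 1L, seed) {
  if (missing(seed)) mq_config_error("seed is mandatory")
  if (base_substitution_rate < 0 || base_substitution_rate > 1 ||
      base_indel_rate < 0 || base_indel_rate > 1)
    mq_config_error("rates must lie in [0, 1]")
  if (runlength_multiplier < 1)
    mq_config_error("runlength_multiplier must be >= 1")
  if (max_indel_size < 1L) mq_config_error("max_indel_size must be >= 1")
  structure(list(base_substitution_rate = base_substitution_rate,
                 base_indel_rate = base_indel_rate,
                 runlength_multiplier = runlength_multiplier,
                 max_indel_size = as.integer(max_indel_size),
                 seed = as.integer(seed)),
            class = "error_model")
}

# Build raw (unnormalized) records for chosen event positions.
build_event_records <- function(chars, pos, kind, ins_dir = NULL,
                                sizes = NULL) {
  n <- length(pos)
  if (is.null(sizes)) sizes <- rep.int(1L, n)
  ref_bases <- character(n); query_bases <- character(n)
  for (i in seq_len(n)) {
    p <- pos[i]; s <- sizes[i]
    if (kind[i] == "substitution") {
      rb <- chars[p + 1L]
      qb <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
      ref_bases[i] <- rb; query_bases[i] <- qb
    } else if (kind[i] == "deletion") {
      s <- min(s, length(chars) - p)
      ref_bases[i] <- paste(chars[(p + 1L):(p + s)], collapse = "")
      query_bases[i] <- ""
    } else {
      ref_bases[i] <- ""
      query_bases[i] <- strrep(chars[p + 1L], s)
    }
  }
  difference_records(ref_pos = pos, kind = kind,
                     ref_bases = ref_bases, query_bases = query_bases)
}

#' Corrupt a sequence under a nanopore-style error model
#'
#' Applies the per-position Bernoulli process of [error_model()] and
#' returns both the corrupted copy and the exact truth list of injected
#' differences in reference coordinates, left-normalized so they are
#' directly comparable with aligner output.
#'
#' @param seq A `circular_sequence`.
#' @param model An [error_model()].
#' @return List with `corrupted` (`circular_sequence`) and `truth`
#'   (difference-record `data.frame`).
#' @export
inject_errors <- function(seq, model) {
  stopifnot(inherits(seq, "circular_sequence"), inherits(model, "error_model"))
  chars <- seq_chars(seq)
  runs <- run_info(chars)
  p_ind <- model$base_indel_rate *
    model$runlength_multiplier^(runs$len - 1L)
  if (any(p_ind > 1)) {
    bad <- min(runs$len[p_ind > 1])
    mq_config_error("indel rate exceeds 1 at homopolymer run length ", bad,
                    "; lower base_indel_rate or runlength_multiplier")
  }
  withr::with_seed(model$seed, {
    u <- stats::runif(length(chars))
    is_ind <- u < p_ind
    is_sub <- !is_ind &
      (stats::runif(length(chars)) < model$base_substitution_rate)
    pos <- sort(c(which(is_ind), which(is_sub))) - 1L
    kind <- ifelse((pos + 1L) %in% which(is_ind),
                   NA_character_, "substitution")
    ind_idx <- which(is.na(kind))
    kind[ind_idx] <- sample(c("insertion", "deletion"),
                            length(ind_idx), replace = TRUE)
    sizes <- rep.int(1L, length(pos))
    if (model$max_indel_size > 1L && length(ind_idx))
      sizes[ind_idx] <- sample.int(model$max_indel_size,
                                   length(ind_idx), replace = TRUE,
                                   prob = 2^-(seq_len(model$max_indel_size)))
    rec <- build_event_records(chars, pos, kind, sizes = sizes)
  })
  finalize_injection(seq, chars, rec)
}

# Shared tail of the injectors: drop events that would collide after
# multi-base deletions, apply, left-normalize the truth.
finalize_injection <- function(seq, chars, rec) {
  if (nrow(rec) > 1L) {
    # deletions longer than 1 bp may swallow a later event; drop the later
    keep <- rep(TRUE, nrow(rec))
    reach <- rec$ref_pos + ifelse(rec$kind == "insertion", 0L,
                                  nchar(rec$ref_bases))
    for (i in 2:nrow(rec))
      if (rec$ref_pos[i] < max(reach[seq_len(i - 1L)][keep[seq_len(i - 1L)]]))
        keep[i] <- FALSE
    rec <- rec[keep, , drop = FALSE]
  }
  corrupted_bases <- apply_differences(seq$bases, rec)
  truth <- sort_records(left_normalize_records(chars, rec))
  corrupted <- seq
  corrupted$name <- paste0(seq$name, "_corrupted")
  corrupted$bases <- corrupted_bases
  list(corrupted = corrupted, truth = truth)
}

#' Inject a stratified error mixture with stated composition
#'
#' Draws a fixed number of single-base events whose composition follows
#' stated target fractions — share of single-base indels among all
#' errors, share of T/A indels among indels, and share of all errors
#' falling in homopolymer runs — by sampling event loci from the
#' corresponding position strata of the reference. Used to emulate an
#' empirically observed error spectrum directly, independent of the
#' rate-based model in [inject_errors()].
#'
#' @param seq A `circular_sequence`.
#' @param n_events Number of events to inject.
#' @param p_single_indel Probability an event is a single-base indel
#'   (rest are substitutions).
#' @param p_ta_given_indel Probability an indel sits on an A or T base.
#' @param p_homopolymer Probability an event falls in a homopolymer run
#'   of length >= `min_run`.
#' @param min_run Run length defining "homopolymer" (default 3).
#' @param min_spacing Minimum distance in bp between event loci.
#' @param edge_exclusion Keep events at least this many bp from the
#'   sequence ends.
#' @param seed Mandatory integer seed.
#' @return List with `corrupted` and left-normalized `truth`, as
#'   [inject_errors()].
#' @export
inject_error_mixture <- function(seq, n_events, p_single_indel = 0.75,
                                 p_ta_given_indel = 0.64,
                                 p_homopolymer = 0.712, min_run = 3L,
                                 min_spacing = 0L, edge_exclusion = 0L,
                                 seed) {
  if (missing(seed)) mq_config_error("seed is mandatory")
  stopifnot(inherits(seq, "circular_sequence"))
  chars <- seq_chars(seq)
  runs <- run_info(chars)
  n <- length(chars)
  ok <- seq_len(n) > edge_exclusion & seq_len(n) <= n - edge_exclusion
  in_hp <- runs$len >= min_run
  is_ta <- chars %in% c("A", "T")
  strata <- list(
    ind_hp_ta  = which(ok & in_hp & is_ta),
    ind_hp_gc  = which(ok & in_hp & !is_ta),
    ind_lo_ta  = which(ok & !in_hp & is_ta),
    ind_lo_gc  = which(ok & !in_hp & !is_ta),
    sub_hp     = which(ok & in_hp),
    sub_lo     = which(ok & !in_hp))
  withr::with_seed(as.integer(seed), {
    chosen <- integer(0)
    pos <- integer(n_events); kind <- character(n_events)
    for (i in seq_len(n_events)) {
      indel <- stats::runif(1) < p_single_indel
      hp <- stats::runif(1) < p_homopolymer
      if (indel) {
        ta <- stats::runif(1) < p_ta_given_indel
        key <- paste0("ind_", if (hp) "hp" else "lo", "_",
                      if (ta) "ta" else "gc")
      } else key <- paste0("sub_", if (hp) "hp" else "lo")
      pool <- strata[[key]]
      placed <- FALSE
      for (try in seq_len(200L)) {
        cand <- pool[sample.int(length(pool), 1L)]
        if (!length(chosen) || min(abs(chosen - cand)) > min_spacing) {
          placed <- TRUE; break
        }
      }
      if (!placed)
        mq_config_error("could not place event ", i,
                        " with min_spacing = ", min_spacing,
                        " in stratum ", key)
      chosen <- c(chosen, cand)
      pos[i] <- cand - 1L
      kind[i] <- if (indel) sample(c("insertion", "deletion"), 1L)
                 else "substitution"
    }
    o <- order(pos)
    rec <- build_event_records(chars, pos[o], kind[o])
  })
  finalize_injection(seq, chars, rec)
}

#' Technology-specific coverage model
#'
#' Nanopore coverage is flat in expectation; Illumina coverage collapses
#' over windows whose AT fraction exceeds `at_threshold` (expected depth
#' multiplied by `at_suppression`), emulating the short-read dropout seen
#' over highly AT-biased control regions.
#'
#' @param technology `"ont"` or `"illumina"`.
#' @param mean_depth Expected depth over unbiased sequence.
#' @param at_threshold AT fraction above which suppression applies
#'   (Illumina only).
#' @param at_suppression Multiplier on expected depth above the
#'   threshold, in `[0, 1]`.
#' @param noise_dispersion Negative-binomial dispersion of per-window
#'   depth; 0 gives noiseless expectation.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `coverage_model`.
#' @export
coverage_model <- function(technology = c("ont", "illumina"),
                           mean_depth = 30, at_threshold = 0.85,
                           at_suppression = 0.05, noise_dispersion = 0.1,
                           seed) {
  if (missing(seed)) mq_config_error("seed is mandatory")
  technology <- match.arg(technology)
  if (mean_depth <= 0) mq_config_error("mean_depth must be > 0")
  if (at_suppression < 0 || at_suppression > 1)
    mq_config_error("at_suppression must lie in [0, 1]")
  if (noise_dispersion < 0)
    mq_config_error("noise_dispersion must be >= 0")
  structure(list(technology = technology, mean_depth = mean_depth,
                 at_threshold = at_threshold,
                 at_suppression = at_suppression,
                 noise_dispersion = noise_dispersion,
                 seed = as.integer(seed)),
            class = "coverage_model")
}

#' Simulate a per-window coverage track
#'
#' @param seq A `circular_sequence`.
#' @param model A [coverage_model()].
#' @param window Window size in bp (50 bp mirrors the emulated tracks).
#' @return A window-track `data.frame` (see [window_stats()]) with a
#'   `depth` column.
#' @export
simulate_coverage <- function(seq, model, window = 50L) {
  stopifnot(inherits(seq, "circular_sequence"),
            inherits(model, "coverage_model"))
  if (window > seq_length(seq))
    mq_config_error("window (", window, ") exceeds sequence length (",
                    seq_length(seq), ")")
  track <- window_stats(seq, window)
  expected <- rep(model$mean_depth, nrow(track))
  if (model$technology == "illumina")
    expected[track$at_fraction > model$at_threshold] <-
      model$mean_depth * model$at_suppression
  if (model$noise_dispersion == 0) {
    track$depth <- expected
  } else {
    withr::with_seed(model$seed,
      track$depth <- stats::rnbinom(length(expected), mu = expected,
                                    size = 1 / model$noise_dispersion))
  }
  track
}
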