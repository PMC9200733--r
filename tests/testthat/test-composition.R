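# Windows, unique segments, N50, completeness, premature stops and
# circular gene-order comparison.

test_that("window AT fractions match direct counting", {
  t1 <- window_stats(strrep("A", 100), 50)
  expect_identical(nrow(t1), 2L)
  expect_true(all(t1$at_fraction == 1))
  t2 <- window_stats(strrep("AG", 50), 50)  # alternating AT / GC content
  expect_true(all(t2$at_fraction == 0.5))

  set.seed(21)
  s <- random_seq(5000, name = "s")
  tr <- window_stats(s, 50)
  expect_equal(tr$at_fraction, oracle_window_at(seq_chars(s), 50))

  # ambiguity codes drop out of numerator and denominator
  t3 <- window_stats("AANNTT", 6)
  expect_equal(t3$at_fraction, 1)

  # final partial window flagged
  t4 <- window_stats(strrep("A", 120), 50)
  expect_identical(t4$partial, c(FALSE, FALSE, TRUE))
  expect_identical(t4$end[3] - t4$start[3], 20L)

  expect_error(window_stats(s, 50, depth = rep(1, 10)),
               class = "mitoqc_config_error")
  d <- window_stats(s, 50, depth = rep(2, 5000))
  expect_true(all(d$depth == 2))
})

test_that("window AT is mirror-symmetric under reverse complement", {
  set.seed(22)
  s <- random_seq(1200, name = "s")
  fwd <- window_stats(s, 50)
  rev <- window_stats(reverse_complement(s), 50)
  expect_equal(fwd$at_fraction, rev(rev$at_fraction))
})

test_that("a simulated AT-rich insertion is recovered as a unique segment", {
  cfg <- simulation_config(seed = 23)
  sim <- simulate_mitogenome(cfg)
  set.seed(24)
  ins <- paste(sample(c("A", "T", "G", "C"), 2000, TRUE,
                      prob = c(0.4935, 0.4935, 0.0065, 0.0065)),
               collapse = "")
  ref <- sim$sequence
  qry <- circular_sequence("with_insert",
                           paste0(substr(ref$bases, 1, 8000), ins,
                                  substr(ref$bases, 8001, 16000)),
                           circular = TRUE)
  d <- align_assemblies(ref, qry)
  segs <- detect_unique_segments(d, ref = ref, query = qry,
                                 annotations = sim$annotations,
                                 min_length = 500)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$owner, "query")
  expect_lte(abs(segs$start - 8000L), 10L)
  expect_lte(abs(segs$length - 2000L), 10L)
  expect_lt(abs(segs$at_fraction - at_content(seq_chars(ins))), 0.02)

  # identical assemblies: nothing unique
  expect_identical(nrow(detect_unique_segments(align_assemblies(ref, ref),
                                               ref = ref, query = ref)), 0L)
})

test_that("the segment length threshold filters short insertions", {
  set.seed(25)
  g <- random_seq(6000, name = "g")
  ins1 <- random_seq(868, name = "i1")$bases
  ins2 <- random_seq(300, name = "i2")$bases
  qb <- paste0(substr(g$bases, 1, 2000), ins1,
               substr(g$bases, 2001, 4000), ins2,
               substr(g$bases, 4001, 6000))
  q <- circular_sequence("q", qb)
  d <- align_assemblies(g, q)
  segs <- detect_unique_segments(d, ref = g, query = q, min_length = 500)
  expect_identical(nrow(segs), 1L)
  expect_lte(abs(segs$length - 868L), 10L)
})

test_that("n50 equals exhaustive search over candidate cutoffs", {
  expect_identical(n50(100), 100)
  expect_identical(n50(c(1, 1, 1, 1, 4)), 4)
  expect_error(n50(numeric(0)), class = "mitoqc_domain_error")
  expect_error(n50(c(5, 0)), class = "mitoqc_domain_error")
  set.seed(26)
  for (i in 1:100) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    expect_identical(n50(lens), oracle_n50(lens))
  }
  # k identical reads of length l always give l
  expect_identical(n50(rep(777, 13)), 777)
})

test_that("completeness check flags missing, duplicated and extra genes", {
  ann <- full_annotation_fixture()
  ok <- completeness_check(ann)
  expect_true(ok$complete)
  expect_length(ok$missing, 0L)

  cfl <- ann[!ann$name %in% c("nad5", "trnH", "trnF"), ]
  res <- completeness_check(cfl)
  expect_setequal(res$missing, c("nad5", "trnH", "trnF"))
  expect_false(res$complete)

  dup <- rbind(ann, ann[ann$name == "cox1", ])
  res2 <- completeness_check(dup)
  expect_identical(res2$duplicated, c(cox1 = 2L))

  odd <- rbind(ann, data.frame(name = "orfX", class = "PCG", start = 0L,
                               end = 30L, strand = "+"))
  expect_identical(completeness_check(odd)$extra, "orfX")
})

test_that("premature stops respect the genetic code table", {
  expect_identical(count_premature_stops("ATGTTTTAA")$internal_stop_count,
                   0L)
  # TGA is Trp under the invertebrate mitochondrial code
  expect_identical(count_premature_stops("ATGTGATTTTAA")$internal_stop_count,
                   0L)
  expect_identical(count_premature_stops("ATGTGATTTTAA",
                                         code = "1")$internal_stop_count,
                   1L)
  expect_error(count_premature_stops("AT"), class = "mitoqc_domain_error")
  expect_warning(count_premature_stops("ATGTTTTAAG"), "partial codon")
})

test_that("a frameshift produces the stops an independent walk predicts", {
  set.seed(27)
  stops5 <- c("TAA", "TAG")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  good <- setdiff(codons, stops5)
  cds <- paste(c("ATG", sample(good, 298, TRUE), "TAA"), collapse = "")
  expect_identical(count_premature_stops(cds)$internal_stop_count, 0L)
  # delete one base at codon 100: frameshifted tail
  mut <- paste0(substr(cds, 1, 299), substr(cds, 301, nchar(cds)))
  mut <- substr(mut, 1, 897)  # keep in-frame length
  res <- count_premature_stops(mut)
  # independent frame-walk oracle on the mutated sequence
  oracle <- sum(vapply(seq(1, 894, by = 3), function(i)
    substr(mut, i, i + 2) %in% stops5, NA))
  expect_identical(res$internal_stop_count, as.integer(oracle))
  expect_gt(oracle, 0)
  expect_lt(res$longest_orf_fraction, 1)
})

test_that("gene order breakpoints match a brute-force adjacency oracle", {
  genes <- paste0("g", 1:8)
  a <- data.frame(name = genes, strand = "+")
  b <- a
  b[2:5, ] <- data.frame(name = rev(genes[2:5]), strand = "-")
  res <- gene_order_breakpoints(a, b)
  expect_length(res$inverted_blocks, 1L)
  expect_setequal(res$inverted_blocks[[1]], genes[2:5])
  expect_identical(res$breakpoint_count,
                   length(setdiff(oracle_adjacencies(a),
                                  oracle_adjacencies(b))))

  same <- gene_order_breakpoints(a, a)
  expect_identical(same$breakpoint_count, 0L)
  expect_length(same$inverted_blocks, 0L)

  set.seed(28)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    oa <- data.frame(name = paste0("g", 1:n),
                     strand = sample(c("+", "-"), n, TRUE))
    ob <- oa[sample(n), ]
    ob$strand <- sample(c("+", "-"), n, TRUE)
    res <- gene_order_breakpoints(oa, ob)
    expect_identical(res$breakpoint_count,
                     length(setdiff(oracle_adjacencies(oa),
                                    oracle_adjacencies(ob))))
    # symmetry and rotation invariance
    rev_res <- gene_order_breakpoints(ob, oa)
    expect_identical(rev_res$breakpoint_count, res$breakpoint_count)
    rot <- rbind(ob[3:n, ], ob[1:2, ])
    expect_identical(gene_order_breakpoints(oa, rot)$breakpoint_count,
                     res$breakpoint_count)
  }
  expect_error(gene_order_breakpoints(a[1, , drop = FALSE], b),
               class = "mitoqc_domain_error")
})

test_that("an 11-gene protein-coding inversion is called as one block", {
  pcgs <- mitoqc:::mito_complement()$PCG
  a <- data.frame(name = c("cox1", "cox3", setdiff(pcgs, c("cox1", "cox3"))),
                  strand = "+")
  b <- a
  b[3:13, ] <- data.frame(name = rev(a$name[3:13]), strand = "-")
  res <- gene_order_breakpoints(a, b)
  expect_length(res$inverted_blocks, 1L)
  expect_identical(sort(res$inverted_blocks[[1]]),
                   sort(setdiff(pcgs, c("cox1", "cox3"))))
  expect_false(any(c("cox1", "cox3") %in% res$inverted_blocks[[1]]))
})

test_that("control region span is the circular trnF-to-cox3 gap", {
  cfg <- simulation_config(seed = 29, control_region_length = 1500)
  sim <- simulate_mitogenome(cfg)
  span <- control_region_span(sim$annotations, 16000)
  cr <- sim$annotations[sim$annotations$name == "control_region", ]
  expect_gte(span, cr$end - cr$start)
  expect_lte(span - (cr$end - cr$start), 100)  # only spacer slack on top
})
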