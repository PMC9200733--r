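# Simulator: genome composition, error injection truth, coverage models.

test_that("simulated mitogenome honors length, composition and determinism", {
  cfg <- simulation_config(genome_length = 16000, control_region_at = 0.987,
                           control_region_length = 2000, seed = 1)
  sim <- simulate_mitogenome(cfg)
  expect_s3_class(sim$sequence, "circular_sequence")
  expect_identical(seq_length(sim$sequence), 16000L)
  expect_true(sim$sequence$circular)

  cr <- sim$annotations[sim$annotations$name == "control_region", ]
  expect_identical(cr$end - cr$start, 2000L)
  cr_at <- at_content(seq_chars(sim$sequence)[(cr$start + 1):cr$end])
  expect_gte(cr_at, 0.967)
  expect_lte(cr_at, 1.0)

  # control region sits between trnF and cox3
  ann <- sim$annotations
  expect_identical(ann$name[which(ann$name == "control_region") - 1L], "trnF")
  expect_identical(ann$name[which(ann$name == "control_region") + 1L], "cox3")

  sim2 <- simulate_mitogenome(cfg)
  expect_identical(sim$sequence$bases, sim2$sequence$bases)
  expect_identical(sim$annotations, sim2$annotations)

  # full canonical complement, in-frame stop-free genes
  expect_true(completeness_check(sim$annotations)$complete)
  pcg <- ann[ann$class == "PCG", ]
  chars <- seq_chars(sim$sequence)
  stops <- vapply(seq_len(nrow(pcg)), function(i) {
    cds <- paste(chars[(pcg$start[i] + 1):pcg$end[i]], collapse = "")
    if (pcg$strand[i] == "-") cds <- reverse_complement(cds)
    count_premature_stops(cds)$internal_stop_count
  }, numeric(1))
  expect_identical(sum(stops), 0)
})

test_that("infeasible simulation configs are rejected", {
  expect_error(simulation_config(seed = 1, control_region_length = 17000),
               class = "mitoqc_config_error")
  expect_error(simulation_config(seed = 1, genome_length = 14000,
                                 control_region_length = 2000),
               class = "mitoqc_config_error")
  expect_error(simulation_config(genome_length = 16000),
               class = "mitoqc_config_error")  # seed mandatory
})

test_that("error injection count matches its binomial expectation", {
  cfg <- simulation_config(seed = 2)
  sim <- simulate_mitogenome(cfg)
  em <- error_model(base_indel_rate = 1 / 70.8, base_substitution_rate = 0,
                    runlength_multiplier = 1, seed = 5)
  inj <- inject_errors(sim$sequence, em)
  expected <- 16000 / 70.8
  sd3 <- 3 * sqrt(16000 * (1 / 70.8) * (1 - 1 / 70.8))
  expect_lt(abs(nrow(inj$truth) - expected), sd3)
})

test_that("zero rates leave the sequence untouched", {
  s <- random_seq(500, name = "s")
  inj <- inject_errors(s, error_model(0, 0, 1, seed = 3))
  expect_identical(inj$corrupted$bases, s$bases)
  expect_identical(nrow(inj$truth), 0L)
})

test_that("truth records replay forwards and backwards exactly", {
  set.seed(41)
  for (rep in 1:3) {
    s <- random_seq(2000, name = "s")
    inj <- inject_errors(s, error_model(5e-3, 8e-3, 1.3, seed = 10 + rep))
    expect_identical(apply_differences(s$bases, inj$truth),
                     inj$corrupted$bases)
    inv <- invert_differences(s$bases, inj$truth)
    expect_identical(apply_differences(inj$corrupted$bases, inv), s$bases)
    # length conservation
    delta <- sum(inj$truth$size[inj$truth$kind == "insertion"]) -
      sum(inj$truth$size[inj$truth$kind == "deletion"])
    expect_identical(nchar(inj$corrupted$bases), nchar(s$bases) + delta)
  }
})

test_that("run-length scaling concentrates indels in homopolymers", {
  cfg <- simulation_config(seed = 6)
  sim <- simulate_mitogenome(cfg)
  em <- error_model(base_substitution_rate = 0, base_indel_rate = 0.015,
                    runlength_multiplier = 1.25, seed = 8)
  inj <- inject_errors(sim$sequence, em)
  expect_gte(nrow(inj$truth), 200)
  rec <- attribute_homopolymer(sim$sequence, inj$truth)
  chars <- seq_chars(sim$sequence)
  genome_frac <- mean(mitoqc:::run_info(chars)$len >= 3)
  expect_gt(mean(rec$in_homopolymer), genome_frac)
})

test_that("rates that cap above 1 name the offending run length", {
  s <- circular_sequence("hp", paste0("ACGT", strrep("A", 30), "CGTA"))
  expect_error(inject_errors(s, error_model(0, 0.5, 2, seed = 1)),
               "run length", class = "mitoqc_config_error")
})

test_that("stratified mixture injection hits its stated composition", {
  cfg <- simulation_config(seed = 9)
  sim <- simulate_mitogenome(cfg)
  inj <- inject_error_mixture(sim$sequence, 400, p_single_indel = 0.75,
                              p_ta_given_indel = 0.64,
                              p_homopolymer = 0.712, seed = 31)
  expect_identical(nrow(inj$truth), 400L)
  rec <- attribute_homopolymer(sim$sequence, inj$truth)
  p <- summarize_profile(rec, seq_length(sim$sequence))
  ci <- function(p0) 2.576 * sqrt(p0 * (1 - p0) / 400)
  expect_lt(abs(p$fraction_single_base_indel - 0.75), ci(0.75))
  expect_lt(abs(p$fraction_TA_single_indel - 0.48), ci(0.48))
  expect_lt(abs(p$fraction_in_homopolymer - 0.712), ci(0.712))
  # determinism
  inj2 <- inject_error_mixture(sim$sequence, 400, p_single_indel = 0.75,
                               p_ta_given_indel = 0.64,
                               p_homopolymer = 0.712, seed = 31)
  expect_identical(inj$corrupted$bases, inj2$corrupted$bases)
})

test_that("coverage models reproduce their expectations", {
  cfg <- simulation_config(seed = 12, control_region_length = 2000)
  sim <- simulate_mitogenome(cfg)
  ont <- simulate_coverage(sim$sequence,
                           coverage_model("ont", mean_depth = 30,
                                          noise_dispersion = 0, seed = 1),
                           50)
  expect_true(all(ont$depth == 30))

  ill <- simulate_coverage(sim$sequence,
                           coverage_model("illumina", mean_depth = 300,
                                          at_suppression = 0.05,
                                          noise_dispersion = 0.1, seed = 2),
                           50)
  cr <- sim$annotations[sim$annotations$name == "control_region", ]
  in_cr <- ill$start >= cr$start & ill$end <= cr$end
  expect_gte(sum(in_cr), 20)
  expect_lt(mean(ill$depth[in_cr]), 0.2 * 300)

  # unbiased genome below threshold: depth near the mean
  flat <- random_seq(10000, at = 0.5, name = "flat")
  ill2 <- simulate_coverage(flat,
                            coverage_model("illumina", mean_depth = 300,
                                           noise_dispersion = 0.05,
                                           seed = 3), 50)
  expect_lt(abs(mean(ill2$depth) - 300) / 300, 0.05)

  expect_error(simulate_coverage(flat,
                                 coverage_model("ont", seed = 1),
                                 20000),
               class = "mitoqc_config_error")
})
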