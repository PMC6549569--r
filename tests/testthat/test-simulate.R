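test_that("identical seeds give byte-identical libraries", {
  cfg <- sim_config(seed = 5, n_molecules = 300, true_vaf = 0.02,
                    index_hop_rate = 0.01, pcr_error_rate = 1e-4)
  l1 <- simulate_library(cfg)
  l2 <- simulate_library(cfg)
  expect_identical(l1$records, l2$records)
  expect_identical(l1$truth, l2$truth)
  l3 <- simulate_library(sim_config(seed = 6, n_molecules = 300,
                                    true_vaf = 0.02))
  expect_false(identical(l1$records$umi1, l3$records$umi1))
})

test_that("truth table matches the library and expected mutant load", {
  cfg <- sim_config(seed = 8, n_molecules = 1000, true_vaf = 0.01)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib$truth), 1000L)
  expect_equal(sum(lib$truth$n_reads) * 2L, nrow(lib$records))
  # ~10 expected mutant molecules; allow 4 sd of binomial noise
  expect_lt(abs(sum(lib$truth$mutant) - 10), 4 * sqrt(10) + 1)
  # every record's key matches its molecule's truth row
  rec <- lib$records[lib$records$mate == 1L, ]
  mol_id <- as.integer(sub("^M0*(\\d+)_.*$", "\\1", rec$qname))
  expect_identical(rec$umi1, lib$truth$umi1[mol_id])
  expect_identical(rec$frag_start, lib$truth$start[mol_id])
})

test_that("a sub-molecule expected mutant count warns about stochastic zeros", {
  expect_warning(
    simulate_library(sim_config(seed = 1, n_molecules = 50,
                                true_vaf = 1e-4)),
    "stochastic zero")
})

test_that("the noise-free pipeline recovers the planted truth exactly", {
  # fixed 120 bp fragments exactly covered by the 60 bp mate pair, so the
  # only N sources would be real disagreements
  cfg <- sim_config(seed = 12, n_molecules = 400, true_vaf = 0.05,
                    pcr_error_rate = 0, seq_error_rate = 0,
                    frag_len_mean = 120, frag_len_sd = 0,
                    mean_reads_per_molecule = 8)
  lib <- simulate_library(cfg)
  res <- run_consensus_pipeline(lib$records, mask_n = 0)
  pu <- pileup_panel(res$fragments, cfg$reference$panel)
  expect_equal(sum(pu$other_count), 0L)
  expect_equal(sum(pu$n_count), 0L)
  # alt consensus reads = mutant molecules with surviving families
  surv <- merge(as.data.frame(res$fragments), lib$truth,
                by.x = c("umi1", "umi2", "start", "end"),
                by.y = c("umi1", "umi2", "start", "end"))
  expect_equal(sum(pu$alt_count), sum(surv$mutant))
})

test_that("consensus reduces the raw error rate when sequencing noise dominates", {
  cfg <- sim_config(seed = 13, n_molecules = 1500, true_vaf = 0,
                    seq_error_rate = 2e-3, pcr_error_rate = 1e-7)
  lib <- suppressWarnings(simulate_library(cfg))
  panel <- cfg$reference$panel
  # raw per-read alt rate at panel sites (mate 1 covers frag_start onward)
  rec <- lib$records
  raw_alt <- 0L; raw_depth <- 0L
  for (i in seq_len(nrow(panel))) {
    p <- panel$pos[i]
    sel <- rec[rec$start <= p & rec$end > p, ]
    if (!nrow(sel)) next
    ch <- substr(sel$seq, p - sel$start + 1L, p - sel$start + 1L)
    raw_depth <- raw_depth + length(ch)
    raw_alt <- raw_alt + sum(ch == panel$alt[i])
  }
  res <- run_consensus_pipeline(lib$records)
  pu <- pileup_panel(res$fragments, panel)
  raw_rate <- raw_alt / raw_depth
  cons_rate <- sum(pu$alt_count) / sum(pu$depth - pu$n_count)
  expect_gt(raw_rate, cons_rate)
  expect_gt(raw_rate, 1e-4)  # sequencing noise clearly visible pre-consensus
})

test_that("negative controls carry background only, recovered within the CI", {
  # no polymerase error, no sequencing error: zero alt consensus reads
  cfg0 <- sim_config(seed = 14, n_molecules = 500, true_vaf = 0,
                     pcr_error_rate = 0, seq_error_rate = 0)
  lib0 <- simulate_negative_control(cfg0)
  expect_equal(sum(lib0$truth$mutant), 0L)
  res0 <- run_consensus_pipeline(lib0$records)
  pu0 <- pileup_panel(res0$fragments, cfg0$reference$panel)
  expect_equal(sum(pu0$alt_count), 0L)

  # with polymerase error, the error model's bound covers the residual rate
  cfg1 <- sim_config(seed = 15, n_molecules = 4000, true_vaf = 0,
                     pcr_error_rate = 2e-4, seq_error_rate = 1e-3)
  lib1 <- simulate_negative_control(cfg1)
  res1 <- run_consensus_pipeline(lib1$records)
  pu1 <- pileup_panel(res1$fragments, cfg1$reference$panel)
  model <- build_error_model(list(pu1))
  expect_gte(model$rate_upper95, model$rate_point)
  # residual consensus errors exist but sit far below the raw PCR error load
  expect_lt(model$rate_point, 2e-4 * cfg1$pcr_cycles)
})

test_that("dilution factors scale expected VAF with derived replicate seeds", {
  cfg <- sim_config(seed = 16, n_molecules = 200, true_vaf = 0.01)
  series <- simulate_dilution_series(cfg, c(1, 0.1, 0.01), replicates = 3)
  expect_length(series, 9L)
  expect_equal(vapply(series, `[[`, numeric(1), "expected_vaf"),
               rep(c(0.01, 0.001, 1e-4), each = 3))
  seeds <- vapply(series, function(e) e$library$config$seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  # replicate libraries differ; identical master seed reproduces the series
  expect_false(identical(series[[1]]$library$records,
                         series[[2]]$library$records))
  series2 <- simulate_dilution_series(cfg, c(1, 0.1, 0.01), replicates = 3)
  expect_identical(series[[5]]$library$records,
                   series2[[5]]$library$records)
})

test_that("planted index hops land in the hop bin and are filtered out", {
  cfg <- sim_config(seed = 17, n_molecules = 600, true_vaf = 0,
                    index_hop_rate = 0.25, mean_reads_per_molecule = 12,
                    seq_error_rate = 0, pcr_error_rate = 0)
  lib <- simulate_negative_control(cfg)
  expect_gt(sum(lib$truth$n_hopped_reads), 0)
  expect_setequal(unique(lib$records$sample_id), c("S1", "S2"))

  res <- run_consensus_pipeline(lib$records, across_samples = TRUE)
  frags <- as.data.frame(res$fragments)
  # after filtering, no surviving molecule appears in both sample bins
  key <- paste(frags$chrom, frags$start, frags$end, frags$umi1, frags$umi2)
  expect_equal(anyDuplicated(key), 0L)
  # hopped families large enough to consensus were present, so some removal
  # must have happened
  expect_gt(res$metrics$tag_swaps_removed, 0L)
  # and the survivor of each duplicated molecule is its larger family
  expect_true(all(table(key) == 1))
})

test_that("pileup-level generator draws at vaf + error rate, reproducibly", {
  pu <- simulate_consensus_pileups(n_sites = 15, depth_per_site = 2e5,
                                   true_vaf = 1e-3, error_rate = 1e-5,
                                   seed = 20)
  pu2 <- simulate_consensus_pileups(n_sites = 15, depth_per_site = 2e5,
                                    true_vaf = 1e-3, error_rate = 1e-5,
                                    seed = 20)
  expect_identical(pu, pu2)
  total <- sum(pu$alt_count)
  expn <- 15 * 2e5 * (1e-3 + 1e-5)
  expect_lt(abs(total - expn), 5 * sqrt(expn))
})

test_that("panel VAF recovery is within 3 binomial SE across true VAFs", {
  for (v in c(1e-2, 1e-3, 1e-4)) {
    pu <- simulate_consensus_pileups(n_sites = 15, depth_per_site = 2e5,
                                     true_vaf = v, error_rate = 0,
                                     seed = round(30 + 1e4 * v))
    pv <- panel_vaf(pu)
    se <- sqrt(v * (1 - v) / pv$total_depth)
    expect_lt(abs(pv$vaf - v), 3 * se + 1e-12)
  }
  # read-level generator at desk scale, same tolerance
  cfg <- sim_config(seed = 33, n_molecules = 8000, true_vaf = 1e-2)
  lib <- simulate_library(cfg)
  res <- run_consensus_pipeline(lib$records)
  pv <- panel_vaf(pileup_panel(res$fragments, cfg$reference$panel))
  se <- sqrt(1e-2 * 0.99 / pv$total_depth)
  expect_lt(abs(pv$vaf - 1e-2), 3 * se)
})

test_that("simulated quartets demultiplex back to the truth", {
  sheet <- make_sheet()
  cfg <- sim_config(seed = 21, n_molecules = 50, true_vaf = 0,
                    sample_id = "A", hop_sample_id = "B")
  lib <- simulate_negative_control(cfg)
  quartet <- sim_read_quartet(lib, sheet)
  dm <- demultiplex(quartet, sheet)
  expect_equal(unname(dm$counts["A"]), nrow(quartet))
  m1 <- lib$records[lib$records$mate == 1L, ]
  ix <- match(dm$reads$name, m1$qname)
  expect_identical(dm$reads$umi1, m1$umi1[ix])
  expect_identical(dm$reads$umi2, m1$umi2[ix])
})
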