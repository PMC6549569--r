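# Synthetic DIDA library generator.
#
# Emulates the generative process the consensus pipeline corrects: input
# cfDNA molecules (some carrying panel mutations), PCR amplification with
# per-cycle polymerase errors propagating down the copy lineage ("jackpot"
# structure), per-read sequencing errors, and index hopping between
# co-multiplexed libraries. Reads are emitted pre-aligned (coordinates from
# the truth table) so tests need no external aligner; a FASTQ quartet can
# be emitted for end-to-end demultiplexing runs.

#' Synthetic reference sequence and panel
#'
#' Builds a random reference chromosome with `n_sites` evenly spaced
#' tracked-mutation sites and a matching panel (random alternate allele per
#' site).
#'
#' @param n_sites Number of panel sites (default 15).
#' @param site_spacing Bases between consecutive sites (default 1000;
#'   sites sit at the centre of each window so fragments cover one site).
#' @param seed Integer seed.
#' @return List: `sequence` (character), `chrom`, and `panel` (data.frame
#'   `chrom`, `pos` (0-based), `ref`, `alt`, `gene`).
#' @export
synthetic_panel <- function(n_sites = 15L, site_spacing = 1000L, seed = 1L) {
  with_seed(seed, {
    len <- n_sites * site_spacing
    seq <- random_dna(1L, len)
    pos <- as.integer(site_spacing / 2 + site_spacing * (seq_len(n_sites) - 1L))
    ref <- substring(seq, pos + 1L, pos + 1L)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "")
    list(sequence = seq, chrom = "chrS",
         panel = data.frame(chrom = "chrS", pos = pos, ref = ref,
                            alt = unname(alt),
                            gene = sprintf("SYN%02d", seq_len(n_sites)),
                            stringsAsFactors = FALSE))
  })
}

#' Simulation configuration
#'
#' Parameters of the synthetic library generator. Defaults describe a
#' typical hybrid-capture cfDNA experiment: ~120 bp inserts sequenced with
#' 60 bp paired ends, 8 library PCR cycles with a proofreading-polymerase
#' error rate of 1e-6 per base per cycle, a raw sequencing error rate of
#' 1e-3 per base, 6-base degenerate barcodes on both adapter sides, and a
#' mean of 6 sequenced reads per input molecule (truncated geometric, so
#' family sizes are realistically skewed).
#'
#' @param seed Master seed; all randomness flows from it through named
#'   substreams (molecules, pcr, sequencing, hopping).
#' @param n_molecules Number of input molecules.
#' @param true_vaf Fraction of molecules carrying the alt allele at their
#'   covered site; scalar or one value per panel site.
#' @param reference Optional list from [synthetic_panel()]; built fresh
#'   from `n_sites` when `NULL`.
#' @param n_sites Panel size when building a reference (default 15).
#' @param frag_len_mean,frag_len_sd Fragment length distribution (normal,
#'   rounded, floored at `read_len`).
#' @param read_len Bases per mate (default 60).
#' @param pcr_cycles Amplification cycles (default 8).
#' @param pcr_error_rate Polymerase error rate per base per cycle
#'   (default 1e-6).
#' @param seq_error_rate Sequencing error rate per base (default 1e-3).
#' @param umi_len Degenerate barcode length, 4-6 (default 6).
#' @param index_hop_rate Per-read probability that the fixed index is
#'   swapped to another library (default 0).
#' @param mean_reads_per_molecule Mean sequenced reads per molecule
#'   (default 6).
#' @param max_reads_per_molecule Truncation of the reads-per-molecule
#'   distribution (default 30).
#' @param sample_id Sample bin for this library (default `"S1"`).
#' @param hop_sample_id Bin that hopped reads land in (default `"S2"`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_molecules = 1000L, true_vaf = 0.001,
                       reference = NULL, n_sites = 15L,
                       frag_len_mean = 120, frag_len_sd = 15,
                       read_len = 60L, pcr_cycles = 8L,
                       pcr_error_rate = 1e-6, seq_error_rate = 1e-3,
                       umi_len = 6L, index_hop_rate = 0,
                       mean_reads_per_molecule = 6,
                       max_reads_per_molecule = 30L,
                       sample_id = "S1", hop_sample_id = "S2") {
  rates <- c(pcr_error_rate, seq_error_rate, index_hop_rate)
  stopifnot(all(rates >= 0 & rates <= 1), all(true_vaf >= 0 & true_vaf <= 1),
            n_molecules >= 1, umi_len >= 4, umi_len <= 6,
            mean_reads_per_molecule >= 1)
  if (is.null(reference)) {
    reference <- synthetic_panel(n_sites = n_sites,
                                 seed = derive_seed(seed, "reference"))
  }
  n_sites <- nrow(reference$panel)
  if (length(true_vaf) == 1L) true_vaf <- rep(true_vaf, n_sites)
  stopifnot(length(true_vaf) == n_sites)
  structure(
    list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
         true_vaf = true_vaf, reference = reference,
         frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
         read_len = as.integer(read_len), pcr_cycles = as.integer(pcr_cycles),
         pcr_error_rate = pcr_error_rate, seq_error_rate = seq_error_rate,
         umi_len = as.integer(umi_len), index_hop_rate = index_hop_rate,
         mean_reads_per_molecule = mean_reads_per_molecule,
         max_reads_per_molecule = as.integer(max_reads_per_molecule),
         sample_id = sample_id, hop_sample_id = hop_sample_id),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim config: %d molecules, %d panel sites, VAF %s, seed %d\n",
    x$n_molecules, nrow(x$reference$panel),
    paste(signif(unique(x$true_vaf), 3), collapse = "/"), x$seed))
  invisible(x)
}

#' Simulate one tagged, pre-aligned DIDA library
#'
#' Draws input molecules over the panel, assigns each a unique UMI pair and
#' fragment coordinates, plants the alt allele per `true_vaf`, amplifies
#' through a branching PCR in which a polymerase error at cycle *i* is
#' inherited by every sequenced read descending from that copy (early
#' "jackpot" errors can dominate a family), adds independent sequencing
#' errors per read, and optionally hops reads to another sample bin at the
#' index-hop rate. Identical seeds give byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_library`:
#'   \describe{
#'     \item{records}{tagged aligned records (two rows per read pair: mates
#'       1 and 2) ready for [group_families()]}
#'     \item{truth}{one row per molecule: coordinates, UMIs, site, mutant
#'       status, reads drawn, hopped-read count}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ref <- cfg$reference
  panel <- ref$panel
  n_sites <- nrow(panel)
  rl <- cfg$read_len

  mol <- with_seed(derive_seed(cfg$seed, "molecules"), {
    n <- cfg$n_molecules
    site <- sample.int(n_sites, n, replace = TRUE)
    frag_len <- pmax(rl, pmin(
      as.integer(round(stats::rnorm(n, cfg$frag_len_mean, cfg$frag_len_sd))),
      nchar(ref$sequence)))
    offset <- floor(stats::runif(n) * frag_len)  # site position within frag
    start <- pmax(0L, panel$pos[site] - as.integer(offset))
    end <- pmin(nchar(ref$sequence), start + frag_len)
    umi1 <- int_to_umi(sample.int(4^cfg$umi_len, n, replace = TRUE),
                       cfg$umi_len)
    umi2 <- int_to_umi(sample.int(4^cfg$umi_len, n, replace = TRUE),
                       cfg$umi_len)
    mutant <- stats::rbinom(n, 1L, cfg$true_vaf[site]) == 1L
    orientation <- sample(c("F1R2", "F2R1"), n, replace = TRUE)
    p_geom <- 1 / cfg$mean_reads_per_molecule
    n_reads <- pmin(1L + stats::rgeom(n, p_geom), cfg$max_reads_per_molecule)
    data.frame(molecule_id = seq_len(n), site = site, pos = panel$pos[site],
               start = start, end = end, umi1 = umi1, umi2 = umi2,
               mutant = mutant, orientation = orientation, n_reads = n_reads,
               stringsAsFactors = FALSE)
  })

  # template sequence per molecule (alt planted on mutant molecules)
  mol_seq <- substring(ref$sequence, mol$start + 1L, mol$end)
  mut_ix <- which(mol$mutant)
  if (length(mut_ix)) {
    so <- mol$pos[mut_ix] - mol$start[mut_ix] + 1L
    for (j in seq_along(mut_ix)) {
      substr(mol_seq[mut_ix[j]], so[j], so[j]) <- panel$alt[mol$site[mut_ix[j]]]
    }
  }

  n_total_reads <- sum(mol$n_reads)
  read_mol <- rep.int(mol$molecule_id, mol$n_reads)
  frag_seq <- mol_seq[read_mol]  # per-read fragment copy, errors added below

  # PCR: each read's copy descends through `pcr_cycles` binary splits; an
  # error on a lineage node is shared by all reads under that node.
  frag_seq <- with_seed(derive_seed(cfg$seed, "pcr"), {
    if (cfg$pcr_error_rate > 0 && n_total_reads > 0) {
      frag_len_read <- mol$end[read_mol] - mol$start[read_mol]
      prefix <- rep.int(0, n_total_reads)
      for (cy in seq_len(cfg$pcr_cycles)) {
        prefix <- prefix * 2 + stats::rbinom(n_total_reads, 1L, 0.5)
        node <- read_mol * 2^cfg$pcr_cycles + prefix  # unique per (mol, node)
        first_idx <- which(!duplicated(node))
        n_err <- stats::rbinom(length(first_idx), frag_len_read[first_idx],
                               cfg$pcr_error_rate)
        for (t in which(n_err > 0)) {
          h <- first_idx[t]
          members <- which(node == node[h])
          for (e in seq_len(n_err[t])) {
            p <- sample.int(frag_len_read[h], 1L)
            cur <- substr(frag_seq[h], p, p)
            alt <- sample(setdiff(DNA_BASES, cur), 1L)
            for (mbr in members) substr(frag_seq[mbr], p, p) <- alt
          }
        }
      }
    }
    frag_seq
  })

  # mate sequences: mate 1 covers the left read_len bases of the fragment,
  # mate 2 the right read_len bases (overlapping when the insert is short)
  frag_len_read <- mol$end[read_mol] - mol$start[read_mol]
  s1 <- substr(frag_seq, 1L, rl)
  s2 <- substr(frag_seq, frag_len_read - rl + 1L, frag_len_read)

  seqs <- with_seed(derive_seed(cfg$seed, "sequencing"), {
    add_seq_errors <- function(s) {
      n_err <- stats::rbinom(length(s), rl, cfg$seq_error_rate)
      ii <- which(n_err > 0)
      idx <- rep.int(ii, n_err[ii])
      pos <- if (length(idx)) {
        as.integer(ceiling(stats::runif(length(idx)) * rl))
      } else integer(0)
      apply_substitutions(s, idx, pos)
    }
    list(s1 = add_seq_errors(s1), s2 = add_seq_errors(s2))
  })

  hopped <- with_seed(derive_seed(cfg$seed, "hopping"), {
    if (cfg$index_hop_rate > 0) {
      stats::runif(n_total_reads) < cfg$index_hop_rate
    } else {
      rep(FALSE, n_total_reads)
    }
  })
  sample_id <- ifelse(hopped, cfg$hop_sample_id, cfg$sample_id)

  within_idx <- sequence(mol$n_reads)
  qname <- sprintf("M%07d_R%03d", read_mol, within_idx)
  m2_start <- mol$end[read_mol] - rl

  records <- data.table::data.table(
    qname = rep(qname, 2L),
    sample_id = rep(sample_id, 2L),
    chrom = ref$chrom,
    frag_start = rep(mol$start[read_mol], 2L),
    frag_end = rep(mol$end[read_mol], 2L),
    orientation = rep(mol$orientation[read_mol], 2L),
    umi1 = rep(mol$umi1[read_mol], 2L),
    umi2 = rep(mol$umi2[read_mol], 2L),
    mate = rep(1:2, each = n_total_reads),
    start = c(mol$start[read_mol], m2_start),
    end = c(mol$start[read_mol] + rl, m2_start + rl),
    seq = c(seqs$s1, seqs$s2)
  )
  data.table::setorder(records, qname, mate)

  truth <- mol
  truth$sample_id <- cfg$sample_id
  truth$chrom <- ref$chrom
  hops_per_mol <- tapply(hopped, read_mol, sum)
  truth$n_hopped_reads <- 0L
  truth$n_hopped_reads[as.integer(names(hops_per_mol))] <-
    as.integer(hops_per_mol)

  if (sum(cfg$true_vaf) / n_sites * cfg$n_molecules < 1) {
    warning("expected mutant molecules < 1: a stochastic zero is possible")
  }
  structure(list(records = records, truth = truth, config = cfg),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("simulated library: %d molecules, %d read pairs, %d mutant molecules\n",
              nrow(x$truth), nrow(x$records) / 2L, sum(x$truth$mutant)))
  invisible(x)
}

#' Simulate a negative-control library
#'
#' A library with no mutant molecules (`true_vaf = 0`): the only
#' alt-matching consensus reads are early-cycle PCR jackpot errors that
#' survive consensus — exactly the background the error model measures.
#'
#' @param config A [sim_config()]; its `true_vaf` is forced to 0.
#' @return A `sim_library`.
#' @export
simulate_negative_control <- function(config) {
  config$true_vaf <- rep(0, length(config$true_vaf))
  suppressWarnings(simulate_library(config))
}

#' Simulate a serial dilution series
#'
#' Scales the expected mutant-molecule fraction of the base configuration
#' by each dilution factor (emulating serial dilution of tumor DNA into a
#' constant unmutated background), in `replicates` independent libraries
#' per factor with seeds derived deterministically from the master seed.
#'
#' @param config Base [sim_config()]; its `true_vaf` is the undiluted VAF.
#' @param dilution_factors Numeric factors in `(0, 1]`.
#' @param replicates Libraries per factor (default 3).
#' @return List of entries, each with `factor`, `replicate`,
#'   `expected_vaf` (mean over sites), and `library` (a `sim_library`).
#' @export
simulate_dilution_series <- function(config, dilution_factors,
                                     replicates = 3L) {
  stopifnot(all(dilution_factors > 0 & dilution_factors <= 1))
  out <- list()
  k <- 0L
  for (i in seq_along(dilution_factors)) {
    f <- dilution_factors[i]
    for (j in seq_len(replicates)) {
      cfg <- config
      cfg$true_vaf <- config$true_vaf * f
      cfg$seed <- derive_seed(config$seed, "dilution", i * 1000L + j)
      k <- k + 1L
      out[[k]] <- list(factor = f, replicate = j,
                       expected_vaf = mean(cfg$true_vaf),
                       library = suppressWarnings(simulate_library(cfg)))
    }
  }
  out
}

#' Run the consensus pipeline on simulated libraries and recover VAFs
#'
#' Convenience for dilution-series evaluation: runs each simulated library
#' through the consensus pipeline, piles up the panel, and returns expected
#' versus recovered panel VAF per library.
#'
#' @param series Output of [simulate_dilution_series()].
#' @param ... Passed to [run_consensus_pipeline()].
#' @return Data.frame: `factor`, `replicate`, `expected_vaf`,
#'   `recovered_vaf`, `mutant_reads`, `total_depth`.
#' @export
recover_dilution_series <- function(series, ...) {
  rows <- lapply(series, function(e) {
    res <- run_consensus_pipeline(e$library$records, ...)
    pu <- pileup_panel(res$fragments, e$library$config$reference$panel)
    pv <- panel_vaf(pu)
    data.frame(factor = e$factor, replicate = e$replicate,
               expected_vaf = e$expected_vaf,
               recovered_vaf = if (pv$total_depth > 0) pv$vaf else NA_real_,
               mutant_reads = pv$mutant_reads, total_depth = pv$total_depth)
  })
  do.call(rbind, rows)
}

#' Linearity of a recovered dilution series
#'
#' Averages recovered VAF over replicates per dilution level and regresses
#' the mean recovered VAF on the expected VAF (intercept included).
#'
#' @param recovered Data.frame from [recover_dilution_series()].
#' @return List: `slope`, `r_squared`, `fit` (the `lm` object), and
#'   `means` (per-level mean recovered VAF).
#' @export
dilution_linearity <- function(recovered) {
  means <- stats::aggregate(recovered_vaf ~ expected_vaf, data = recovered,
                            FUN = mean)
  fit <- stats::lm(recovered_vaf ~ expected_vaf, data = means)
  list(slope = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       fit = fit, means = means)
}

#' Draw consensus pileups directly from the post-consensus error model
#'
#' Generates per-site consensus pileup counts without simulating reads:
#' each consensus read carries the alt allele with probability
#' `true_vaf + error_rate` (mutant molecule, or a background error on a
#' wild-type molecule). This is the statistical model the detection test
#' inverts, and is used for calibration studies at depths where read-level
#' simulation is unnecessary.
#'
#' @param n_sites Panel sites (default 15).
#' @param depth_per_site Consensus depth per site (default 200000).
#' @param true_vaf Panel-level true VAF (default 0).
#' @param error_rate Background alt-matching error rate (default 1e-5).
#' @param seed Integer seed.
#' @return Pileup data.frame (`chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `other_count`, `n_count`).
#' @export
simulate_consensus_pileups <- function(n_sites = 15L, depth_per_site = 2e5,
                                       true_vaf = 0, error_rate = 1e-5,
                                       seed = 1L) {
  p_alt <- min(1, true_vaf + error_rate)
  with_seed(seed, {
    data.frame(
      chrom = "chrS", pos = seq_len(n_sites) * 1000L - 500L,
      ref = "A", alt = "T",
      depth = as.integer(rep(depth_per_site, n_sites)),
      alt_count = stats::rbinom(n_sites, as.integer(depth_per_site), p_alt),
      other_count = 0L, n_count = 0L, stringsAsFactors = FALSE)
  })
}

#' Emit a FASTQ-style read quartet from a simulated library
#'
#' Builds the demultiplexer's input table (R1/R2 plus two index reads) from
#' a simulated library: each index read is the sample's fixed index
#' followed by the molecule's degenerate barcode (trailing-UMI layout).
#' Index hopping is expressed by substituting the hop sample's fixed index
#' on the first index read of hopped reads.
#'
#' @param lib A `sim_library`.
#' @param sample_sheet Data.frame `sample`, `index1`, `index2` covering the
#'   library's `sample_id` (and `hop_sample_id` when hopping is simulated).
#' @param layout An [index_layout()]; `umi_len` must match the simulation.
#' @return Data.frame consumable by [demultiplex()].
#' @export
sim_read_quartet <- function(lib, sample_sheet, layout = index_layout()) {
  stopifnot(inherits(lib, "sim_library"),
            layout$umi_len == lib$config$umi_len)
  recs <- lib$records
  m1 <- recs[recs$mate == 1L, ]
  m2 <- recs[recs$mate == 2L, ]
  ix <- match(m1$sample_id, sample_sheet$sample)
  if (anyNA(ix)) stop("sample sheet does not cover simulated bins",
                      call. = FALSE)
  data.frame(
    name = m1$qname,
    read1_seq = m1$seq, read1_qual = strrep("I", nchar(m1$seq)),
    read2_seq = m2$seq, read2_qual = strrep("I", nchar(m2$seq)),
    index1_seq = paste0(sample_sheet$index1[ix], m1$umi1),
    index2_seq = paste0(sample_sheet$index2[ix], m1$umi2),
    stringsAsFactors = FALSE)
}
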