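# Per-timepoint ctDNA calling: panel-summed VAF, binomial detection against
# the background error model, mutant genomes per mL plasma, and the
# per-timepoint limit of detection.

#' Panel-summed variant allele fraction
#'
#' Sums mutant reads and consensus depth over the included panel sites; the
#' panel VAF is their ratio. `N` consensus calls carry no evidence for or
#' against the variant, so when the pileup tracks them (an `n_count`
#' column) the denominator is the informative depth `depth - n_count`,
#' matching the error model's convention and keeping the detection test's
#' trials on the same scale as its null rate.
#'
#' @param pileups Pileup data.frame (columns `depth`, `alt_count`, and
#'   optionally `n_count`) restricted to the error model's included sites.
#' @return List: `mutant_reads`, `total_depth`, `vaf` (`NA` with a
#'   `"insufficient_depth"` status marker when depth is zero).
#' @export
panel_vaf <- function(pileups) {
  mutant_reads <- sum(pileups$alt_count)
  total_depth <- sum(pileups$depth)
  if ("n_count" %in% names(pileups)) {
    total_depth <- total_depth - sum(pileups$n_count)
  }
  if (total_depth <= 0) {
    return(list(mutant_reads = mutant_reads, total_depth = total_depth,
                vaf = NA_real_, status = "insufficient_depth"))
  }
  list(mutant_reads = mutant_reads, total_depth = total_depth,
       vaf = mutant_reads / total_depth, status = "ok")
}

#' Binomial detection test against the background error rate
#'
#' One-sided exact binomial test: the p-value is the upper-tail probability
#' of observing at least `mutant_reads` alt consensus reads in
#' `total_depth` trials at the background `error_rate` (normally the error
#' model's conservative upper bound). A timepoint is called detected when
#' `p_value < alpha`.
#'
#' @param mutant_reads Observed alt consensus reads (panel-summed).
#' @param total_depth Panel-summed consensus depth.
#' @param error_rate Background error rate under the null.
#' @param alpha Significance level (default 0.05).
#' @return List: `p_value`, `detected`.
#' @export
#' @examples
#' detect(0, 1e5, 1e-5)    # p = 1, not detected
#' detect(300, 3e6, 1e-5)  # far above background: detected
detect <- function(mutant_reads, total_depth, error_rate, alpha = 0.05) {
  stopifnot(total_depth > 0, error_rate >= 0, error_rate <= 1)
  if (error_rate == 0 && mutant_reads > 0) {
    warning("error_rate = 0: any mutant read is significant (degenerate null)")
    return(list(p_value = 0, detected = TRUE))
  }
  p <- binom_tail(mutant_reads, total_depth, error_rate)
  list(p_value = p, detected = p < alpha)
}

#' Convert a VAF to mutant genomes per mL plasma
#'
#' Rescales the allele fraction by the cell-free DNA mass concentration
#' divided by the mass of one haploid genome (0.003 ng), giving an absolute
#' ctDNA abundance that is comparable across draws with different cfDNA
#' yields:
#' `conc (ng/mL) / 0.003 (ng/genome) * VAF = mutant genomes / mL`.
#'
#' @param cfdna_conc Cell-free DNA concentration, ng per mL plasma.
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param ng_per_genome Mass of one genome in ng (default 0.003).
#' @return Mutant genomes per mL plasma; exactly linear in both arguments.
#' @export
#' @examples
#' mutant_genomes(3, 0.01)    # 10 genomes/mL
mutant_genomes <- function(cfdna_conc, vaf, ng_per_genome = 0.003) {
  stopifnot(all(cfdna_conc >= 0), all(vaf >= 0 & vaf <= 1))
  cfdna_conc / ng_per_genome * vaf
}

#' Per-timepoint limit of detection
#'
#' Finds the minimal number of mutant reads `k_min` whose one-sided
#' binomial upper-tail probability at the panel error rate and the achieved
#' depth falls below `alpha`; the LOD VAF is `k_min / total_depth`, and,
#' when a cfDNA concentration is supplied, the LOD is also expressed in
#' mutant genomes per mL.
#'
#' @param error_rate Panel background error rate (the model's upper bound).
#' @param total_depth Panel-summed consensus depth achieved.
#' @param alpha Significance level (default 0.05).
#' @param cfdna_conc Optional cfDNA concentration (ng/mL).
#' @param ng_per_genome Mass per genome (default 0.003 ng).
#' @return List: `k_min`, `lod_vaf`, and `lod_mutant_genomes` (`NA` when no
#'   concentration given).
#' @export
#' @examples
#' lod(1e-5, 1e5)   # k_min = 4, lod_vaf = 4e-5
lod <- function(error_rate, total_depth, alpha = 0.05, cfdna_conc = NULL,
                ng_per_genome = 0.003) {
  stopifnot(total_depth > 0)
  if (error_rate == 0) {
    warning("error_rate = 0: k_min = 1 by convention")
    k <- 1L
  } else {
    # start from the binomial quantile, then adjust to the exact boundary
    k <- max(1L, as.integer(stats::qbinom(1 - alpha, total_depth, error_rate)))
    while (binom_tail(k, total_depth, error_rate) >= alpha) k <- k + 1L
    while (k > 1L && binom_tail(k - 1L, total_depth, error_rate) < alpha) {
      k <- k - 1L
    }
  }
  lod_vaf <- k / total_depth
  lod_mg <- if (is.null(cfdna_conc)) NA_real_ else {
    mutant_genomes(cfdna_conc, lod_vaf, ng_per_genome)
  }
  list(k_min = k, lod_vaf = lod_vaf, lod_mutant_genomes = lod_mg)
}

#' Classify a timepoint
#'
#' Three-way call: `detected` when the binomial p-value is below `alpha`;
#' otherwise `insufficient_depth` when the panel depth is below
#' `depth_floor` (the draw cannot support the assay's working sensitivity),
#' else `not_detected` (adequately sequenced, signal statistically
#' indistinguishable from background; such points are reported at their
#' per-timepoint limit of detection for plotting).
#'
#' @param p_value Binomial detection p-value.
#' @param total_depth Panel-summed consensus depth.
#' @param alpha Significance level (default 0.05).
#' @param depth_floor Minimum panel depth for an informative non-detection
#'   (default 10000 consensus reads).
#' @return One of `"detected"`, `"not_detected"`, `"insufficient_depth"`.
#' @export
classify_timepoint <- function(p_value, total_depth, alpha = 0.05,
                               depth_floor = 1e4) {
  if (p_value < alpha) return("detected")
  if (total_depth < depth_floor) return("insufficient_depth")
  "not_detected"
}

#' Mean limit of detection across timepoints
#'
#' Arithmetic mean of the finite per-timepoint LOD values (VAF or
#' mutant-genome scale, matching the input); non-finite values
#' (zero-depth timepoints) are excluded with a message.
#'
#' @param lods Numeric vector of per-timepoint LOD values.
#' @return Scalar mean LOD.
#' @export
mean_lod <- function(lods) {
  finite <- is.finite(lods)
  if (!any(finite)) stop("no finite LOD values to average", call. = FALSE)
  if (any(!finite)) {
    message(sum(!finite), " non-finite LOD value(s) excluded from the mean")
  }
  mean(lods[finite])
}

#' Quantify one timepoint
#'
#' Full per-draw ctDNA call: panel VAF, binomial detection against the
#' error model's conservative rate, mutant genomes per mL, status, and the
#' per-timepoint limit of detection.
#'
#' @param pileups This sample's pileup over the panel (included sites).
#' @param error_model An `error_model` (or a single numeric rate).
#' @param cfdna_conc cfDNA concentration, ng/mL plasma (`NA` allowed).
#' @param alpha Significance level (default 0.05).
#' @param depth_floor Depth floor for [classify_timepoint()].
#' @param use_upper_bound Test against `rate_upper95` (default) rather than
#'   the point estimate.
#' @param ng_per_genome Mass per genome (default 0.003 ng).
#' @return A one-row data.frame: `mutant_reads`, `total_depth`, `vaf`,
#'   `p_value`, `detected`, `status`, `mutant_genomes_per_ml`, `lod_vaf`,
#'   `lod_mutant_genomes`.
#' @export
quantify_timepoint <- function(pileups, error_model, cfdna_conc = NA,
                               alpha = 0.05, depth_floor = 1e4,
                               use_upper_bound = TRUE,
                               ng_per_genome = 0.003) {
  rate <- if (inherits(error_model, "error_model")) {
    if (use_upper_bound) error_model$rate_upper95 else error_model$rate_point
  } else {
    as.numeric(error_model)
  }
  pv <- panel_vaf(pileups)
  if (pv$status == "insufficient_depth") {
    return(data.frame(
      mutant_reads = pv$mutant_reads, total_depth = pv$total_depth,
      vaf = NA_real_, p_value = NA_real_, detected = FALSE,
      status = "insufficient_depth", mutant_genomes_per_ml = NA_real_,
      lod_vaf = NA_real_, lod_mutant_genomes = NA_real_,
      stringsAsFactors = FALSE))
  }
  d <- detect(pv$mutant_reads, pv$total_depth, rate, alpha = alpha)
  status <- classify_timepoint(d$p_value, pv$total_depth, alpha = alpha,
                               depth_floor = depth_floor)
  l <- lod(rate, pv$total_depth, alpha = alpha,
           cfdna_conc = if (is.na(cfdna_conc)) NULL else cfdna_conc,
           ng_per_genome = ng_per_genome)
  mg <- if (is.na(cfdna_conc)) NA_real_ else {
    mutant_genomes(cfdna_conc, pv$vaf, ng_per_genome)
  }
  data.frame(
    mutant_reads = pv$mutant_reads, total_depth = pv$total_depth,
    vaf = pv$vaf, p_value = d$p_value, detected = d$detected,
    status = status, mutant_genomes_per_ml = mg,
    lod_vaf = l$lod_vaf, lod_mutant_genomes = l$lod_mutant_genomes,
    stringsAsFactors = FALSE)
}

#' Assemble a longitudinal ctDNA table for one patient
#'
#' One row per timepoint and replicate, sorted by collection day, with a
#' per-day summary (replicate mean and standard error) of mutant genomes
#' per mL and VAF. Non-detected timepoints carry their per-timepoint LOD so
#' they can be plotted at the limit of detection.
#'
#' @param timepoints Data.frame with columns `day`, `replicate_id`, plus
#'   the [quantify_timepoint()] result columns.
#' @param annotations Optional data.frame of treatment annotations (e.g.
#'   columns `day`, `label`), carried through as an attribute.
#' @return List of class `ctdna_timeseries`: `timepoints` (sorted rows) and
#'   `by_day` (per-day mean and SEM).
#' @export
build_timeseries <- function(timepoints, annotations = NULL) {
  stopifnot(all(c("day", "replicate_id") %in% names(timepoints)))
  if (anyDuplicated(timepoints[, c("day", "replicate_id")])) {
    stop("duplicate (day, replicate_id) rows", call. = FALSE)
  }
  tp <- timepoints[order(timepoints$day, timepoints$replicate_id), ,
                   drop = FALSE]
  rownames(tp) <- NULL
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  agg <- function(col) {
    if (!col %in% names(tp)) return(NULL)
    m <- tapply(tp[[col]], tp$day, function(x) mean(x[is.finite(x)]))
    s <- tapply(tp[[col]], tp$day, sem)
    data.frame(day = as.numeric(names(m)), mean = as.numeric(m),
               sem = as.numeric(s))
  }
  by_day <- agg("mutant_genomes_per_ml")
  if (is.null(by_day)) by_day <- agg("vaf")
  out <- structure(list(timepoints = tp, by_day = by_day),
                   class = "ctdna_timeseries")
  if (!is.null(annotations)) attr(out, "annotations") <- annotations
  out
}

#' @export
print.ctdna_timeseries <- function(x, ...) {
  cat("ctDNA time series:", nrow(x$timepoints), "timepoint rows over",
      length(unique(x$timepoints$day)), "days\n")
  print(utils::head(x$timepoints, 10))
  invisible(x)
}
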