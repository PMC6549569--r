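# Panel background error model from pooled negative-control pileups.
#
# Negative controls are libraries from DNA known not to carry the panel
# mutations; any alt-matching consensus read there is assay background.
# The model pools counts across control runs, drops high-error sites
# (negative-control VAF > 0.05, predominantly mismapping artefacts), and
# estimates one panel-wide error rate with an exact binomial upper
# confidence bound used as the conservative null for detection.

#' Pool negative-control pileups across runs
#'
#' Sums counts site-wise across control runs covering the same panel.
#'
#' @param runs A list of pileup data.frames (columns `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_count`, `other_count`, `n_count`), one per
#'   negative-control run.
#' @return One pooled pileup data.frame; run identifiers (list names, or
#'   run indices) are kept in the `run_ids` attribute.
#' @export
pool_negative_controls <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  ref_key <- sort(key(runs[[1L]]))
  for (r in runs) {
    if (!identical(sort(key(r)), ref_key)) {
      stop("negative-control runs do not cover the same panel",
           call. = FALSE)
    }
  }
  pooled <- runs[[1L]][order(key(runs[[1L]])), , drop = FALSE]
  cnt_cols <- c("depth", "alt_count", "other_count", "n_count")
  for (r in runs[-1L]) {
    r <- r[order(key(r)), , drop = FALSE]
    for (cc in cnt_cols) pooled[[cc]] <- pooled[[cc]] + r[[cc]]
  }
  pooled <- pooled[order(pooled$chrom, pooled$pos), , drop = FALSE]
  rownames(pooled) <- NULL
  ids <- names(runs)
  if (is.null(ids)) ids <- paste0("run", seq_along(runs))
  attr(pooled, "run_ids") <- ids
  pooled
}

#' Flag high-error panel sites
#'
#' Sites whose pooled negative-control VAF exceeds `vaf_cutoff` (strictly)
#' are excluded from the error model and from detection — in practice these
#' are dominated by recurrent mismapping rather than true polymerase or
#' sequencing error. Zero-depth sites are excluded as uninformative.
#'
#' @param pooled Pooled pileup from [pool_negative_controls()].
#' @param vaf_cutoff Exclusion threshold on negative-control VAF
#'   (default 0.05, exclusive: a site at exactly the cutoff is kept).
#' @return List: `included` (pileup rows kept) and `excluded` (rows with a
#'   `reason` column, `"high_error"` or `"no_coverage"`).
#' @export
flag_high_error_sites <- function(pooled, vaf_cutoff = 0.05) {
  vaf <- ifelse(pooled$depth > 0, pooled$alt_count / pooled$depth, NA_real_)
  no_cov <- pooled$depth == 0
  high <- !no_cov & vaf > vaf_cutoff
  excluded <- pooled[no_cov | high, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(excluded$depth == 0, "no_coverage", "high_error")
  } else {
    excluded$reason <- character(0)
  }
  included <- pooled[!(no_cov | high), , drop = FALSE]
  rownames(included) <- rownames(excluded) <- NULL
  list(included = included, excluded = excluded)
}

#' Estimate the panel-wide background error rate
#'
#' Pools alt-matching consensus counts and informative depth over the
#' included sites. The point estimate is the pooled alt count divided by
#' the pooled non-N depth; the conservative estimate is the exact one-sided
#' binomial (Clopper-Pearson) upper confidence bound on that proportion.
#' Per-substitution-class rates (e.g. `C>T`) are reported by the same
#' formula restricted to sites of each class. `N` consensus calls carry no
#' evidence and are removed from both numerator and denominator.
#'
#' @param included Included pileup rows (see [flag_high_error_sites()]).
#' @param conf_level Confidence level for the upper bound (default 0.95).
#' @param two_sided Use the upper end of a two-sided `conf_level` interval
#'   instead of a one-sided bound (default `FALSE`).
#' @return An object of class `error_model` with fields `included_sites`,
#'   `excluded_sites`, `pooled_alt`, `pooled_depth`, `rate_point`,
#'   `rate_upper95`, `class_rates`, `conf_level`.
#' @export
estimate_error_rate <- function(included, conf_level = 0.95,
                                two_sided = FALSE) {
  if (nrow(included) == 0L) {
    stop("no included sites: cannot build error model", call. = FALSE)
  }
  eff_depth <- included$depth - included$n_count
  pooled_alt <- sum(included$alt_count)
  pooled_depth <- sum(eff_depth)
  if (pooled_depth <= 0) {
    stop("pooled informative depth is zero: cannot build error model",
         call. = FALSE)
  }
  rate_point <- pooled_alt / pooled_depth
  rate_upper <- binom_upper(pooled_alt, pooled_depth, conf = conf_level,
                            two_sided = two_sided)

  cls <- paste0(included$ref, ">", included$alt)
  class_rates <- do.call(rbind, lapply(split(seq_len(nrow(included)), cls),
    function(ix) {
      d <- sum(eff_depth[ix])
      a <- sum(included$alt_count[ix])
      data.frame(class = cls[ix[1L]], n_sites = length(ix), depth = d,
                 alt = a, rate = if (d > 0) a / d else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(class_rates) <- NULL

  structure(
    list(included_sites = included, excluded_sites = NULL,
         pooled_alt = pooled_alt, pooled_depth = pooled_depth,
         rate_point = rate_point, rate_upper95 = rate_upper,
         class_rates = class_rates, conf_level = conf_level,
         two_sided = two_sided),
    class = "error_model"
  )
}

#' Build a complete panel error model
#'
#' Convenience wrapper: pools negative-control runs, excludes high-error
#' and uncovered sites, and estimates the panel-wide rate with its upper
#' confidence bound.
#'
#' @param runs List of per-run negative-control pileups, or a single pooled
#'   pileup data.frame.
#' @param vaf_cutoff High-error exclusion threshold (default 0.05).
#' @param conf_level,two_sided Passed to [estimate_error_rate()].
#' @return An `error_model` with `excluded_sites` populated.
#' @export
build_error_model <- function(runs, vaf_cutoff = 0.05, conf_level = 0.95,
                              two_sided = FALSE) {
  pooled <- if (is.data.frame(runs)) runs else pool_negative_controls(runs)
  fl <- flag_high_error_sites(pooled, vaf_cutoff = vaf_cutoff)
  model <- estimate_error_rate(fl$included, conf_level = conf_level,
                               two_sided = two_sided)
  model$excluded_sites <- fl$excluded
  model
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("panel error model: %d sites (%d excluded)\n",
              nrow(x$included_sites),
              if (is.null(x$excluded_sites)) 0L else nrow(x$excluded_sites)))
  cat(sprintf("  pooled: %d alt / %.0f informative depth\n",
              x$pooled_alt, x$pooled_depth))
  cat(sprintf("  error rate: %.3g (point), %.3g (%.0f%% upper bound)\n",
              x$rate_point, x$rate_upper95, 100 * x$conf_level))
  invisible(x)
}

#' Write / read an error model as JSON
#'
#' @param model An `error_model`.
#' @param path Output (input) file path.
#' @return `write_error_model`: the path, invisibly. `read_error_model`:
#'   the restored `error_model`.
#' @export
write_error_model <- function(model, path) {
  stopifnot(inherits(model, "error_model"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("included_sites", "excluded_sites", "class_rates")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.data.frame(obj[[f]])
  }
  structure(obj, class = "error_model")
}
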