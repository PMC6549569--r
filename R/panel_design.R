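# Patient-specific tracked-mutation panel selection from tumor/normal
# variant calls.

#' Filter candidate tumor variants for panel inclusion
#'
#' Keeps single-nucleotide variants with tumor VAF at or above `min_vaf`,
#' at least `min_alt_reads` supporting reads, and bidirectional support
#' (at least one alt read on each strand).
#'
#' @param variants Data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_vaf`, `alt_read_count`, `forward_alt_reads`,
#'   `reverse_alt_reads`, and optionally `gene`.
#' @param min_vaf Minimum tumor VAF (default 0.1).
#' @param min_alt_reads Minimum supporting reads (default 3).
#' @return The passing rows (possibly empty).
#' @export
filter_candidates <- function(variants, min_vaf = 0.1, min_alt_reads = 3L) {
  req <- c("chrom", "pos", "ref", "alt", "tumor_vaf", "alt_read_count",
           "forward_alt_reads", "reverse_alt_reads")
  stopifnot(all(req %in% names(variants)))
  if (nrow(variants) &&
      any(variants$forward_alt_reads + variants$reverse_alt_reads !=
          variants$alt_read_count)) {
    stop("strand counts do not sum to alt_read_count", call. = FALSE)
  }
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% DNA_BASES & variants$alt %in% DNA_BASES
  pass <- snv &
    variants$tumor_vaf >= min_vaf &
    variants$alt_read_count >= min_alt_reads &
    variants$forward_alt_reads >= 1L &
    variants$reverse_alt_reads >= 1L
  out <- variants[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a patient-specific mutation panel
#'
#' Builds the tracked panel from filtered candidates. Variants in driver
#' genes are always included when present. Remaining slots are filled by
#' passenger mutations, ranked to prefer substitution classes outside
#' `avoid_classes` (classes like `T>C` and `G>A` carry systematically
#' higher background error) and, within that, higher tumor VAF; avoided
#' classes are used only if slots remain. Ties break on (chrom, pos) so
#' identical inputs always give identical panels.
#'
#' @param variants Passing candidates from [filter_candidates()].
#' @param target_size Desired panel size (default 20; panels of roughly
#'   10-50 sites are typical).
#' @param avoid_classes Substitution classes to deprioritise, written as
#'   `"ref>alt"` literals, not strand-collapsed (default `T>C`, `G>A`).
#' @param driver_genes Genes whose variants are always included (default
#'   PIK3CA, TP53, AKT1 — recurrent breast cancer drivers).
#' @return A data.frame of class `mutation_panel`, one row per tracked
#'   site, with a `selection` column (`"driver"` or `"passenger"`).
#' @export
select_panel <- function(variants, target_size = 20L,
                         avoid_classes = c("T>C", "G>A"),
                         driver_genes = c("PIK3CA", "TP53", "AKT1")) {
  stopifnot(target_size >= 1L)
  v <- variants
  if (!"gene" %in% names(v)) v$gene <- rep(NA_character_, nrow(v))
  v$substitution_class <- if (nrow(v)) paste0(v$ref, ">", v$alt) else character(0)
  v$is_driver <- !is.na(v$gene) & v$gene %in% driver_genes
  if (!nrow(v)) {
    warning("no passing variants: empty panel")
    v$selection <- character(0)
    class(v) <- c("mutation_panel", "data.frame")
    return(v)
  }

  drivers <- v[v$is_driver, , drop = FALSE]
  drivers <- drivers[order(drivers$chrom, drivers$pos), , drop = FALSE]
  if (nrow(drivers) > target_size) {
    warning("driver variants alone exceed target_size; all are kept")
  }

  passengers <- v[!v$is_driver, , drop = FALSE]
  avoided <- passengers$substitution_class %in% avoid_classes
  ord <- order(avoided, -passengers$tumor_vaf, passengers$chrom,
               passengers$pos)
  passengers <- passengers[ord, , drop = FALSE]
  slots <- max(0L, target_size - nrow(drivers))
  chosen <- passengers[seq_len(min(slots, nrow(passengers))), , drop = FALSE]

  if (nrow(drivers) + nrow(passengers) < target_size) {
    warning(sprintf("only %d passing variants for a target of %d: panel is smaller",
                    nrow(drivers) + nrow(passengers), target_size))
  }

  panel <- rbind(
    if (nrow(drivers)) cbind(drivers, selection = "driver") else NULL,
    if (nrow(chosen)) cbind(chosen, selection = "passenger") else NULL
  )
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("mutation_panel", "data.frame")
  panel
}

#' @export
print.mutation_panel <- function(x, ...) {
  cat(sprintf("mutation panel: %d sites (%d driver, %d passenger)\n",
              nrow(x), sum(x$selection == "driver"),
              sum(x$selection == "passenger")))
  print.data.frame(utils::head(as.data.frame(x), 20))
  invisible(x)
}
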