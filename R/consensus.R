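# Molecule-family grouping and single-strand consensus (SSCS) calling.
#
# Tagged aligned reads are grouped by fragment mapping coordinates plus the
# ordered degenerate-barcode pair; each family is presumed to contain PCR /
# sequencing copies of one input molecule and is collapsed into an SSCS.
# Coordinates are 0-based half-open internally ([start, end)); the fragment
# key spans the whole insert (leftmost start to rightmost end of the pair).

FAMILY_KEY_COLS <- c("sample_id", "chrom", "frag_start", "frag_end",
                     "orientation", "umi1", "umi2")

#' Group tagged aligned reads into molecule families
#'
#' Reads sharing the fragment mapping key (chromosome, fragment start/end,
#' orientation) and the ordered UMI pair are presumed copies of one input
#' molecule. Unmapped, secondary and supplementary records are excluded and
#' counted; records whose UMI contains `N` are kept here but dropped (and
#' counted) by the consensus caller, since an ambiguous barcode cannot
#' safely identify a molecule.
#'
#' @param records Data.frame/data.table of tagged aligned records. Required
#'   columns: `qname`, `sample_id`, `chrom`, `frag_start`, `frag_end`,
#'   `orientation`, `umi1`, `umi2`, `mate`, `start`, `end`, `seq`. Optional
#'   logical columns `unmapped`, `secondary`, `supplementary` mark records
#'   to exclude.
#' @return A list of class `read_families`:
#'   \describe{
#'     \item{records}{usable records with a `family_id` column}
#'     \item{families}{one row per family: key columns plus `family_id` and
#'       `size` (read pairs)}
#'     \item{excluded}{named counts of excluded records}
#'   }
#' @export
group_families <- function(records) {
  dt <- data.table::as.data.table(records)
  req <- c(FAMILY_KEY_COLS, "qname", "mate", "start", "end", "seq")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    if (any(c("umi1", "umi2") %in% miss)) {
      stop("records are missing barcode tags (umi1/umi2); run attach_tags first",
           call. = FALSE)
    }
    stop("records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  excluded <- c(unmapped = 0L, secondary = 0L, supplementary = 0L)
  for (flag in names(excluded)) {
    if (flag %in% names(dt)) {
      drop <- isTRUE_vec(dt[[flag]])
      excluded[[flag]] <- sum(drop)
      dt <- dt[!drop]
    }
  }
  data.table::setorderv(dt, c(FAMILY_KEY_COLS, "qname", "mate"))
  dt[, family_id := .GRP, by = FAMILY_KEY_COLS]
  fam <- dt[, .(size = data.table::uniqueN(qname)),
            by = c("family_id", FAMILY_KEY_COLS)]
  structure(list(records = dt[], families = fam[], excluded = excluded),
            class = "read_families")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.read_families <- function(x, ...) {
  cat(sprintf("%d families from %d records (%d read pairs); excluded: %s\n",
              nrow(x$families), nrow(x$records),
              data.table::uniqueN(x$records$qname),
              paste(names(x$excluded), x$excluded, collapse = ", ")))
  invisible(x)
}

# Per-position consensus over equal-length aligned sequences.
# Returns the consensus string. At each position the modal base among
# non-N member bases is emitted when its fraction (of non-N bases) is
# >= agreement, inclusive; otherwise N. Ties for the mode give N, as does a
# position where every member is N.
consensus_string <- function(seqs, agreement = 0.90) {
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) {
    stop("family members must have identical aligned length", call. = FALSE)
  }
  if (length(unique(seqs)) == 1L) return(seqs[1L])
  m <- matrix(unlist(lapply(seqs, utf8ToInt), use.names = FALSE),
              ncol = L, byrow = TRUE)
  codes <- c(A = 65L, C = 67L, G = 71L, T = 84L)
  cnt <- vapply(codes, function(cd) colSums(m == cd), numeric(L))
  if (L == 1L) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, names(codes)))
  non_n <- rowSums(cnt)
  mi <- max.col(cnt, ties.method = "first")
  top <- cnt[cbind(seq_len(L), mi)]
  modal <- names(codes)[mi]
  tie <- rowSums(cnt == top) > 1L
  ok <- non_n > 0 & !tie & (top / pmax(non_n, 1)) >= agreement
  out <- ifelse(ok, modal, "N")
  paste(out, collapse = "")
}

#' Collapse one read family into a single-strand consensus sequence
#'
#' Families with fewer than `min_family_size` reads are omitted (returns
#' `NULL`). At each position the modal base is called when it reaches the
#' `agreement` fraction (inclusive) of non-N member bases; otherwise `N`.
#'
#' @param seqs Character vector of equal-length aligned member sequences
#'   (one per read).
#' @param min_family_size Minimum reads required to emit a consensus
#'   (default 3).
#' @param agreement Minimum modal-base fraction to call a base (default
#'   0.90, inclusive).
#' @return The consensus string, or `NULL` if the family is too small.
#' @export
#' @examples
#' call_sscs(c("ACGT", "ACGT", "ACGT"))       # "ACGT"
#' call_sscs(c("ACGT", "ACGT"))               # NULL: fewer than 3 reads
call_sscs <- function(seqs, min_family_size = 3L, agreement = 0.90) {
  if (length(seqs) == 0L) stop("empty family", call. = FALSE)
  if (length(seqs) < min_family_size) return(NULL)
  consensus_string(seqs, agreement)
}

# Vectorised SSCS calling over grouped records. One consensus per
# (family, mate). Families below min size, keyed on an N-containing UMI, or
# with inconsistent member alignments (differing start/end within a mate
# group, the no-indel analogue of a mixed cigar class) are dropped and
# counted.
call_all_sscs <- function(fams, min_family_size = 3L, agreement = 0.90) {
  recs <- data.table::copy(fams$records)
  sizes <- fams$families[, .(family_id, size)]
  recs <- sizes[recs, on = "family_id"]

  n_fam <- nrow(fams$families)
  umi_n <- fams$families[grepl("N", umi1, fixed = TRUE) |
                           grepl("N", umi2, fixed = TRUE), family_id]
  small <- fams$families[size < min_family_size, family_id]
  small <- setdiff(small, umi_n)
  recs <- recs[!family_id %in% c(umi_n, small)]

  inconsistent <- integer(0)
  if (nrow(recs)) {
    chk <- recs[, .(nkey = data.table::uniqueN(paste(start, end, nchar(seq)))),
                by = .(family_id, mate)]
    inconsistent <- unique(chk[nkey > 1L, family_id])
    recs <- recs[!family_id %in% inconsistent]
  }

  out <- NULL
  if (nrow(recs)) {
    grp <- recs[, .(
      n = .N,
      homogeneous = data.table::uniqueN(seq) == 1L,
      bases = seq[1L],
      chrom = chrom[1L], start = start[1L], end = end[1L],
      frag_start = frag_start[1L], frag_end = frag_end[1L],
      orientation = orientation[1L], umi1 = umi1[1L], umi2 = umi2[1L],
      sample_id = sample_id[1L], family_size = size[1L]
    ), by = .(family_id, mate)]
    het <- which(!grp$homogeneous)
    if (length(het)) {
      key <- recs[, paste(family_id, mate)]
      seq_by_grp <- split(recs$seq, key)
      het_keys <- paste(grp$family_id[het], grp$mate[het])
      het_bases <- vapply(het_keys, function(k) {
        consensus_string(seq_by_grp[[k]], agreement)
      }, character(1), USE.NAMES = FALSE)
      data.table::set(grp, i = het, j = "bases", value = het_bases)
    }
    grp[, c("n", "homogeneous") := NULL]
    out <- grp[]
  }

  metrics <- c(
    families_in = n_fam,
    families_below_min_size = length(small),
    families_umi_n = length(umi_n),
    families_inconsistent = length(inconsistent),
    families_consensused = n_fam - length(small) - length(umi_n) -
      length(inconsistent)
  )
  list(sscs = out, metrics = metrics)
}

#' Mask low-quality consensus ends with N
#'
#' Replaces the first and last `n` bases of each consensus sequence with
#' `N`; length is unchanged. Sequences of length `<= 2n` become all-N (use
#' [is_all_n()] to flag them).
#'
#' @param bases Character vector of consensus sequences.
#' @param n Bases to mask at each end (default 5).
#' @return Character vector of masked sequences.
#' @export
#' @examples
#' mask_ends("ACGTACGTACGT", n = 2)  # "NNGTACGTACNN"
mask_ends <- function(bases, n = 5L) {
  n <- as.integer(n)
  if (n == 0L) return(bases)
  len <- nchar(bases)
  all_n <- len <= 2L * n
  out <- ifelse(
    all_n,
    strrep("N", len),
    paste0(strrep("N", n), substr(bases, n + 1L, len - n), strrep("N", n))
  )
  out
}

#' Flag all-N sequences
#' @param bases Character vector.
#' @return Logical vector, `TRUE` where a sequence contains no called base.
#' @export
is_all_n <- function(bases) !grepl("[ACGT]", bases)

#' Collapse mate overlap into one per-fragment base track
#'
#' Merges the two mate consensus tracks of each fragment so every reference
#' position contributes at most one consensus base per molecule. Where
#' mates overlap and agree the base is kept; where they disagree the
#' position becomes `N`; where one mate is `N` (no evidence) the other
#' mate's call is used. Fragments whose mates map to different chromosomes
#' are dropped and counted.
#'
#' @param sscs A data.table of per-mate consensus records as produced by
#'   [call_all_sscs()] (columns `family_id`, `mate`, `chrom`, `start`,
#'   `end`, `bases`, plus carried key columns).
#' @return A list: `fragments` (one row per molecule with a full-length
#'   `bases` track spanning `frag_start`..`frag_end`) and `n_discordant`
#'   (fragments dropped for mate chromosome disagreement).
#' @export
collapse_mate_overlap <- function(sscs) {
  dt <- data.table::as.data.table(sscs)
  disc <- dt[, .(nchrom = data.table::uniqueN(chrom)), by = family_id]
  bad <- disc[nchrom > 1L, family_id]
  dt <- dt[!family_id %in% bad]
  if (!nrow(dt)) {
    return(list(fragments = dt, n_discordant = length(bad)))
  }

  # long form: one row per (fragment, reference position, mate base)
  reps <- dt$end - dt$start
  long <- data.table::data.table(
    family_id = rep(dt$family_id, reps),
    pos = unlist(lapply(seq_len(nrow(dt)),
                        function(i) seq.int(dt$start[i], dt$end[i] - 1L)),
                 use.names = FALSE),
    ch = unlist(strsplit(dt$bases, "", fixed = TRUE), use.names = FALSE)
  )
  data.table::setorder(long, family_id, pos)
  dup <- duplicated(long, by = c("family_id", "pos"))
  i2 <- which(dup)
  if (length(i2)) {
    i1 <- i2 - 1L
    c1 <- long$ch[i1]
    c2 <- long$ch[i2]
    resolved <- ifelse(c1 == c2, c1,
                       ifelse(c1 == "N", c2, ifelse(c2 == "N", c1, "N")))
    long$ch[i1] <- resolved
    long <- long[!dup]
  }

  meta <- dt[, .(chrom = chrom[1L], frag_start = frag_start[1L],
                 frag_end = frag_end[1L], orientation = orientation[1L],
                 umi1 = umi1[1L], umi2 = umi2[1L],
                 sample_id = sample_id[1L], family_size = family_size[1L]),
             by = family_id]
  # fragment positions not covered by either mate (long inserts) stay N
  span <- meta[long, on = "family_id"]
  tracks <- span[, .(bases = {
    full <- rep("N", frag_end[1L] - frag_start[1L])
    full[pos - frag_start[1L] + 1L] <- ch
    paste(full, collapse = "")
  }), by = family_id]
  frags <- meta[tracks, on = "family_id"]
  data.table::setnames(frags, c("frag_start", "frag_end"), c("start", "end"))
  list(fragments = frags[], n_discordant = length(bad))
}

#' Remove tag-swap / index-hopping duplicate consensus reads
#'
#' Within each group of consensus fragments sharing the exact same
#' chromosome, start and stop position, any two records whose first
#' barcodes match exactly OR whose second barcodes match exactly are
#' treated as copies of one input molecule (a tag swap, an index hop, or a
#' single barcode error). Matching records are clustered transitively; one
#' representative per cluster is kept — the largest family, ties broken
#' lexicographically by the barcode pair — and the rest removed.
#'
#' The filter is idempotent, never grows the input, and never removes the
#' last record of a position group.
#'
#' @param fragments Data.frame/data.table with columns `chrom`, `start`,
#'   `end`, `umi1`, `umi2`, `family_size`.
#' @param across_samples Compare barcodes across all samples in the run
#'   (default `TRUE`, catching index hops between co-multiplexed
#'   libraries); if `FALSE`, filter within each sample independently.
#' @return List: `kept` (filtered table) and `n_removed`.
#' @export
filter_tag_swaps <- function(fragments, across_samples = TRUE) {
  dt <- data.table::as.data.table(fragments)
  if (!nrow(dt)) return(list(kept = dt, n_removed = 0L))
  grp_cols <- c("chrom", "start", "end")
  if (!across_samples && "sample_id" %in% names(dt)) {
    grp_cols <- c("sample_id", grp_cols)
  }
  dt[, .grp_tmp := .GRP, by = grp_cols]
  dt[, .row_tmp := .I]

  multi <- dt[, .N, by = .grp_tmp][N > 1L, .grp_tmp]
  keep <- rep(TRUE, nrow(dt))
  for (g in multi) {
    sub <- dt[.grp_tmp == g]
    comp <- cluster_by_umi(sub$umi1, sub$umi2)
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) == 1L) next
      ord <- order(-sub$family_size[members], sub$umi1[members],
                   sub$umi2[members])
      drop <- members[ord][-1L]
      keep[sub$.row_tmp[drop]] <- FALSE
    }
  }
  removed <- sum(!keep)
  out <- dt[keep]
  out[, c(".grp_tmp", ".row_tmp") := NULL]
  list(kept = out[], n_removed = removed)
}

# Connected components where records sharing umi1 or umi2 are linked.
cluster_by_umi <- function(u1, u2) {
  n <- length(u1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (u in list(u1, u2)) {
    first <- match(u, u)
    for (i in seq_len(n)) if (first[i] != i) link(first[i], i)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Run the full consensus pipeline
#'
#' Groups tagged aligned records into families, calls per-mate SSCS
#' (minimum family size, agreement threshold), masks consensus ends,
#' collapses mate overlap into per-fragment tracks, and removes tag-swap
#' duplicates. Counts are conserved at every stage and reported.
#'
#' @param records Tagged aligned records (see [group_families()]).
#' @param min_family_size Minimum reads per family (default 3).
#' @param agreement Consensus agreement threshold (default 0.90).
#' @param mask_n Bases masked at each consensus end (default 5).
#' @param filter_swaps Apply the tag-swap filter (default `TRUE`).
#' @param across_samples Passed to [filter_tag_swaps()].
#' @return List of class `consensus_result`: `fragments` (per-molecule base
#'   tracks), `sscs` (per-mate consensus reads before overlap collapse),
#'   and `metrics` (named counts: input families, omissions by reason,
#'   emitted consensus reads, tag swaps removed).
#' @export
run_consensus_pipeline <- function(records, min_family_size = 3L,
                                   agreement = 0.90, mask_n = 5L,
                                   filter_swaps = TRUE,
                                   across_samples = TRUE) {
  fams <- group_families(records)
  cc <- call_all_sscs(fams, min_family_size = min_family_size,
                      agreement = agreement)
  metrics <- as.list(cc$metrics)
  metrics$records_excluded <- sum(fams$excluded)
  if (is.null(cc$sscs) || !nrow(cc$sscs)) {
    empty <- data.table::data.table()
    return(structure(list(fragments = empty, sscs = empty, metrics = metrics),
                     class = "consensus_result"))
  }
  sscs <- cc$sscs
  sscs[, bases := mask_ends(bases, mask_n)]
  col <- collapse_mate_overlap(sscs)
  metrics$fragments_discordant <- col$n_discordant
  frags <- col$fragments
  if (filter_swaps && nrow(frags)) {
    fl <- filter_tag_swaps(frags, across_samples = across_samples)
    frags <- fl$kept
    metrics$tag_swaps_removed <- fl$n_removed
  } else {
    metrics$tag_swaps_removed <- 0L
  }
  metrics$fragments_out <- nrow(frags)
  structure(list(fragments = frags, sscs = sscs, metrics = metrics),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  m <- x$metrics
  cat("consensus pipeline:\n")
  for (k in names(m)) cat(sprintf("  %-26s %d\n", k, m[[k]]))
  invisible(x)
}

#' Pile up consensus fragments over panel sites
#'
#' Counts, at each tracked mutation site, the consensus fragments covering
#' the site and how many carry the alternate allele, another non-reference
#' base, or `N`. `depth` counts all covering fragments including `N` calls;
#' the reference count is `depth - alt_count - other_count - n_count`.
#'
#' @param fragments Per-fragment consensus tracks
#'   (`run_consensus_pipeline()$fragments`).
#' @param panel Data.frame of panel sites with columns `chrom`, `pos`
#'   (0-based), `ref`, `alt`.
#' @return Data.frame: panel columns plus `depth`, `alt_count`,
#'   `other_count`, `n_count`.
#' @export
pileup_panel <- function(fragments, panel) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(panel)))
  fr <- data.table::as.data.table(fragments)
  out <- panel
  out$depth <- 0L
  out$alt_count <- 0L
  out$other_count <- 0L
  out$n_count <- 0L
  if (!nrow(fr)) return(out)
  for (i in seq_len(nrow(panel))) {
    p <- panel$pos[i]
    sel <- fr[chrom == panel$chrom[i] & start <= p & end > p]
    if (!nrow(sel)) next
    ch <- substr(sel$bases, p - sel$start + 1L, p - sel$start + 1L)
    out$depth[i] <- length(ch)
    out$alt_count[i] <- sum(ch == panel$alt[i])
    out$n_count[i] <- sum(ch == "N")
    out$other_count[i] <- sum(ch != panel$alt[i] & ch != panel$ref[i] &
                                ch != "N")
  }
  out
}
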