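# Catalog construction: inclusion filters, ancestry flag, highly conserved
# subset. Coordinates are 0-based half-open (BED convention) throughout.

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Default thresholds for the CNE inclusion filters
#'
#' Minimum element length 70 bp; Blastx E-value below 0.01 rejects (protein
#' similarity implies coding potential); a second self-BLAT hit with score of
#' at least 40 rejects (close paralogy risks orthology mis-alignment); exon
#' flank margin 100 bp (trimmed away to avoid splice-regulatory conservation);
#' mitochondrial / random / haplotype chromosomes denied.
#'
#' @return named list of thresholds consumed by [apply_cne_filters()].
#' @export
cne_filter_thresholds <- function() {
  list(min_len = 70L, blastx_evalue = 0.01, blat_score = 40,
       exon_flank = 100L, chrom_deny_regex = "(^chrM$)|(_random$)|(_hap)")
}

#' Apply the CNE inclusion filters to candidate conserved elements
#'
#' Builds the analyzable CNE catalog from candidate conserved elements:
#' \enumerate{
#'   \item candidates on denied chromosomes (mitochondrial, random, haplotype)
#'     are removed;
#'   \item candidates overlapping any exon are removed;
#'   \item candidates overlapping the ncRNA / transposon / pseudogene
#'     exclusion track are removed;
#'   \item portions of the remaining candidates within `exon_flank` bp of an
#'     exon are trimmed away; each resulting fragment re-enters the length
#'     filter independently (an element split in two can yield two records);
#'   \item fragments shorter than `min_len` bp are removed;
#'   \item elements with a Blastx protein hit at E-value < 0.01 are removed;
#'   \item elements with a second self-BLAT hit of score >= 40 are removed;
#'   \item elements with no alignment to any outgroup species are removed
#'     (loss of an ancestral element must be distinguished from recent gain).
#' }
#' The removal rules commute; only the trim step is ordered (before the
#' length check). Absent hit-table entries mean "no hit".
#'
#' @param candidates data.frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open) plus any annotation columns (carried through).
#' @param exon_track,exclusion_track data.frames with `chrom`, `start`, `end`.
#' @param blastx_hits data.frame `id`, `evalue` (minimum E-value per element),
#'   or NULL.
#' @param self_blat_hits data.frame `id`, `score` (second-best BLAT score per
#'   element), or NULL.
#' @param outgroup_alignment data.frame `id`, `species`: one row per element x
#'   outgroup species with detectable alignment, or NULL (no element passes).
#' @param thresholds list as produced by [cne_filter_thresholds()].
#' @return list with `cnes` (accepted records, possibly trimmed/split, with a
#'   `trimmed` flag) and `report` (one row per input element: `id`,
#'   `accepted`, `reason`).
#' @export
apply_cne_filters <- function(candidates, exon_track = NULL,
                              exclusion_track = NULL, blastx_hits = NULL,
                              self_blat_hits = NULL, outgroup_alignment = NULL,
                              thresholds = cne_filter_thresholds()) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(candidates)))
  if (any(candidates$start < 0) || any(candidates$end <= candidates$start))
    stop("malformed interval: start must satisfy 0 <= start < end")
  th <- utils::modifyList(cne_filter_thresholds(), thresholds)
  if (th$min_len < 0 || th$blastx_evalue < 0 || th$blat_score < 0 ||
      th$exon_flank < 0)
    stop("negative threshold")
  if (anyDuplicated(candidates$id)) stop("duplicate candidate ids")

  n <- nrow(candidates)
  reason <- rep(NA_character_, n)

  deny <- grepl(th$chrom_deny_regex, candidates$chrom)
  reason[deny] <- "chrom_denied"

  cand_gr <- .as_granges(candidates)
  if (!is.null(exon_track) && nrow(exon_track)) {
    hit <- IRanges::overlapsAny(cand_gr, .as_granges(exon_track))
    reason[is.na(reason) & hit] <- "exon_overlap"
  }
  if (!is.null(exclusion_track) && nrow(exclusion_track)) {
    hit <- IRanges::overlapsAny(cand_gr, .as_granges(exclusion_track))
    reason[is.na(reason) & hit] <- "ncrna_transposon_overlap"
  }

  # trim away portions within exon_flank bp of exons, then re-check length
  zones <- NULL
  if (!is.null(exon_track) && nrow(exon_track)) {
    zones <- GenomicRanges::reduce(
      .as_granges(exon_track) + th$exon_flank)
  }
  keep_rows <- list()
  for (i in seq_len(n)) {
    if (!is.na(reason[i])) next
    frags <- data.frame(start = candidates$start[i], end = candidates$end[i])
    trimmed <- FALSE
    if (!is.null(zones)) {
      ir <- IRanges::IRanges(candidates$start[i] + 1L, candidates$end[i])
      zi <- IRanges::ranges(zones[GenomicRanges::seqnames(zones) ==
                                    candidates$chrom[i]])
      left <- IRanges::setdiff(ir, zi)
      if (length(left) == 0L || sum(IRanges::width(left)) <
            candidates$end[i] - candidates$start[i]) trimmed <- TRUE
      frags <- data.frame(start = IRanges::start(left) - 1L,
                          end = IRanges::end(left))
    }
    frags <- frags[frags$end - frags$start >= th$min_len, , drop = FALSE]
    if (nrow(frags) == 0L) { reason[i] <- "min_length"; next }
    ids <- if (nrow(frags) == 1L) candidates$id[i] else
      paste0(candidates$id[i], ".", seq_len(nrow(frags)))
    keep_rows[[length(keep_rows) + 1L]] <-
      data.frame(row = i, id = ids, start = frags$start, end = frags$end,
                 trimmed = trimmed, stringsAsFactors = FALSE)
  }

  # hit-table and outgroup filters operate on the original element id
  reject_by_id <- function(ids_bad, code) {
    bad <- is.na(reason) & candidates$id %in% ids_bad
    reason[bad] <<- code
  }
  if (!is.null(blastx_hits) && nrow(blastx_hits))
    reject_by_id(blastx_hits$id[blastx_hits$evalue < th$blastx_evalue],
                 "blastx_coding")
  if (!is.null(self_blat_hits) && nrow(self_blat_hits))
    reject_by_id(self_blat_hits$id[self_blat_hits$score >= th$blat_score],
                 "blat_paralog")
  og_ids <- if (is.null(outgroup_alignment)) character(0) else
    unique(outgroup_alignment$id)
  reject_by_id(setdiff(candidates$id, og_ids), "no_outgroup")

  accepted <- is.na(reason)
  cnes <- NULL
  if (length(keep_rows)) {
    kept <- do.call(rbind, keep_rows)
    kept <- kept[accepted[kept$row], , drop = FALSE]
    if (nrow(kept)) {
      extra <- candidates[kept$row,
                          setdiff(names(candidates), c("id", "start", "end")),
                          drop = FALSE]
      cnes <- data.frame(id = kept$id, extra, start = kept$start,
                         end = kept$end, row.names = NULL,
                         stringsAsFactors = FALSE)
      cnes$length <- cnes$end - cnes$start
      cnes$trimmed <- kept$trimmed
      cnes <- cnes[, c("id", "chrom", "start", "end", "length", "trimmed",
                       setdiff(names(cnes), c("id", "chrom", "start", "end",
                                              "length", "trimmed")))]
    }
  }
  if (is.null(cnes))
    cnes <- data.frame(id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       length = integer(0), trimmed = logical(0))
  report <- data.frame(id = candidates$id, accepted = accepted,
                       reason = reason, stringsAsFactors = FALSE)
  list(cnes = cnes, report = report)
}

#' Flag CNEs that predate the mammalian ancestor
#'
#' A CNE is flagged as pre-mammalian when it aligns with at least 80% of its
#' length to at least one non-mammalian vertebrate (e.g. chicken, zebra
#' finch, lizard, frog or fish). The 80% rule is inclusive.
#'
#' @param cnes data.frame with `id` and `length` (or `start`/`end`).
#' @param nonmammal_cov data.frame `id`, `species`, `aligned_bp`: aligned
#'   bases of the element to each non-mammalian vertebrate.
#' @param min_fraction alignment fraction required, default 0.8.
#' @return logical vector along `cnes` rows.
#' @export
flag_ancestry <- function(cnes, nonmammal_cov, min_fraction = 0.8) {
  len <- if ("length" %in% names(cnes)) cnes$length else cnes$end - cnes$start
  if (is.null(nonmammal_cov) || nrow(nonmammal_cov) == 0L)
    return(rep(FALSE, nrow(cnes)))
  best <- tapply(nonmammal_cov$aligned_bp, nonmammal_cov$id, max)
  cov <- as.numeric(best[match(cnes$id, names(best))])
  cov[is.na(cov)] <- 0
  if (any(cov > len))
    stop("aligned coverage exceeds element length for: ",
         paste(cnes$id[cov > len], collapse = ", "))
  cov / len >= min_fraction
}

#' Select the highly conserved CNE subset
#'
#' Keeps elements under extreme sequence constraint: fraction of rejected
#' substitutions (GERP-style RS fraction) strictly greater than `rs_min` and
#' conservation P-value (phyloP-style) strictly below `phylop_max`. Elements
#' missing either annotation are skipped with a warning and counted in the
#' `skipped` attribute.
#'
#' @param cnes data.frame with columns `constraint_rs` and `phylop_p`.
#' @param rs_min strict lower bound on the rejected-substitution fraction
#'   (default 0.5, i.e. ">50%").
#' @param phylop_max strict upper bound on the conservation P-value
#'   (default 1e-20).
#' @return the selected subset of `cnes`, with attribute `skipped` giving the
#'   number of elements lacking annotation.
#' @export
select_highly_conserved <- function(cnes, rs_min = 0.5, phylop_max = 1e-20) {
  stopifnot(all(c("constraint_rs", "phylop_p") %in% names(cnes)))
  miss <- is.na(cnes$constraint_rs) | is.na(cnes$phylop_p)
  if (any(miss))
    warning(sum(miss), " element(s) lack constraint annotation and were skipped")
  keep <- !miss & cnes$constraint_rs > rs_min & cnes$phylop_p < phylop_max
  out <- cnes[keep, , drop = FALSE]
  attr(out, "skipped") <- sum(miss)
  out
}
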