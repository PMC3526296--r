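# Classification of CNE x species cells from syntenic flank evidence,
# deletion-size analysis, spanning-read validation and control regions.

MISSING_REASONS <- c("no_flank", "not_cosyntenic", "assembly_gap",
                     "similarity_hit", "low_coverage_species")

# Derive co-synteny flag, inter-flank distances and the query inter-flank
# interval from raw evidence rows. Negative-strand blocks are oriented so
# query distances run along the query and are non-negative.
.evidence_derive <- function(ev) {
  has_up <- !is.na(ev$up_q_start) & !is.na(ev$up_q_end)
  has_down <- !is.na(ev$down_q_start) & !is.na(ev$down_q_end)
  same_scaf <- has_up & has_down &
    as.character(ev$up_scaffold) == as.character(ev$down_scaffold)
  plus <- !is.na(ev$strand) & ev$strand == "+"
  order_ok <- same_scaf &
    ifelse(plus, ev$up_q_end <= ev$down_q_start, ev$down_q_end <= ev$up_q_start)
  co <- same_scaf & order_ok
  q_start <- ifelse(plus, ev$up_q_end, ev$down_q_end)
  q_end <- ifelse(plus, ev$down_q_start, ev$up_q_start)
  q_start[!co] <- NA_real_
  q_end[!co] <- NA_real_
  ref_dist <- ev$down_ref_start - ev$up_ref_end
  data.frame(
    has_up = has_up, has_down = has_down, co_syntenic = co,
    ref_flank_distance = ref_dist,
    query_flank_distance = ifelse(co, pmax(q_end - q_start, 0), NA_real_),
    q_interflank_start = q_start, q_interflank_end = q_end,
    scaffold = ifelse(has_up, as.character(ev$up_scaffold),
                      as.character(ev$down_scaffold))
  )
}

.empty_evidence_row <- function() {
  data.frame(up_ref_start = NA_real_, up_ref_end = NA_real_,
             down_ref_start = NA_real_, down_ref_end = NA_real_,
             up_scaffold = NA_character_, down_scaffold = NA_character_,
             up_q_start = NA_real_, up_q_end = NA_real_,
             down_q_start = NA_real_, down_q_end = NA_real_,
             strand = NA_character_, cne_overlap_bp = 0)
}

#' Classify one CNE in one species from alignment evidence
#'
#' A cell is CONSERVED when at least `min_overlap` bp of the species'
#' alignment overlaps the CNE. For a loss-search species with zero overlap,
#' the cell is LOST only when all three loss filters pass: co-syntenic
#' aligning flanks exist up- and downstream, the query inter-flank interval
#' contains no assembly gap, and no sequence-similarity hit (genome or
#' unassembled trace reads) is recorded for the element in that species.
#' Otherwise the cell is MISSING with the first failing reason, in fixed
#' precedence: `no_flank`, `not_cosyntenic`, `assembly_gap`,
#' `similarity_hit`. Species in which losses are not searched (presence-only
#' and outgroup genomes) get MISSING with reason `low_coverage_species` when
#' the CNE does not align: absence there may be an artifact, so neither loss
#' nor conservation is claimed.
#'
#' @param cne_id element identifier (evidence must reference the same id).
#' @param species leaf name of the tree.
#' @param ev single evidence row (see [build_status_matrix()] for columns) or
#'   NULL when the species has no flank evidence for this CNE.
#' @param gaps data.frame of assembly gaps in query coordinates of this
#'   species: `scaffold`, `start`, `end`; or NULL.
#' @param sim_hits data.frame of similarity hits: `cne_id`, `species` (plus
#'   optional `source`, `score`); or NULL.
#' @param tree a `cne_phylo` (supplies the species role).
#' @param min_overlap minimum aligning overlap in bp to call CONSERVED
#'   (default 1).
#' @return list with `status`, `reason` (NA unless MISSING), and the derived
#'   evidence fields (`co_syntenic`, `ref_flank_distance`,
#'   `query_flank_distance`).
#' @export
classify_status <- function(cne_id, species, ev = NULL, gaps = NULL,
                            sim_hits = NULL, tree, min_overlap = 1) {
  stopifnot(inherits(tree, "cne_phylo"))
  role <- tree$leaf_roles[[species]]
  if (is.null(role) || is.na(role)) stop("species has no role: ", species)
  if (!is.null(ev)) {
    if (!is.na(ev$cne_id) && ev$cne_id != cne_id)
      stop("evidence row references a different CNE: ", ev$cne_id)
  } else ev <- cbind(cne_id = cne_id, .empty_evidence_row())
  d <- .evidence_derive(ev)
  overlap <- ifelse(is.na(ev$cne_overlap_bp), 0, ev$cne_overlap_bp)

  if (overlap >= min_overlap)
    return(list(status = STATUS_CONSERVED, reason = NA_character_,
                co_syntenic = d$co_syntenic,
                ref_flank_distance = d$ref_flank_distance,
                query_flank_distance = d$query_flank_distance))
  if (role != "loss_search")
    return(list(status = STATUS_MISSING, reason = "low_coverage_species",
                co_syntenic = d$co_syntenic,
                ref_flank_distance = d$ref_flank_distance,
                query_flank_distance = d$query_flank_distance))

  reason <- NA_character_
  if (!d$has_up || !d$has_down) reason <- "no_flank"
  else if (!d$co_syntenic) reason <- "not_cosyntenic"
  else {
    gap_hit <- FALSE
    if (!is.null(gaps) && nrow(gaps)) {
      g <- gaps[gaps$scaffold == d$scaffold, , drop = FALSE]
      gap_hit <- any(g$start < d$q_interflank_end & g$end > d$q_interflank_start)
    }
    if (gap_hit) reason <- "assembly_gap"
    else {
      sim <- !is.null(sim_hits) && nrow(sim_hits) > 0 &&
        any(sim_hits$cne_id == cne_id & sim_hits$species == species)
      if (sim) reason <- "similarity_hit"
    }
  }
  status <- if (is.na(reason)) STATUS_LOST else STATUS_MISSING
  list(status = status, reason = reason, co_syntenic = d$co_syntenic,
       ref_flank_distance = d$ref_flank_distance,
       query_flank_distance = d$query_flank_distance)
}

#' Build the CNE x species status matrix
#'
#' Applies the loss-detection filters across a CNE catalog for every species
#' in the tree. Evidence is supplied as one long table keyed by
#' (`cne_id`, `species`); duplicated keys are an error; a missing row means
#' no alignment and no flank evidence for that species.
#'
#' CNEs for which no outgroup species is CONSERVED are dropped with an audit
#' (such elements cannot be asserted ancestral; the catalog normally
#' guarantees at least one aligning outgroup).
#'
#' @param cnes data.frame with at least `id` (catalog records).
#' @param evidence data.frame with columns `cne_id`, `species`, `ref_chrom`,
#'   `up_ref_start`, `up_ref_end`, `down_ref_start`, `down_ref_end`,
#'   `up_scaffold`, `down_scaffold`, `up_q_start`, `up_q_end`,
#'   `down_q_start`, `down_q_end`, `strand`, `cne_overlap_bp`.
#' @param gaps data.frame `species`, `scaffold`, `start`, `end` of assembly
#'   gaps in query coordinates, or NULL.
#' @param hits data.frame `cne_id`, `species` (+ optional `source`, `score`)
#'   of sequence-similarity hits, or NULL.
#' @param tree a `cne_phylo`.
#' @param min_overlap minimum aligning overlap for CONSERVED (default 1 bp).
#' @return object of class `cne_status`: list with `status` (character
#'   matrix CNE x species), `reason` (reason codes where MISSING),
#'   `loss_evidence` (one row per LOST cell with flank distances, used by
#'   [deletion_analysis()] and trace validation), `dropped` (audit of CNEs
#'   without a conserved outgroup) and `species_summary`.
#' @export
build_status_matrix <- function(cnes, evidence, gaps = NULL, hits = NULL,
                                tree, min_overlap = 1) {
  stopifnot(inherits(tree, "cne_phylo"))
  ids <- as.character(cnes$id)
  species <- tree$ape$tip.label
  if (anyDuplicated(paste(evidence$cne_id, evidence$species, sep = "\r")))
    stop("duplicate (cne, species) evidence rows")
  bad_id <- setdiff(unique(evidence$cne_id), ids)
  if (length(bad_id))
    stop("evidence references unknown CNE ids: ",
         paste(utils::head(bad_id, 5), collapse = ", "))

  n <- length(ids)
  status <- matrix(NA_character_, n, length(species),
                   dimnames = list(ids, species))
  reason <- matrix(NA_character_, n, length(species),
                   dimnames = list(ids, species))
  loss_ev <- list()

  hit_key <- if (!is.null(hits) && nrow(hits))
    unique(paste(hits$cne_id, hits$species, sep = "\r")) else character(0)

  for (s in species) {
    role <- tree$leaf_roles[[s]]
    ev_s <- evidence[evidence$species == s, , drop = FALSE]
    row_of <- match(ids, ev_s$cne_id)
    overlap <- rep(0, n)
    overlap[!is.na(row_of)] <- ev_s$cne_overlap_bp[row_of[!is.na(row_of)]]
    overlap[is.na(overlap)] <- 0
    conserved <- overlap >= min_overlap
    status[conserved, s] <- STATUS_CONSERVED
    rest <- which(!conserved)
    if (!length(rest)) next
    if (role != "loss_search") {
      status[rest, s] <- STATUS_MISSING
      reason[rest, s] <- "low_coverage_species"
      next
    }
    d <- if (nrow(ev_s)) .evidence_derive(ev_s) else NULL
    for (i in rest) {
      r <- row_of[i]
      if (is.na(r) || !d$has_up[r] || !d$has_down[r]) {
        status[i, s] <- STATUS_MISSING; reason[i, s] <- "no_flank"; next
      }
      if (!d$co_syntenic[r]) {
        status[i, s] <- STATUS_MISSING; reason[i, s] <- "not_cosyntenic"; next
      }
      gap_hit <- FALSE
      if (!is.null(gaps) && nrow(gaps)) {
        g <- gaps[gaps$species == s & gaps$scaffold == d$scaffold[r], ,
                  drop = FALSE]
        gap_hit <- nrow(g) > 0 &&
          any(g$start < d$q_interflank_end[r] & g$end > d$q_interflank_start[r])
      }
      if (gap_hit) {
        status[i, s] <- STATUS_MISSING; reason[i, s] <- "assembly_gap"; next
      }
      if (paste(ids[i], s, sep = "\r") %in% hit_key) {
        status[i, s] <- STATUS_MISSING; reason[i, s] <- "similarity_hit"; next
      }
      status[i, s] <- STATUS_LOST
      loss_ev[[length(loss_ev) + 1L]] <- data.frame(
        cne_id = ids[i], species = s,
        ref_flank_distance = d$ref_flank_distance[r],
        query_flank_distance = d$query_flank_distance[r],
        scaffold = d$scaffold[r],
        q_interflank_start = d$q_interflank_start[r],
        q_interflank_end = d$q_interflank_end[r],
        stringsAsFactors = FALSE)
    }
  }

  og <- species[tree$leaf_roles == "outgroup"]
  has_og <- rowSums(status[, og, drop = FALSE] == STATUS_CONSERVED) > 0
  dropped <- ids[!has_og]
  loss_evidence <- if (length(loss_ev)) do.call(rbind, loss_ev) else
    data.frame(cne_id = character(0), species = character(0),
               ref_flank_distance = numeric(0),
               query_flank_distance = numeric(0), scaffold = character(0),
               q_interflank_start = numeric(0), q_interflank_end = numeric(0))
  if (length(dropped)) {
    status <- status[has_og, , drop = FALSE]
    reason <- reason[has_og, , drop = FALSE]
    loss_evidence <- loss_evidence[!(loss_evidence$cne_id %in% dropped), ,
                                   drop = FALSE]
  }
  sum_tab <- apply(status, 2, function(col)
    c(conserved = sum(col == STATUS_CONSERVED),
      lost = sum(col == STATUS_LOST),
      missing = sum(col == STATUS_MISSING)))

  out <- list(status = status, reason = reason,
              loss_evidence = loss_evidence, dropped = dropped,
              species_summary = t(sum_tab), tree = tree)
  class(out) <- "cne_status"
  out
}

#' @export
print.cne_status <- function(x, ...) {
  cat("CNE status matrix: ", nrow(x$status), " CNEs x ", ncol(x$status),
      " species\n", sep = "")
  print(x$species_summary)
  if (length(x$dropped))
    cat("dropped (no conserved outgroup):", length(x$dropped), "\n")
  invisible(x)
}

#' Deletion-size analysis of CNE losses
#'
#' For each LOST cell with co-syntenic evidence, the deletion involved in the
#' loss is estimated as the difference between the inter-flank distance in
#' the reference and in the CNE-loss genome. A per-species summary is
#' returned together with the least-squares regression of the reference
#' distance on the query distance (slope 1 indicates no net deletion).
#' Negative estimates (net insertions) are permitted and reported.
#'
#' @param calls data.frame with `species`, `ref_flank_distance`,
#'   `query_flank_distance` (e.g. the `loss_evidence` element of a
#'   `cne_status`).
#' @return data.frame with one row per species plus a pooled `all` row:
#'   `n`, median/mean reference and query distances, median/mean estimated
#'   deletion, regression `slope` and `intercept`.
#' @export
deletion_analysis <- function(calls) {
  cols <- c("species", "ref_flank_distance", "query_flank_distance")
  if (is.null(calls) || nrow(calls) == 0L)
    return(data.frame(species = character(0), n = integer(0),
                      median_ref = numeric(0), mean_ref = numeric(0),
                      median_query = numeric(0), mean_query = numeric(0),
                      median_deletion = numeric(0), mean_deletion = numeric(0),
                      slope = numeric(0), intercept = numeric(0)))
  stopifnot(all(cols %in% names(calls)))
  one <- function(df, label) {
    del <- df$ref_flank_distance - df$query_flank_distance
    q <- df$query_flank_distance
    r <- df$ref_flank_distance
    if (nrow(df) >= 2L && stats::var(q) > 0) {
      slope <- stats::cov(q, r) / stats::var(q)
      intercept <- mean(r) - slope * mean(q)
    } else { slope <- NA_real_; intercept <- NA_real_ }
    data.frame(species = label, n = nrow(df),
               median_ref = median(r), mean_ref = mean(r),
               median_query = median(q), mean_query = mean(q),
               median_deletion = median(del), mean_deletion = mean(del),
               slope = slope, intercept = intercept,
               stringsAsFactors = FALSE)
  }
  per <- lapply(split(calls, calls$species), function(df)
    one(df, df$species[1]))
  rbind(do.call(rbind, per), one(calls, "all"))
}

#' Validate a CNE-loss region with spanning unassembled reads
#'
#' A loss region (the interval between the aligning flanks in the CNE-loss
#' genome) is `validated` when a single mapped read spans the entire region
#' plus `flank_pad` bp on either side. Regions of `max_len` bp or more are
#' excluded (`too_long`): typical Sanger reads (~800 bp) cannot span them.
#' Read placements are taken as given; mapping criteria (>= 90% identity,
#' alignment <= 105% of read length, best hit per read) are applied upstream.
#'
#' @param region numeric length-2 vector `c(start, end)` of the loss region
#'   on a query scaffold (0-based half-open).
#' @param reads data.frame of read placements on the same scaffold with
#'   `start`, `end`.
#' @param flank_pad extra bases required on each side (default 50).
#' @param max_len regions at least this long are excluded (default 500,
#'   strict: a 500 bp region is `too_long`).
#' @return one of `"validated"`, `"not_validated"`, `"too_long"`.
#' @export
validate_with_traces <- function(region, reads, flank_pad = 50,
                                 max_len = 500) {
  if (flank_pad < 0 || max_len < 0) stop("flank_pad and max_len must be >= 0")
  stopifnot(length(region) == 2L, region[2] >= region[1])
  if (region[2] - region[1] >= max_len) return("too_long")
  if (!is.null(reads) && nrow(reads) &&
      any(reads$start <= region[1] - flank_pad &
          reads$end >= region[2] + flank_pad))
    return("validated")
  "not_validated"
}

#' Sample gap-free control regions of a given size
#'
#' Draws `n` intervals of exactly `size` bp, uniformly over all placements on
#' the supplied chromosomes/scaffolds that do not overlap an assembly gap.
#' The feasible start positions are enumerated exactly, so the draw is
#' uniform by construction and reproducible under a fixed RNG seed.
#'
#' @param size region size in bp (>= 0).
#' @param chrom_sizes named numeric vector of chromosome/scaffold lengths
#'   (typically those carrying at least one loss region).
#' @param gaps data.frame `chrom`, `start`, `end` of assembly gaps, or NULL.
#' @param n number of control regions (default 5 per loss region).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
sample_control_regions <- function(size, chrom_sizes, gaps = NULL, n = 5) {
  stopifnot(size >= 0, n >= 1, length(chrom_sizes) >= 1,
            !is.null(names(chrom_sizes)))
  free <- list()
  for (ch in names(chrom_sizes)) {
    ir <- IRanges::IRanges(1L, as.integer(chrom_sizes[[ch]]))
    if (!is.null(gaps) && nrow(gaps)) {
      g <- gaps[gaps$chrom == ch, , drop = FALSE]
      if (nrow(g))
        ir <- IRanges::setdiff(ir, IRanges::IRanges(g$start + 1L, g$end))
    }
    if (length(ir))
      free[[length(free) + 1L]] <- data.frame(
        chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }
  if (!length(free)) stop("no gap-free sequence on the supplied chromosomes")
  free <- do.call(rbind, free)
  counts <- pmax(0, free$end - free$start - size + 1)
  total <- sum(counts)
  if (total == 0)
    stop("no feasible gap-free placement of size ", size,
         " on the supplied chromosomes")
  idx <- sample.int(total, n, replace = TRUE)
  cum <- cumsum(counts)
  block <- findInterval(idx - 1, cum) + 1L
  offset <- idx - c(0, cum)[block] - 1L
  start <- free$start[block] + offset
  data.frame(chrom = free$chrom[block], start = start, end = start + size,
             stringsAsFactors = FALSE)
}
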