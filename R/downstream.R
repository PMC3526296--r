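# Genomic-context analyses of independently lost CNEs: grouping, window
# clustering, separate-event verification, nearest-TSS gene-loss
# association, size matching and characteristic comparisons.

#' Group CNEs by loss multiplicity
#'
#' Labels every CNE from its inferred loss-branch set: no branch ->
#' `no_loss`, one branch -> `lineage_specific`, two or more -> `independent`
#' (with multiplicity k).
#'
#' @param events_by_cne named list (CNE id -> character vector of loss
#'   branches), e.g. `attr(infer_events(...), "by_cne")`.
#' @return data.frame `cne_id`, `group`, `k`.
#' @export
group_cnes <- function(events_by_cne) {
  ks <- lengths(events_by_cne)
  data.frame(
    cne_id = names(events_by_cne),
    group = ifelse(ks == 0L, "no_loss",
                   ifelse(ks == 1L, "lineage_specific", "independent")),
    k = as.integer(ks),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Sliding-window clustering of independently lost CNEs
#'
#' Slides a window over every chromosome and counts the independently lost
#' CNEs (by midpoint) in each window, returning the windows ranked by count.
#' The 5 Mb default window mirrors the scale at which regional
#' concentrations of independent losses (such as the DIAPH2 locus) become
#' apparent; the step is a design choice as sub-window resolution.
#'
#' @param cnes data.frame with `chrom`, `start`, `end` of the independently
#'   lost CNEs.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param window window size in bp (default 5e6).
#' @param step step size in bp (default 1e5); must satisfy
#'   `window >= step > 0`.
#' @return data.frame `chrom`, `start`, `end`, `count`, `rank` ordered by
#'   decreasing count (zero-count windows omitted); tied counts share a
#'   rank.
#' @export
window_clusters <- function(cnes, chrom_sizes, window = 5e6, step = 1e5) {
  stopifnot(window >= step, step > 0)
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes)))
    stop("chrom_sizes must be a named vector")
  if (nrow(cnes) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), count = integer(0), rank = integer(0)))
  mid <- (cnes$start + cnes$end) / 2
  out <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + window, len)
    m <- mid[cnes$chrom == ch]
    if (!length(m)) next
    cnt <- vapply(seq_along(starts), function(i)
      sum(m >= starts[i] & m < ends[i]), integer(1))
    keep <- cnt > 0
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts[keep], end = ends[keep],
        count = cnt[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), count = integer(0), rank = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(-res$count, res$chrom, res$start), , drop = FALSE]
  res$rank <- rank(-res$count, ties.method = "min")
  rownames(res) <- NULL
  res
}

#' Verify that adjacent co-lost CNEs reflect separate loss events
#'
#' For CNEs on one chromosome, sorted by position, that are LOST in both
#' species of a pair, checks for every adjacent such pair whether at least
#' one intervening CNE is CONSERVED in both species. When true for every
#' pair, each co-lost CNE reflects a separate deletion event; a violation is
#' consistent with one large deletion removing several CNEs at once.
#'
#' @param cnes data.frame with `id`, `start` (one chromosome, sorted by
#'   `start`).
#' @param status character status matrix (rows = CNE ids).
#' @param species_pair character vector of two species names.
#' @return list with `pairs` (data.frame `left`, `right`, `separated`) and
#'   `all_separate` (TRUE when every adjacent pair has a conserved
#'   separator; TRUE vacuously with < 2 co-lost CNEs).
#' @export
verify_separate_events <- function(cnes, status, species_pair) {
  stopifnot(length(species_pair) == 2L)
  if (is.unsorted(cnes$start)) stop("cnes must be sorted by start position")
  st <- status[match(cnes$id, rownames(status)), species_pair, drop = FALSE]
  lost_both <- rowSums(st == STATUS_LOST) == 2L
  cons_both <- rowSums(st == STATUS_CONSERVED) == 2L
  idx <- which(lost_both)
  if (length(idx) < 2L)
    return(list(pairs = data.frame(left = character(0), right = character(0),
                                   separated = logical(0)),
                all_separate = TRUE))
  sep <- vapply(seq_len(length(idx) - 1L), function(i)
    any(cons_both[(idx[i] + 1L):(idx[i + 1L] - 1L)]), logical(1))
  pairs <- data.frame(left = cnes$id[idx[-length(idx)]],
                      right = cnes$id[idx[-1L]],
                      separated = sep, stringsAsFactors = FALSE)
  list(pairs = pairs, all_separate = all(sep))
}

#' Assign each CNE to the gene with the nearest transcription start site
#'
#' Nearest TSS by absolute distance from the CNE midpoint, upstream or
#' downstream without regard to gene orientation (enhancers act
#' orientation-independently). Equidistant TSS are broken toward the smaller
#' coordinate and flagged.
#'
#' @param cnes data.frame `id`, `chrom`, `start`, `end`.
#' @param tss data.frame `chrom`, `pos`, `gene` (strand optional and
#'   unused for the distance).
#' @param anchor distance anchor: `"midpoint"` (default) or `"edge"`
#'   (closest CNE edge).
#' @return data.frame `cne_id`, `gene`, `tss_pos`, `distance` (signed,
#'   TSS minus anchor), `tie` flag.
#' @export
assign_nearest_tss <- function(cnes, tss, anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  if (is.null(tss) || nrow(tss) == 0L) stop("empty TSS list")
  out <- lapply(seq_len(nrow(cnes)), function(i) {
    cand <- tss[tss$chrom == cnes$chrom[i], , drop = FALSE]
    if (!nrow(cand))
      return(data.frame(cne_id = cnes$id[i], gene = NA_character_,
                        tss_pos = NA_real_, distance = NA_real_, tie = FALSE))
    if (anchor == "midpoint") {
      a <- (cnes$start[i] + cnes$end[i]) / 2
      d <- abs(cand$pos - a)
      signed <- cand$pos - a
    } else {
      d <- pmax(pmax(cnes$start[i] - cand$pos, cand$pos - cnes$end[i]), 0)
      signed <- ifelse(cand$pos < cnes$start[i], cand$pos - cnes$start[i],
                       ifelse(cand$pos > cnes$end[i],
                              cand$pos - cnes$end[i], 0))
    }
    best <- which(d == min(d))
    tie <- length(best) > 1L
    j <- best[which.min(cand$pos[best])]
    data.frame(cne_id = cnes$id[i], gene = cand$gene[j],
               tss_pos = cand$pos[j], distance = signed[j], tie = tie,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Association of independent CNE losses with nearby gene loss
#'
#' For each independently lost CNE with an assigned nearest gene, asks
#' whether that gene lacks an ortholog in the CNE-loss species. Entries
#' recorded as `gap` (gene absent due to an assembly gap) are excluded from
#' the assessment, mirroring the manual filter applied to orthology tables.
#'
#' @param assignments data.frame `cne_id`, `gene` (from
#'   [assign_nearest_tss()]).
#' @param ortholog_presence data.frame `gene`, `species`, `status` in
#'   `c("present","absent","gap")`.
#' @param events_by_cne named list CNE id -> loss branches; loss species are
#'   the loss-search leaves below those branches.
#' @param tree a `cne_phylo`.
#' @return list with `n_any` (CNEs whose nearest gene is absent in at least
#'   one loss species), `n_all` (absent in all assessable loss species),
#'   `audit` (per-CNE rows).
#' @export
gene_loss_association <- function(assignments, ortholog_presence,
                                  events_by_cne, tree) {
  stopifnot(inherits(tree, "cne_phylo"))
  key <- paste(ortholog_presence$gene, ortholog_presence$species, sep = "\r")
  stat_of <- setNames(ortholog_presence$status, key)
  audit <- lapply(seq_len(nrow(assignments)), function(i) {
    id <- assignments$cne_id[i]
    gene <- assignments$gene[i]
    branches <- events_by_cne[[id]]
    sp <- unique(unlist(lapply(.node_id(tree, branches), function(v)
      tree$ape$tip.label[tree$leaves_below[[v]]])))
    st <- stat_of[paste(gene, sp, sep = "\r")]
    if (anyNA(st))
      stop("ortholog table lacks (", gene, ", ",
           paste(sp[is.na(st)], collapse = ","), ")")
    assess <- st != "gap"
    n_abs <- sum(st == "absent")
    data.frame(cne_id = id, gene = gene,
               n_loss_species = length(sp),
               n_assessable = sum(assess), n_absent = n_abs,
               any_absent = n_abs > 0,
               all_absent = n_abs > 0 & n_abs == sum(assess),
               stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, audit)
  list(n_any = sum(audit$any_absent), n_all = sum(audit$all_absent),
       audit = audit)
}

#' Size-matched control sets for the independent-loss CNEs
#'
#' For each independently lost CNE, samples (without replacement) one CNE of
#' exactly the same length from the no-loss pool and one from the
#' lineage-specific pool, so all three sets have identical length
#' multisets. Removes element length as a confounder when comparing
#' constraint or ancestry between the groups.
#'
#' @param independent,no_loss,lineage_specific data.frames with `id` and
#'   `length`.
#' @return list of three data.frames (`independent`, `no_loss`,
#'   `lineage_specific`) with identical length multisets.
#' @export
size_matched_sample <- function(independent, no_loss, lineage_specific) {
  pick <- function(pool, lens, label) {
    avail <- split(seq_len(nrow(pool)), pool$length)
    sel <- integer(0)
    for (L in lens) {
      key <- as.character(L)
      cand <- setdiff(avail[[key]], sel)
      if (!length(cand))
        stop("no unmatched ", label, " candidate of length ", L)
      sel <- c(sel, if (length(cand) == 1L) cand else sample(cand, 1L))
    }
    pool[sel, , drop = FALSE]
  }
  lens <- independent$length
  list(independent = independent,
       no_loss = pick(no_loss, lens, "no_loss"),
       lineage_specific = pick(lineage_specific, lens, "lineage_specific"))
}

#' Compare characteristics between CNE groups
#'
#' Per-group summaries and pairwise tests of the pleiotropy proxies: element
#' length and constraint (Wilcoxon rank-sum), fraction of extremely
#' constrained elements (rejected-substitution fraction above `rs_extreme`)
#' and fraction predating the mammalian ancestor (chi-square on the 2x2
#' table). Constant features are skipped with a note.
#'
#' @param groups named list of data.frames, each with columns among
#'   `length`, `constraint_rs`, `ancestry_pre_mammal`.
#' @param rs_extreme threshold for the "extremely constrained" bin
#'   (default 0.6, i.e. >60% of substitutions rejected).
#' @return list with `summary` (per-group feature table) and `tests`
#'   (pairwise data.frame `feature`, `group1`, `group2`, `test`, `p`).
#' @export
compare_characteristics <- function(groups, rs_extreme = 0.6) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)), all(vapply(groups, nrow, 1L) > 0))
  gn <- names(groups)
  summ <- do.call(rbind, lapply(gn, function(g) {
    d <- groups[[g]]
    data.frame(
      group = g, n = nrow(d),
      mean_length = if ("length" %in% names(d)) mean(d$length) else NA,
      median_length = if ("length" %in% names(d)) median(d$length) else NA,
      mean_rs = if ("constraint_rs" %in% names(d)) mean(d$constraint_rs)
                else NA,
      frac_extreme_rs = if ("constraint_rs" %in% names(d))
        mean(d$constraint_rs > rs_extreme) else NA,
      frac_pre_mammal = if ("ancestry_pre_mammal" %in% names(d))
        mean(d$ancestry_pre_mammal) else NA,
      stringsAsFactors = FALSE)
  }))
  tests <- list()
  add <- function(feature, g1, g2, test, p, note = NA_character_) {
    tests[[length(tests) + 1L]] <<- data.frame(
      feature = feature, group1 = g1, group2 = g2, test = test, p = p,
      note = note, stringsAsFactors = FALSE)
  }
  prs <- combn(gn, 2L, simplify = FALSE)
  for (pr in prs) {
    d1 <- groups[[pr[1]]]; d2 <- groups[[pr[2]]]
    for (feat in c("length", "constraint_rs")) {
      if (!feat %in% names(d1) || !feat %in% names(d2)) next
      x <- d1[[feat]]; y <- d2[[feat]]
      if (length(unique(c(x, y))) < 2L) {
        add(feat, pr[1], pr[2], "wilcoxon", NA_real_, "constant feature")
      } else {
        p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
        add(feat, pr[1], pr[2], "wilcoxon", p)
      }
    }
    for (feat in c("extreme_rs", "ancestry_pre_mammal")) {
      v1 <- switch(feat,
                   extreme_rs = if ("constraint_rs" %in% names(d1))
                     d1$constraint_rs > rs_extreme else NULL,
                   ancestry_pre_mammal = d1[["ancestry_pre_mammal"]])
      v2 <- switch(feat,
                   extreme_rs = if ("constraint_rs" %in% names(d2))
                     d2$constraint_rs > rs_extreme else NULL,
                   ancestry_pre_mammal = d2[["ancestry_pre_mammal"]])
      if (is.null(v1) || is.null(v2)) next
      tab <- rbind(c(sum(v1), sum(!v1)), c(sum(v2), sum(!v2)))
      if (any(colSums(tab) == 0)) {
        add(feat, pr[1], pr[2], "chisq", NA_real_, "constant feature")
      } else {
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
        add(feat, pr[1], pr[2], "chisq", p)
      }
    }
  }
  list(summary = summ, tests = do.call(rbind, tests))
}
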