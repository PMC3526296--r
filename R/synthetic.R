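# Coordinate-level synthetic data generator with known ground truth.
# Emulates the statistical structure the analysis assumes -- per-branch loss
# counts scaling with neutral branch length, losses realized as large
# deletions between co-syntenic flanks, independent per-species missing
# data, and artifact cells (assembly gaps, similarity hits, absent flanks).
# Sequence content is never simulated; everything lives at the
# coordinate/evidence level.

#' Default mammalian study tree for the generator
#'
#' A 12-leaf rooted tree with literature-plausible neutral branch lengths
#' (substitutions per site): seven high-quality loss-search genomes (mouse,
#' rat, guinea pig, cow, horse, dog, elephant), two presence-only genomes
#' (kangaroo rat, rabbit) and three outgroups (opossum, platypus, chicken).
#'
#' @return list with `newick` and `roles` ready for [parse_tree()].
#' @export
default_study_tree <- function() {
  list(
    newick = paste0(
      "((((((mouse:0.35,rat:0.33)MR:0.06,kangaroo_rat:0.42)MRK:0.02,",
      "guinea_pig:0.23)ROD:0.02,rabbit:0.28)GLIRES:0.02,",
      "((cow:0.18,(dog:0.13,horse:0.12)DH:0.02)LAURA:0.02,",
      "elephant:0.11)BOREO:0.01)EUTH:0.10,",
      "((opossum:0.36,platypus:0.46)MARS:0.06,chicken:0.75)OUT:0.05)ROOT;"),
    roles = list(
      loss_search = c("mouse", "rat", "guinea_pig", "cow", "horse", "dog",
                      "elephant"),
      presence_only = c("kangaroo_rat", "rabbit"),
      outgroup = c("opossum", "platypus", "chicken"))
  )
}

#' Generator configuration
#'
#' Assembles and validates the configuration of the synthetic-data
#' generator. Defaults emulate the study conditions of the mammalian CNE
#' loss screen at desk scale: element lengths lognormal with median ~181 bp
#' and mean ~238 bp (truncated at 70 bp); per-branch loss probability
#' `base_rate` x branch length x per-CNE propensity, giving per-species
#' loss frequencies around 1%; deletion sizes lognormal with median
#' ~2.9 kb; low missing-data rates for the high-coverage loss-search
#' genomes and higher rates for presence-only genomes.
#'
#' @param seed mandatory RNG seed.
#' @param n_cnes number of CNEs (default 2000).
#' @param chrom_lengths named vector of reference chromosome lengths.
#' @param tree list with `newick` and `roles` (default
#'   [default_study_tree()]).
#' @param base_rate loss probability per unit branch length (default 0.05).
#' @param propensity list: `model` in `c("uniform","hotspot","gamma")` plus
#'   `fraction`/`fold` (hotspot) or `shape` (gamma). Default hotspot(10%,
#'   10x): a minority of weakly pleiotropic CNEs carries most losses.
#' @param trait_bias when TRUE (default) hotspot CNEs are generated
#'   shorter, less constrained and younger, emulating the pleiotropy-proxy
#'   trends.
#' @param missing_rate named vector of per-role missing-data rates.
#' @param len_meanlog,len_sdlog,len_min CNE length distribution.
#' @param del_meanlog,del_sdlog planted deletion-size distribution.
#' @param artifact_mix named probabilities of how a missing cell in a
#'   loss-search species is realized (`no_flank`, `not_cosyntenic`,
#'   `assembly_gap`, `similarity_hit`); must sum to 1.
#' @param correlated_missing when TRUE, missing data in each species hits
#'   contiguous runs of CNEs (whole-scaffold dropout) instead of
#'   independent cells.
#' @param trace_spanning_rate probability that a short loss region is
#'   covered by a spanning read (default 0.99).
#' @param neg_strand_rate fraction of query alignments on the minus strand.
#' @param n_genes number of coding genes for the TSS/ortholog tables.
#' @param gene_absence_rate,gene_gap_rate ortholog-table rates.
#' @return validated list of class `cne_sim_config`.
#' @export
sim_config <- function(seed,
                       n_cnes = 2000L,
                       chrom_lengths = c(chr1 = 6e7, chr2 = 4e7),
                       tree = default_study_tree(),
                       base_rate = 0.05,
                       propensity = list(model = "hotspot", fraction = 0.1,
                                         fold = 10),
                       trait_bias = TRUE,
                       missing_rate = c(loss_search = 0.02,
                                        presence_only = 0.12,
                                        outgroup = 0.06),
                       len_meanlog = log(181), len_sdlog = 0.74,
                       len_min = 70L,
                       del_meanlog = log(2870), del_sdlog = 1.26,
                       artifact_mix = c(no_flank = 0.35,
                                        not_cosyntenic = 0.2,
                                        assembly_gap = 0.3,
                                        similarity_hit = 0.15),
                       correlated_missing = FALSE,
                       trace_spanning_rate = 0.99,
                       neg_strand_rate = 0.2,
                       n_genes = NULL,
                       gene_absence_rate = 0.02,
                       gene_gap_rate = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cnes >= 1, base_rate >= 0,
            all(missing_rate >= 0 & missing_rate <= 1),
            abs(sum(artifact_mix) - 1) < 1e-9,
            trace_spanning_rate >= 0, trace_spanning_rate <= 1,
            neg_strand_rate >= 0, neg_strand_rate <= 1)
  if (propensity$model == "hotspot") {
    if (propensity$fraction <= 0 && propensity$fold > 1)
      stop("infeasible propensity: hotspot fraction 0 with fold > 1")
    stopifnot(propensity$fold >= 1, propensity$fraction >= 0,
              propensity$fraction <= 1)
  }
  if (is.null(n_genes)) n_genes <- max(50L, ceiling(n_cnes / 10))
  cfg <- list(seed = seed, n_cnes = as.integer(n_cnes),
              chrom_lengths = chrom_lengths, tree = tree,
              base_rate = base_rate, propensity = propensity,
              trait_bias = trait_bias, missing_rate = missing_rate,
              len_meanlog = len_meanlog, len_sdlog = len_sdlog,
              len_min = as.integer(len_min), del_meanlog = del_meanlog,
              del_sdlog = del_sdlog, artifact_mix = artifact_mix,
              correlated_missing = correlated_missing,
              trace_spanning_rate = trace_spanning_rate,
              neg_strand_rate = neg_strand_rate,
              n_genes = as.integer(n_genes),
              gene_absence_rate = gene_absence_rate,
              gene_gap_rate = gene_gap_rate)
  class(cfg) <- "cne_sim_config"
  cfg
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Produces every input the pipeline consumes -- CNE catalog with
#' annotations, per-species alignment evidence, assembly-gap and
#' similarity-hit tables, trace-read placements, TSS and ortholog tables,
#' and the parsed tree -- together with a `truth` component recording the
#' planted per-CNE loss branches, propensities, deletion sizes, missing
#' masks and artifact labels. Re-running the detection and inference stages
#' on a bundle with zero artifacts reproduces the planted statuses and
#' events exactly; byte-identical output for a fixed config.
#'
#' @param config a `cne_sim_config` from [sim_config()].
#' @return object of class `cne_sim`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "cne_sim_config"))
  set.seed(config$seed)
  tree <- parse_tree(config$tree$newick, config$tree$roles)
  tips <- tree$ape$tip.label
  n <- config$n_cnes

  # --- catalog --------------------------------------------------------
  hot <- switch(config$propensity$model,
                uniform = rep(FALSE, n),
                hotspot = runif(n) < config$propensity$fraction,
                gamma = rep(FALSE, n))
  # propensity is a relative weight with expectation 1, so base_rate x
  # branch length stays the marginal per-branch loss probability under
  # every propensity model
  propensity <- switch(config$propensity$model,
                       uniform = rep(1, n),
                       hotspot = ifelse(hot, config$propensity$fold, 1) /
                         (1 + config$propensity$fraction *
                            (config$propensity$fold - 1)),
                       gamma = stats::rgamma(n, shape = config$propensity$shape,
                                             rate = config$propensity$shape))
  bias <- config$trait_bias & hot
  len <- round(rlnorm(n, config$len_meanlog + ifelse(bias, log(0.6), 0),
                      config$len_sdlog))
  len <- pmax(len, config$len_min)
  rs <- stats::rbeta(n, ifelse(bias, 3.2, 4.2), 5.8)
  phylop_p <- 10^-runif(n, 5, 40)
  ancestry <- runif(n) < ifelse(bias, 0.15, 0.25)

  glen <- config$chrom_lengths
  chrom <- sample(names(glen), n, replace = TRUE, prob = glen / sum(glen))
  pos <- floor(runif(n, 2e4, glen[chrom] - 2e4))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; len <- len[ord]
  propensity <- propensity[ord]; hot <- hot[ord]; rs <- rs[ord]
  phylop_p <- phylop_p[ord]; ancestry <- ancestry[ord]
  ids <- sprintf("cne%05d", seq_len(n))
  cnes <- data.frame(id = ids, chrom = chrom, start = pos, end = pos + len,
                     length = len, constraint_rs = rs, phylop_p = phylop_p,
                     ancestry_pre_mammal = ancestry,
                     stringsAsFactors = FALSE)

  # --- missing mask ---------------------------------------------------
  miss <- matrix(FALSE, n, length(tips), dimnames = list(ids, tips))
  for (s in tips) {
    rate <- config$missing_rate[[tree$leaf_roles[[s]]]]
    if (rate <= 0) next
    if (config$correlated_missing) {
      run <- max(5L, round(n / 50))
      n_runs <- stats::rbinom(1, ceiling(n * rate / run) * 2, 0.5)
      if (n_runs > 0) for (r in seq_len(n_runs)) {
        a <- sample.int(n, 1L)
        miss[a:min(n, a + run - 1L), s] <- TRUE
      }
    } else miss[, s] <- runif(n) < rate
  }
  og <- tips[tree$leaf_roles == "outgroup"]
  all_og_missing <- rowSums(!miss[, og, drop = FALSE]) == 0
  if (any(all_og_missing))  # catalog guarantees a conserved outgroup
    miss[all_og_missing, sample(og, 1L)] <- FALSE

  # --- planted loss events -------------------------------------------
  elig <- .eligibility_mats(miss, tree)
  br_ids <- tree$capable
  br_names <- tree$labels[br_ids]
  bl <- tree$branch_length[br_ids]
  leaves <- tree$leaves_below[br_ids]
  leaves_par <- lapply(br_ids, function(a) tree$leaves_below[[tree$parent[a]]])
  p_evt <- outer(propensity, config$base_rate * bl)  # n x nB
  p_evt <- pmin(p_evt, 0.9)
  drawn <- matrix(runif(n * length(br_ids)), n) < p_evt

  events_by_cne <- vector("list", n)
  names(events_by_cne) <- ids
  lost_leaf <- matrix(FALSE, n, length(tips), dimnames = list(ids, tips))
  for (i in which(rowSums(drawn) > 0)) {
    S <- integer(0)
    for (a in which(drawn[i, ])) {
      if (!elig$solo_ok[i, a]) next
      lv <- leaves[[a]]
      if (any(lost_leaf[i, lv])) next          # overlaps an accepted event
      lm <- lost_leaf[i, ] | miss[i, ]
      lm[lv] <- TRUE
      ok <- TRUE
      for (b in c(S, a)) if (all(lm[leaves_par[[b]]])) { ok <- FALSE; break }
      if (!ok) next                             # would merge under parsimony
      S <- c(S, a)
      lost_leaf[i, lv] <- TRUE
    }
    if (length(S)) events_by_cne[[i]] <- sort(br_names[S])
  }
  per_branch <- table(factor(unlist(events_by_cne), levels = sort(br_names)))

  # deletion size per (cne, event); shared by all species below the branch
  ev_tab <- data.frame(
    cne_id = rep(ids, lengths(events_by_cne)),
    branch = unlist(events_by_cne) %||% character(0),
    stringsAsFactors = FALSE)
  if (nrow(ev_tab)) {
    ev_len <- cnes$length[match(ev_tab$cne_id, ids)]
    ev_tab$deletion <- pmax(round(rlnorm(nrow(ev_tab), config$del_meanlog,
                                         config$del_sdlog)), ev_len + 20)
  } else ev_tab$deletion <- numeric(0)

  # --- truth status matrix -------------------------------------------
  status <- matrix(STATUS_CONSERVED, n, length(tips),
                   dimnames = list(ids, tips))
  status[miss] <- STATUS_MISSING
  status[lost_leaf] <- STATUS_LOST

  # artifact kind for missing loss-search cells
  kinds <- names(config$artifact_mix)
  artifact <- matrix(NA_character_, n, length(tips),
                     dimnames = list(ids, tips))
  for (s in tips) {
    mcol <- which(miss[, s])
    if (!length(mcol)) next
    artifact[mcol, s] <- if (tree$leaf_roles[[s]] == "loss_search")
      sample(kinds, length(mcol), replace = TRUE,
             prob = config$artifact_mix) else "low_coverage_species"
  }

  # --- evidence, gaps, hits, traces ----------------------------------
  emitted <- .emit_evidence(cnes, status, artifact, ev_tab, tree, config)

  # --- genes ----------------------------------------------------------
  gid <- sprintf("gene%04d", seq_len(config$n_genes))
  gchrom <- sample(names(glen), config$n_genes, replace = TRUE,
                   prob = glen / sum(glen))
  gpos <- floor(runif(config$n_genes, 1e4, glen[gchrom] - 1e4))
  tss <- data.frame(chrom = gchrom, pos = gpos, gene = gid,
                    strand = sample(c("+", "-"), config$n_genes, TRUE),
                    stringsAsFactors = FALSE)
  tss <- tss[order(tss$chrom, tss$pos), , drop = FALSE]
  rownames(tss) <- NULL
  ls_sp <- tips[tree$leaf_roles == "loss_search"]
  orth <- expand.grid(gene = gid, species = ls_sp,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- runif(nrow(orth))
  orth$status <- ifelse(u < config$gene_absence_rate, "absent",
                        ifelse(u < config$gene_absence_rate +
                                 config$gene_gap_rate, "gap", "present"))

  truth <- list(status = status,
                events_by_cne = Filter(Negate(is.null), events_by_cne),
                per_branch = per_branch,
                deletions = ev_tab,
                propensity = setNames(propensity, ids),
                hotspot = setNames(hot, ids),
                missing = miss,
                artifact = artifact)
  out <- list(tree = tree, cnes = cnes, evidence = emitted$evidence,
              gaps = emitted$gaps, hits = emitted$hits,
              traces = emitted$traces, tss = tss, orthologs = orth,
              truth = truth, config = config)
  class(out) <- "cne_sim"
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# vectorized per-species emission of evidence rows and side tables
.emit_evidence <- function(cnes, status, artifact, ev_tab, tree, config) {
  tips <- tree$ape$tip.label
  ids <- cnes$id
  flankw <- 100L
  ev_rows <- list(); gap_rows <- list(); hit_rows <- list()
  trace_rows <- list()
  for (s in tips) {
    st <- status[, s]
    art <- artifact[, s]
    emit <- st == STATUS_CONSERVED | st == STATUS_LOST |
      (!is.na(art) & art %in% c("not_cosyntenic", "assembly_gap",
                                "similarity_hit"))
    idx <- which(emit)
    if (!length(idx)) next
    m <- length(idx)
    len <- cnes$length[idx]
    lost <- st[idx] == STATUS_LOST
    kind <- art[idx]

    # deletion of the event this species belongs to (lost cells only)
    D <- rep(NA_real_, m)
    if (any(lost) && nrow(ev_tab)) {
      below <- vapply(.node_id(tree, ev_tab$branch), function(v)
        s %in% tips[tree$leaves_below[[v]]], logical(1))
      evs <- ev_tab[below, , drop = FALSE]
      D[lost] <- evs$deletion[match(ids[idx][lost], evs$cne_id)]
    }

    q_dist <- ifelse(lost | (!is.na(kind) &
                               kind %in% c("assembly_gap", "not_cosyntenic")),
                     round(runif(m, 50, 450)), NA)
    ref_dist <- ifelse(lost, D + q_dist, len + 100)
    q_dist[is.na(q_dist)] <- ref_dist[is.na(q_dist)]  # conserved: identical
    extra <- ref_dist - len
    u <- ifelse(lost, runif(m, 0.3, 0.7), 0.5)
    pad_up <- round(extra * u)
    pad_down <- extra - pad_up

    up_ref_end <- cnes$start[idx] - pad_up
    up_ref_start <- up_ref_end - flankw
    down_ref_start <- cnes$end[idx] + pad_down
    down_ref_end <- down_ref_start + flankw

    scaf <- paste0(s, "_", cnes$chrom[idx])
    strand <- ifelse(runif(m) < config$neg_strand_rate, "-", "+")
    block <- 2L * flankw + q_dist + 1000
    o <- order(scaf)
    cur <- numeric(m)
    cur[o] <- unlist(lapply(split(block[o], scaf[o]), function(b)
      cumsum(c(0, b[-length(b)]))), use.names = FALSE)
    # plus strand: up block, inter-flank, down block; minus: reversed
    plus <- strand == "+"
    up_q_start <- ifelse(plus, cur, cur + flankw + q_dist)
    up_q_end <- up_q_start + flankw
    down_q_start <- ifelse(plus, cur + flankw + q_dist, cur)
    down_q_end <- down_q_start + flankw
    if_start <- ifelse(plus, up_q_end, down_q_end)
    if_end <- if_start + q_dist

    overlap <- ifelse(st[idx] == STATUS_CONSERVED, len, 0)
    # not_cosyntenic: down flank lands on a different scaffold
    down_scaf <- ifelse(!is.na(kind) & kind == "not_cosyntenic",
                        paste0(scaf, "_alt"), scaf)
    ev_rows[[s]] <- data.frame(
      cne_id = ids[idx], species = s, ref_chrom = cnes$chrom[idx],
      up_ref_start = up_ref_start, up_ref_end = up_ref_end,
      down_ref_start = down_ref_start, down_ref_end = down_ref_end,
      up_scaffold = scaf, down_scaffold = down_scaf,
      up_q_start = up_q_start, up_q_end = up_q_end,
      down_q_start = down_q_start, down_q_end = down_q_end,
      strand = strand, cne_overlap_bp = overlap, stringsAsFactors = FALSE)

    gapc <- !is.na(kind) & kind == "assembly_gap"
    if (any(gapc)) {
      gs <- if_start[gapc] + pmax(10, floor(q_dist[gapc] / 3))
      gap_rows[[s]] <- data.frame(
        species = s, scaffold = scaf[gapc], start = gs,
        end = gs + pmax(10, floor(q_dist[gapc] / 3)),
        stringsAsFactors = FALSE)
    }
    simc <- !is.na(kind) & kind == "similarity_hit"
    if (any(simc))
      hit_rows[[s]] <- data.frame(cne_id = ids[idx][simc], species = s,
                                  source = "trace", score = 100,
                                  stringsAsFactors = FALSE)

    short <- lost & q_dist < 500
    if (any(short)) {
      span <- runif(sum(short)) < config$trace_spanning_rate
      ss <- if_start[short]; se <- if_end[short]; sc <- scaf[short]
      tr <- list()
      if (any(span))
        tr[[1]] <- data.frame(species = s, scaffold = sc[span],
                              start = ss[span] - 60, end = se[span] + 60,
                              stringsAsFactors = FALSE)
      if (any(!span)) {
        mid <- floor((ss[!span] + se[!span]) / 2)
        tr[[2]] <- data.frame(
          species = s, scaffold = rep(sc[!span], 2),
          start = c(ss[!span] - 60, mid),
          end = c(mid, se[!span] + 60), stringsAsFactors = FALSE)
      }
      trace_rows[[s]] <- do.call(rbind, tr)
    }
  }
  empty_gap <- data.frame(species = character(0), scaffold = character(0),
                          start = numeric(0), end = numeric(0))
  list(evidence = do.call(rbind, c(ev_rows, list(NULL))),
       gaps = if (length(gap_rows)) do.call(rbind, gap_rows) else empty_gap,
       hits = if (length(hit_rows)) do.call(rbind, hit_rows) else
         data.frame(cne_id = character(0), species = character(0),
                    source = character(0), score = numeric(0)),
       traces = if (length(trace_rows)) do.call(rbind, trace_rows) else
         empty_gap)
}

#' @export
print.cne_sim <- function(x, ...) {
  cat("Synthetic CNE-loss dataset: ", nrow(x$cnes), " CNEs, ",
      length(x$truth$events_by_cne), " CNEs with planted losses (",
      sum(lengths(x$truth$events_by_cne)), " events)\n", sep = "")
  cat("  propensity model: ", x$config$propensity$model, "; seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Deterministic labeled artifact fixtures
#'
#' A miniature bundle with one CNE per detection outcome: a clean loss, a
#' conserved element, an assembly-gap mimic, a translocated element with a
#' trace similarity hit, a loss candidate with an absent flank, one with
#' non-co-syntenic flanks, and an absence in a presence-only (low-coverage)
#' genome. The `truth` table gives the expected status and reason code of
#' the focal cell of each case.
#'
#' @return list with `cnes`, `evidence`, `gaps`, `hits`, `tree` and `truth`
#'   (`cne_id`, `species`, `expected_status`, `expected_reason`, `case`).
#' @export
emit_artifact_cases <- function() {
  tt <- default_study_tree()
  tree <- parse_tree(tt$newick, tt$roles)
  ids <- sprintf("art%02d", 1:7)
  cnes <- data.frame(id = ids, chrom = "chr1",
                     start = seq(10000, by = 10000, length.out = 7))
  cnes$end <- cnes$start + 100L
  cnes$length <- 100L
  cases <- c("clean_loss", "conserved", "assembly_gap", "similarity_hit",
             "no_flank", "not_cosyntenic", "low_coverage")
  focal <- c("mouse", "mouse", "mouse", "mouse", "mouse", "mouse",
             "kangaroo_rat")

  base_row <- function(id, sp, overlap = 0, down_scaf_alt = FALSE,
                       drop_down = FALSE) {
    r <- data.frame(
      cne_id = id, species = sp, ref_chrom = "chr1",
      up_ref_start = 0, up_ref_end = 100, down_ref_start = 300,
      down_ref_end = 400,
      up_scaffold = paste0(sp, "_s1"),
      down_scaffold = if (down_scaf_alt) paste0(sp, "_s2") else
        paste0(sp, "_s1"),
      up_q_start = 1000, up_q_end = 1100, down_q_start = 1300,
      down_q_end = 1400, strand = "+", cne_overlap_bp = overlap,
      stringsAsFactors = FALSE)
    if (drop_down) r[c("down_q_start", "down_q_end")] <- NA_real_
    r
  }
  ev <- rbind(
    base_row("art01", "mouse"),
    base_row("art02", "mouse", overlap = 100),
    base_row("art03", "mouse"),
    base_row("art04", "mouse"),
    base_row("art05", "mouse", drop_down = TRUE),
    base_row("art06", "mouse", down_scaf_alt = TRUE))
  # all cases conserved in every other species so the outgroup requirement
  # holds and mouse is the only informative cell
  others <- setdiff(tree$ape$tip.label, "mouse")
  for (sp in others) {
    keep <- if (sp == "kangaroo_rat") setdiff(ids, "art07") else ids
    ev <- rbind(ev, do.call(rbind, lapply(keep, function(id)
      base_row(id, sp, overlap = 100))))
  }
  ev <- rbind(ev, base_row("art07", "mouse", overlap = 100))

  gaps <- data.frame(species = "mouse", scaffold = "mouse_s1",
                     start = 1150, end = 1180, stringsAsFactors = FALSE)
  # the gap interval intersects only art03's inter-flank region: give the
  # other mouse rows distinct scaffolds
  ev$up_scaffold[ev$species == "mouse"] <-
    paste0("mouse_s_", ev$cne_id[ev$species == "mouse"])
  ev$down_scaffold[ev$species == "mouse" &
                     ev$cne_id != "art06"] <-
    ev$up_scaffold[ev$species == "mouse" & ev$cne_id != "art06"]
  gaps$scaffold <- "mouse_s_art03"

  hits <- data.frame(cne_id = "art04", species = "mouse", source = "trace",
                     score = 120, stringsAsFactors = FALSE)
  truth <- data.frame(
    cne_id = ids, species = focal, case = cases,
    expected_status = c("LOST", "CONSERVED", "MISSING", "MISSING",
                        "MISSING", "MISSING", "MISSING"),
    expected_reason = c(NA, NA, "assembly_gap", "similarity_hit",
                        "no_flank", "not_cosyntenic",
                        "low_coverage_species"),
    stringsAsFactors = FALSE)
  list(cnes = cnes, evidence = ev, gaps = gaps, hits = hits, tree = tree,
       truth = truth)
}
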