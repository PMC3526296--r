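# Loss frequencies, eligibility denominators, exact expected independent
# losses under uniformity, and the constrained Monte-Carlo reassignment null.

.status_mats <- function(status, tree) {
  if (inherits(status, "cne_status")) status <- status$status
  tips <- tree$ape$tip.label
  if (!all(tips %in% colnames(status)))
    stop("status matrix must have one column per tree leaf")
  status <- status[, tips, drop = FALSE]
  list(status = status,
       lost = status == STATUS_LOST,
       cons = status == STATUS_CONSERVED,
       miss = status == STATUS_MISSING)
}

#' Infer loss events for every CNE in a status matrix
#'
#' Runs the missing-data parsimony inference ([infer_loss_branches()]) across
#' all CNEs and returns the observed loss events as an ordered event list:
#' one row per (CNE, loss branch), sorted by the depth of the node in which
#' the loss branch ends (ascending, root depth 0), then branch name, then
#' input order. This ordering reflects the relative evolutionary order of
#' the losses and is the order in which the reassignment simulation places
#' events.
#'
#' @param status a `cne_status` object or a character matrix CNE x species.
#' @param tree a `cne_phylo`.
#' @param rule tie rule passed to the parsimony inference.
#' @return data.frame of class `cne_events`: `cne_id`, `branch`, `depth`,
#'   with attribute `by_cne` (list of branch-name sets per CNE).
#' @export
infer_events <- function(status, tree, rule = "ancestral") {
  m <- .status_mats(status, tree)
  sets <- .infer_batch(tree, m$lost, m$cons, rule)
  ids <- rownames(m$status)
  k <- lengths(sets)
  ev <- data.frame(
    cne_id = rep(ids, k),
    branch = tree$labels[unlist(sets)],
    stringsAsFactors = FALSE)
  ev$depth <- tree$depth[.node_id(tree, ev$branch)]
  ev <- ev[order(ev$depth, ev$branch, seq_len(nrow(ev))), , drop = FALSE]
  rownames(ev) <- NULL
  by_cne <- lapply(sets, function(s) sort(tree$labels[s]))
  names(by_cne) <- ids
  attr(ev, "by_cne") <- by_cne
  class(ev) <- c("cne_events", "data.frame")
  ev
}

# Per-CNE eligibility primitives. Returns, for the capable branches of the
# tree, logical matrices over CNEs:
#   no_miss_below[i, a]: CNE i has no MISSING leaf below branch a
#   solo_ok[i, a]: a single loss on branch a would be re-inferred exactly
#     (additionally requires a non-missing leaf below a's parent outside a)
.eligibility_mats <- function(miss, tree) {
  br <- tree$capable
  nB <- length(br)
  n <- nrow(miss)
  no_miss <- matrix(TRUE, n, nB)
  solo <- matrix(FALSE, n, nB)
  for (j in seq_len(nB)) {
    a <- br[j]
    lv <- tree$leaves_below[[a]]
    no_miss[, j] <- rowSums(miss[, lv, drop = FALSE]) == 0
    sep <- setdiff(tree$leaves_below[[tree$parent[a]]], lv)
    if (length(sep))
      solo[, j] <- no_miss[, j] &
        rowSums(!miss[, sep, drop = FALSE]) > 0
  }
  colnames(no_miss) <- colnames(solo) <- tree$labels[br]
  list(no_miss_below = no_miss, solo_ok = solo)
}

# Vectorized validity of one combination across all CNEs' missing sets.
# Valid iff no missing leaf below any branch of the combo and, for each
# branch, a non-missing leaf exists below its parent outside the combo
# (that leaf is CONSERVED under the combo labeling, which makes each branch
# a maximal lost-or-missing clade and re-inference exact).
.combo_eligible <- function(combo_ids, miss, tree) {
  below <- unique(unlist(tree$leaves_below[combo_ids]))
  ok <- rowSums(miss[, below, drop = FALSE]) == 0
  for (a in combo_ids) {
    sep <- setdiff(tree$leaves_below[[tree$parent[a]]], below)
    if (!length(sep)) return(rep(FALSE, nrow(miss)))
    ok <- ok & rowSums(!miss[, sep, drop = FALSE]) > 0
  }
  ok
}

#' Per-branch loss counts, eligibility denominators and loss frequencies
#'
#' For every loss-search-capable branch A computes the observed number of
#' loss events L_A, the number of CNEs with the potential to have an
#' inferable loss on A given their missing data (N_A: the singleton
#' combination \{A\} is valid for the CNE -- no MISSING leaf below A and a
#' non-missing separator leaf below A's parent, so that parsimony would
#' place the loss on A itself), and the loss frequency f_A = L_A / N_A. For every valid independent combination of k = 2 (and,
#' optionally, 3) branches, computes the joint eligibility N_c (the CNEs for
#' which the combination is valid given their missing data, via
#' [is_valid_combination()] semantics) and the observed count O_c of CNEs
#' whose inferred loss-branch set is exactly that combination.
#'
#' @param status a `cne_status` or character status matrix.
#' @param tree a `cne_phylo`.
#' @param k multiplicities for which combination tables are built.
#' @param rule parsimony tie rule.
#' @return object of class `cne_branch_stats`: list with `branches`
#'   (data.frame `branch`, `L`, `N`, `f`, `length`, `depth`), `combos`
#'   (named list "2"/"3" of data.frames `combo`, `N_c`, `O_c` and the
#'   member branches), `events`, and `n_cnes`.
#' @export
eligibility_counts <- function(status, tree, k = c(2L, 3L),
                               rule = "ancestral") {
  m <- .status_mats(status, tree)
  ev <- infer_events(m$status, tree, rule = rule)
  by_cne <- attr(ev, "by_cne")
  elig <- .eligibility_mats(m$miss, tree)

  br_ids <- tree$capable
  br_names <- tree$labels[br_ids]
  L <- table(factor(ev$branch, levels = br_names))
  off_capable <- setdiff(unique(ev$branch), br_names)
  if (length(off_capable))
    warning("loss events inferred on non-capable branches (missing-data ",
            "artifacts) are excluded from the frequency tables: ",
            paste(off_capable, collapse = ", "))
  N <- colSums(elig$solo_ok)
  f <- ifelse(N > 0, as.numeric(L) / N, NA_real_)
  branches <- data.frame(
    branch = br_names, L = as.integer(L), N = as.integer(N), f = f,
    length = tree$branch_length[br_ids], depth = tree$depth[br_ids],
    stringsAsFactors = FALSE)

  key <- vapply(by_cne, paste, character(1), collapse = "+")
  combos <- list()
  for (kk in intersect(k, 2:3)) {
    cc <- enumerate_valid_combinations(tree, kk)
    if (!length(cc)) {
      combos[[as.character(kk)]] <- data.frame(combo = character(0),
                                               N_c = integer(0),
                                               O_c = integer(0))
      next
    }
    tab <- do.call(rbind, lapply(cc, function(co) {
      ids <- .node_id(tree, co)
      data.frame(combo = paste(sort(co), collapse = "+"),
                 N_c = sum(.combo_eligible(ids, m$miss, tree)),
                 O_c = sum(key == paste(sort(co), collapse = "+")),
                 stringsAsFactors = FALSE)
    }))
    combos[[as.character(kk)]] <- tab[order(tab$combo), , drop = FALSE]
  }
  out <- list(branches = branches, combos = combos, events = ev,
              n_cnes = nrow(m$status), rule = rule)
  class(out) <- "cne_branch_stats"
  out
}

#' @export
print.cne_branch_stats <- function(x, ...) {
  cat("Per-branch CNE loss statistics (", x$n_cnes, " CNEs, ",
      nrow(x$events), " loss events)\n", sep = "")
  print(x$branches, row.names = FALSE)
  invisible(x)
}

#' Exact expected number of independent CNE losses under uniformity
#'
#' Under the null model that losses strike eligible CNEs uniformly at
#' random, the expected number of CNEs independently lost in branches A and
#' B is f_A * f_B * N_AB, where N_AB counts CNEs eligible for a joint
#' independent loss in A and B. Summing over all valid independent lineage
#' combinations gives the total expectation E_2; E_3 is computed analogously
#' over valid triples.
#'
#' @param stats a `cne_branch_stats` from [eligibility_counts()].
#' @param k 2 or 3.
#' @return list with `E` (the expectation) and `per_combo` (data.frame with
#'   the per-combination expected counts).
#' @export
expected_independent <- function(stats, k) {
  stopifnot(inherits(stats, "cne_branch_stats"), k %in% c(2L, 3L))
  tab <- stats$combos[[as.character(k)]]
  if (is.null(tab)) stop("combination table for k=", k, " not computed")
  b <- stats$branches
  bad <- b$branch[b$N == 0 & b$L > 0]
  if (length(bad))
    stop("loss frequency undefined (N=0, L>0) for branch: ",
         paste(bad, collapse = ", "))
  fmap <- setNames(ifelse(is.na(b$f), 0, b$f), b$branch)
  if (nrow(tab) == 0L)
    return(list(E = 0, per_combo = cbind(tab, expected = numeric(0))))
  prods <- vapply(strsplit(tab$combo, "+", fixed = TRUE),
                  function(bs) prod(fmap[bs]), numeric(1))
  tab$expected <- prods * tab$N_c
  list(E = sum(tab$expected), per_combo = tab)
}

#' Constrained Monte-Carlo reassignment simulation of CNE losses
#'
#' Simulates the null hypothesis of uniform loss frequencies while holding
#' fixed the observed number and identity of loss events per branch. Each
#' iteration starts with all (CNE, species) labels conserved, sorts the
#' observed loss events by depth of the node the loss branch ends in
#' (ascending; root has depth 0 -- deeper events happened later), and
#' assigns each event to a uniformly drawn CNE, rejecting draws that are
#' invalid because (1) the CNE already carries a lost label for a species of
#' the event, (2) the event conflicts with the CNE's missing data, or (3)
#' parsimony would re-infer a different loss branch (e.g. a mouse loss
#' followed by a rat loss on the same CNE merges into a single mouse-rat
#' ancestor loss). By design every iteration reproduces exactly the input
#' loss branches; after assignment the number of CNEs with 2, 3 and 4+
#' independent losses is recorded, in total and per lineage combination.
#'
#' After `max_reject` uniform draws for one event, the valid CNEs are
#' enumerated exactly and the event is placed uniformly among them, which
#' guarantees termination without biasing the distribution.
#'
#' @param events a `cne_events` data.frame (from [infer_events()]) or NULL to
#'   derive it from `status`.
#' @param status a `cne_status` or character status matrix (supplies the
#'   missing-data masks and the CNE universe).
#' @param tree a `cne_phylo`.
#' @param iterations number of simulation iterations (default 10000).
#' @param seed integer seed; each iteration derives its own substream so
#'   results are stable regardless of execution order.
#' @param order event ordering: `"depth"` (relative evolutionary order,
#'   default), `"reverse"`, or `"random"` (reshuffled each iteration).
#' @param max_reject uniform-proposal rejections per event before exact
#'   enumeration (default 1000).
#' @param rule parsimony tie rule.
#' @param verify when TRUE (default) every iteration re-infers the loss
#'   branches of all CNEs that received events and asserts they equal the
#'   assigned sets (hard conservation check).
#' @return object of class `cne_null_sim`: list with `dist` (data.frame with
#'   one row per iteration: `n2`, `n3`, `n4plus` CNEs with exactly 2/3/4+
#'   losses, `n_indep`, `pairs`, `triples` pair/triple incidences),
#'   `combos2` (per-pair-combination simulated mean and max), `iterations`,
#'   `seed`, `order`, `n_events`.
#' @export
simulate_null <- function(events = NULL, status, tree, iterations = 10000L,
                          seed = NULL, order = c("depth", "reverse", "random"),
                          max_reject = 1000L, rule = "ancestral",
                          verify = TRUE) {
  order <- match.arg(order)
  m <- .status_mats(status, tree)
  if (is.null(events)) events <- infer_events(m$status, tree, rule = rule)
  nC <- nrow(m$status)
  if (nrow(events) == 0L)
    stop("no loss events to simulate")

  br_ids <- tree$capable
  br_names <- tree$labels[br_ids]
  ev_col <- match(events$branch, br_names)
  if (anyNA(ev_col))
    stop("event on a branch that is not loss-search capable: ",
         paste(unique(events$branch[is.na(ev_col)]), collapse = ", "))
  elig <- .eligibility_mats(m$miss, tree)
  solo_ok <- elig$solo_ok
  no_miss <- elig$no_miss_below
  leaves <- tree$leaves_below[br_ids]
  leaves_par <- lapply(br_ids, function(a) tree$leaves_below[[tree$parent[a]]])
  miss <- m$miss
  n_tip <- tree$n_tip

  depth_ord <- order(events$depth, events$branch, seq_len(nrow(events)))
  base_ord <- switch(order, depth = depth_ord, reverse = rev(depth_ord),
                     random = depth_ord)
  nE <- nrow(events)
  for (j in seq_along(br_names)) {
    if (any(ev_col == j) && !any(solo_ok[, j]))
      stop("event on branch ", br_names[j], " has zero valid CNEs")
  }

  if (!is.null(seed)) set.seed(seed)
  iter_seeds <- sample.int(2147483646L, iterations)

  dist <- matrix(0L, iterations, 6L,
                 dimnames = list(NULL, c("n2", "n3", "n4plus", "n_indep",
                                         "pairs", "triples")))
  combo_sum <- new.env(hash = TRUE, parent = emptyenv())
  combo_max <- new.env(hash = TRUE, parent = emptyenv())

  ev_lists <- vector("list", nC)
  lostM <- matrix(FALSE, nC, n_tip)
  per_branch_input <- tabulate(ev_col, nbins = length(br_names))

  for (it in seq_len(iterations)) {
    set.seed(iter_seeds[it])
    this_ord <- if (order == "random") sample(base_ord) else base_ord
    touched <- integer(0)
    for (e in this_ord) {
      a <- ev_col[e]
      lv <- leaves[[a]]
      tries <- 0L
      repeat {
        cne <- sample.int(nC, 1L)
        evs <- ev_lists[[cne]]
        if (is.null(evs)) {
          ok <- solo_ok[cne, a]
        } else {
          ok <- !any(lostM[cne, lv]) && no_miss[cne, a]
          if (ok) {
            lm <- lostM[cne, ] | miss[cne, ]
            lm[lv] <- TRUE
            for (b in c(evs, a)) {
              if (all(lm[leaves_par[[b]]])) { ok <- FALSE; break }
            }
          }
        }
        if (ok) break
        tries <- tries + 1L
        if (tries > max_reject) {
          cand <- .enumerate_valid_cnes(a, lv, ev_lists, lostM, miss, solo_ok,
                                        no_miss, leaves_par, touched)
          if (!length(cand))
            stop("event on branch ", br_names[a],
                 " has no valid CNE in this iteration")
          cne <- cand[sample.int(length(cand), 1L)]
          break
        }
      }
      if (is.null(ev_lists[[cne]])) touched <- c(touched, cne)
      ev_lists[[cne]] <- c(ev_lists[[cne]], a)
      lostM[cne, lv] <- TRUE
    }

    ks <- lengths(ev_lists[touched])
    stopifnot(sum(ks) == nE)
    per_branch_now <- tabulate(unlist(ev_lists[touched]),
                               nbins = length(br_names))
    stopifnot(identical(per_branch_now, per_branch_input))
    dist[it, "n2"] <- sum(ks == 2L)
    dist[it, "n3"] <- sum(ks == 3L)
    dist[it, "n4plus"] <- sum(ks >= 4L)
    dist[it, "n_indep"] <- sum(ks >= 2L)
    dist[it, "pairs"] <- sum(choose(ks, 2L))
    dist[it, "triples"] <- sum(choose(ks, 3L))

    for (cne in touched[ks == 2L]) {
      keyc <- paste(sort(br_names[ev_lists[[cne]]]), collapse = "+")
      combo_sum[[keyc]] <- (if (is.null(combo_sum[[keyc]])) 0 else
        combo_sum[[keyc]]) + 1
      prev <- if (is.null(combo_max[[keyc]])) 0 else combo_max[[keyc]]
      combo_max[[keyc]] <- max(prev, 1)
    }
    # per-iteration multiplicity per combo for the max statistic
    if (any(ks == 2L)) {
      keys <- vapply(touched[ks == 2L], function(cne)
        paste(sort(br_names[ev_lists[[cne]]]), collapse = "+"), character(1))
      tt <- table(keys)
      for (keyc in names(tt))
        combo_max[[keyc]] <- max(combo_max[[keyc]], as.integer(tt[[keyc]]))
    }

    if (verify && length(touched)) {
      lost_sub <- lostM[touched, , drop = FALSE]
      cons_sub <- !(lost_sub | miss[touched, , drop = FALSE])
      reinf <- .infer_batch(tree, lost_sub, cons_sub, rule)
      assigned <- lapply(ev_lists[touched], function(x) sort(br_ids[x]))
      if (!all(mapply(function(x, y) identical(sort(x), y), reinf, assigned)))
        stop("conservation violation: re-inference differs from assigned events")
    }

    # reset state
    for (cne in touched) {
      lostM[cne, ] <- FALSE
      ev_lists[cne] <- list(NULL)
    }
  }

  keys <- sort(ls(combo_sum))
  combos2 <- data.frame(
    combo = keys,
    sim_mean = vapply(keys, function(k0) combo_sum[[k0]] / iterations,
                      numeric(1)),
    sim_max = vapply(keys, function(k0) combo_max[[k0]], numeric(1)),
    stringsAsFactors = FALSE)
  rownames(combos2) <- NULL

  out <- list(dist = as.data.frame(dist), combos2 = combos2,
              iterations = iterations, seed = seed, order = order,
              n_events = nE,
              per_branch = setNames(per_branch_input, br_names))
  class(out) <- "cne_null_sim"
  out
}

# exact enumeration of CNEs valid for an event on branch column `a`
.enumerate_valid_cnes <- function(a, lv, ev_lists, lostM, miss, solo_ok,
                                  no_miss, leaves_par, touched) {
  ok <- solo_ok[, a]
  ok[touched] <- FALSE
  cand <- which(ok)
  for (cne in touched) {
    evs <- ev_lists[[cne]]
    good <- !any(lostM[cne, lv]) && no_miss[cne, a]
    if (good) {
      lm <- lostM[cne, ] | miss[cne, ]
      lm[lv] <- TRUE
      for (b in c(evs, a)) if (all(lm[leaves_par[[b]]])) { good <- FALSE; break }
    }
    if (good) cand <- c(cand, cne)
  }
  cand
}

#' @export
print.cne_null_sim <- function(x, ...) {
  cat("Constrained loss-reassignment simulation: ", x$iterations,
      " iterations, ", x$n_events, " events (order: ", x$order, ")\n",
      sep = "")
  cat("CNEs lost twice:  mean ", round(mean(x$dist$n2), 2), ", max ",
      max(x$dist$n2), "\n", sep = "")
  cat("CNEs lost 3 times: mean ", round(mean(x$dist$n3), 3), ", max ",
      max(x$dist$n3), "\n", sep = "")
  invisible(x)
}

#' Summarize an observed count against a simulated null distribution
#'
#' Computes the z-score (standard deviations above the simulation average)
#' and the add-one empirical P-value
#' P = (1 + #\{simulated >= observed\}) / (1 + iterations). With 10,000
#' iterations and no exceedance this reports P = 1/10001 (< 1e-4).
#'
#' @param observed observed count.
#' @param dist numeric vector of simulated counts.
#' @return list `observed`, `mean`, `sd`, `z` (NA with `degenerate = TRUE`
#'   when the simulation variance is zero), `p`, `n`.
#' @export
summarize_null <- function(observed, dist) {
  stopifnot(length(dist) >= 1)
  mu <- mean(dist)
  s <- sd(dist)
  degenerate <- is.na(s) || s == 0
  z <- if (degenerate) NA_real_ else (observed - mu) / s
  p <- (1 + sum(dist >= observed)) / (1 + length(dist))
  list(observed = observed, mean = mu, sd = s, z = z, p = p,
       n = length(dist), degenerate = degenerate)
}

#' Correlation of loss frequency with branch length
#'
#' Tests whether per-branch CNE loss frequencies f_A scale with the neutral
#' branch length, measured as the summed branch length from a common
#' ancestor (by default the most recent common ancestor of all loss-search
#' species, i.e. the eutherian ancestor for the mammalian screen) to the end
#' of the loss branch. Pearson's r with the closed-form t statistic
#' t = r * sqrt(df / (1 - r^2)), df = n - 2, and two-sided P.
#'
#' @param stats a `cne_branch_stats`.
#' @param tree a `cne_phylo`.
#' @param from name of the ancestor node from which branch lengths are
#'   summed; default the MRCA of the loss-search leaves.
#' @return list `r`, `t`, `df`, `p`, `n`, and the underlying `data`.
#' @export
loss_frequency_vs_branch_length <- function(stats, tree, from = NULL) {
  stopifnot(inherits(stats, "cne_branch_stats"), inherits(tree, "cne_phylo"))
  if (is.null(from)) {
    ls_tips <- which(tree$leaf_roles == "loss_search")
    covers <- which(rowSums(tree$leaf_mat[, ls_tips, drop = FALSE] > 0) ==
                      length(ls_tips))
    from_id <- covers[which.max(tree$depth[covers])]
  } else from_id <- .node_id(tree, from)
  b <- stats$branches[!is.na(stats$branches$f), , drop = FALSE]
  x <- vapply(.node_id(tree, b$branch), function(id)
    .path_length(tree, from_id, id), numeric(1))
  keep <- !is.na(x)
  x <- x[keep]; f <- b$f[keep]
  if (length(x) < 3) stop("need at least 3 branches with defined frequency")
  if (stats::var(x) == 0 || stats::var(f) == 0)
    stop("zero variance in branch length or loss frequency")
  r <- cor(x, f)
  df <- length(x) - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df)
  list(r = r, t = t_stat, df = df, p = p, n = length(x),
       data = data.frame(branch = b$branch[keep], branch_length = x,
                         loss_frequency = f))
}
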