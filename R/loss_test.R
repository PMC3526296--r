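#' Test for an excess of independent CNE losses
#'
#' The central analysis of the package: given a CNE x species status matrix
#' and a rooted species tree, infers the loss branch of every CNE loss by
#' missing-data parsimony, computes per-branch loss frequencies and, for
#' each multiplicity k, compares the observed number of CNEs with k
#' independent losses against the uniform-loss null via two routes that
#' should agree closely: (i) the exact combinatorial expectation
#' E_k = sum over valid lineage combinations of the product of branch loss
#' frequencies times the jointly eligible CNE count, and (ii) a constrained
#' Monte-Carlo simulation that reassigns the observed loss events to random
#' eligible CNEs while preserving every per-branch event count. The
#' simulation supplies the z-score (standard deviations above the
#' simulation average) and an add-one empirical P-value.
#'
#' @param status a `cne_status` object from [build_status_matrix()] or a
#'   character matrix CNE x species with entries CONSERVED/LOST/MISSING.
#' @param tree a `cne_phylo` from [parse_tree()].
#' @param k independent-loss multiplicities to test (subset of 2:3; CNEs
#'   with 4+ losses are always counted in the simulation output).
#' @param iterations simulation iterations (default 10000).
#' @param seed integer RNG seed for the simulation.
#' @param order event ordering in the simulation, see [simulate_null()].
#' @param rule parsimony tie rule, see [infer_loss_branches()].
#' @param verify per-iteration conservation assertion, see [simulate_null()].
#' @return object of class `cne_loss_test` with components `stats`
#'   (`cne_branch_stats`), `expected` (per-k exact expectations), `sim`
#'   (`cne_null_sim`), `summary` (data.frame with one row per k: observed,
#'   expected, simulation mean/sd/max, z, empirical P), `groups` (per-CNE
#'   loss-group labels) and the call.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_cnes = 300, seed = 7)
#' ds <- generate_dataset(cfg)
#' st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
#' fit <- cne_loss_test(st, ds$tree, iterations = 200, seed = 1)
#' fit
#' }
#' @export
cne_loss_test <- function(status, tree, k = c(2L, 3L), iterations = 10000L,
                          seed = NULL, order = "depth", rule = "ancestral",
                          verify = TRUE) {
  stopifnot(inherits(tree, "cne_phylo"), all(k %in% 2:3))
  cl <- match.call()
  stats <- eligibility_counts(status, tree, k = k, rule = rule)
  by_cne <- attr(stats$events, "by_cne")
  ks <- lengths(by_cne)
  observed <- c(`2` = sum(ks == 2L), `3` = sum(ks == 3L),
                `4plus` = sum(ks >= 4L))

  expected <- lapply(setNames(as.list(k), as.character(k)), function(kk)
    expected_independent(stats, kk))

  sim <- simulate_null(stats$events, status, tree, iterations = iterations,
                       seed = seed, order = order, rule = rule,
                       verify = verify)

  rows <- lapply(as.character(k), function(kk) {
    col <- paste0("n", kk)
    s <- summarize_null(observed[[kk]], sim$dist[[col]])
    data.frame(k = as.integer(kk), observed = s$observed,
               expected = expected[[kk]]$E, sim_mean = s$mean,
               sim_sd = s$sd, sim_max = max(sim$dist[[col]]), z = s$z,
               p = s$p, stringsAsFactors = FALSE)
  })
  summary_tab <- do.call(rbind, rows)

  labels <- ifelse(ks == 0L, "no_loss",
                   ifelse(ks == 1L, "lineage_specific", "independent"))
  groups <- data.frame(cne_id = names(by_cne), group = labels, k = ks,
                       row.names = NULL, stringsAsFactors = FALSE)

  out <- list(stats = stats, expected = expected, sim = sim,
              summary = summary_tab, groups = groups, observed = observed,
              n_cnes = stats$n_cnes, iterations = iterations, seed = seed,
              call = cl)
  class(out) <- "cne_loss_test"
  out
}

#' @export
print.cne_loss_test <- function(x, ...) {
  cat("Independent CNE loss test\n")
  cat("  CNEs: ", x$n_cnes, ";  loss events: ", nrow(x$stats$events),
      ";  CNEs with >=1 loss: ",
      sum(x$groups$group != "no_loss"), "\n", sep = "")
  tab <- x$summary
  tab$expected <- round(tab$expected, 2)
  tab$sim_mean <- round(tab$sim_mean, 2)
  tab$sim_sd <- round(tab$sim_sd, 3)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("  (z: standard deviations above the simulation average;",
      "P: add-one empirical)\n")
  invisible(x)
}

#' @method summary cne_loss_test
#' @export
summary.cne_loss_test <- function(object, n_combos = 10L, ...) {
  print(object)
  cat("\nPer-branch loss frequencies:\n")
  print(object$stats$branches, row.names = FALSE)
  tab2 <- object$expected[["2"]]
  if (!is.null(tab2)) {
    pc <- tab2$per_combo
    sim2 <- object$sim$combos2
    pc$sim_mean <- sim2$sim_mean[match(pc$combo, sim2$combo)]
    pc$sim_max <- sim2$sim_max[match(pc$combo, sim2$combo)]
    pc$sim_mean[is.na(pc$sim_mean)] <- 0
    pc$sim_max[is.na(pc$sim_max)] <- 0
    pc <- pc[order(-pc$O_c, -pc$expected), , drop = FALSE]
    cat("\nTop lineage combinations (k = 2):\n")
    print(utils::head(pc, n_combos), row.names = FALSE)
  }
  invisible(object)
}

#' @method coef cne_loss_test
#' @export
coef.cne_loss_test <- function(object, ...) {
  setNames(object$stats$branches$f, object$stats$branches$branch)
}

#' Plot the simulated null distribution against the observed count
#'
#' Histogram of the simulated number of CNEs with k independent losses with
#' the observed count and the exact expectation marked.
#'
#' @param x a `cne_loss_test`.
#' @param k which multiplicity to plot (default 2).
#' @param ... passed to [graphics::hist()].
#' @method plot cne_loss_test
#' @export
plot.cne_loss_test <- function(x, k = 2L, ...) {
  col <- paste0("n", k)
  dist <- x$sim$dist[[col]]
  obs <- x$observed[[as.character(k)]]
  h <- graphics::hist(dist, breaks = seq(min(dist) - 0.5, max(c(dist, obs)) + 0.5),
                      col = "grey", border = "white",
                      main = paste0("CNEs with ", k, " independent losses"),
                      xlab = "simulated count", ...)
  graphics::abline(v = obs, col = "red", lwd = 2)
  graphics::abline(v = x$expected[[as.character(k)]]$E, col = "black",
                   lwd = 2, lty = 2)
  graphics::legend("topright", legend = c("observed", "exact expectation"),
                   col = c("red", "black"), lty = c(1, 2), lwd = 2, bty = "n")
  invisible(h)
}
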