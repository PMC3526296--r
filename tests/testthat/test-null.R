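test_that("eligibility denominators match a per-CNE brute-force recount", {
  ds <- generate_dataset(sim_config(seed = 31, n_cnes = 50))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  stats <- eligibility_counts(st, ds$tree)
  tr <- ds$tree
  miss <- st$status == "MISSING"
  # N_A: CNEs for which the singleton combination {A} is valid, via the
  # is_valid_combination oracle
  for (i in seq_len(nrow(stats$branches))) {
    b <- stats$branches$branch[i]
    n_val <- sum(vapply(seq_len(nrow(miss)), function(j)
      is_valid_combination(tr, b, missing = colnames(miss)[miss[j, ]]),
      logical(1)))
    expect_equal(stats$branches$N[i], n_val)
    # and never more than the CNEs lacking missing data below A
    v <- match(b, tr$labels)
    tips <- tr$ape$tip.label[tr$leaves_below[[v]]]
    expect_lte(stats$branches$N[i],
               sum(rowSums(miss[, tips, drop = FALSE]) == 0))
  }
  # N_c: per-CNE is_valid_combination oracle
  tab <- stats$combos[["2"]]
  for (i in seq_len(nrow(tab))) {
    combo <- strsplit(tab$combo[i], "+", fixed = TRUE)[[1]]
    n_val <- sum(vapply(seq_len(nrow(miss)), function(j)
      is_valid_combination(tr, combo,
                           missing = colnames(miss)[miss[j, ]]),
      logical(1)))
    expect_equal(tab$N_c[i], n_val)
  }
  # invariant: N_c never exceeds the smallest member N_A
  nmap <- setNames(stats$branches$N, stats$branches$branch)
  for (i in seq_len(nrow(tab))) {
    combo <- strsplit(tab$combo[i], "+", fixed = TRUE)[[1]]
    expect_lte(tab$N_c[i], min(nmap[combo]))
  }
})

test_that("a CNE with missing rat is ineligible for a mouse-rat loss", {
  tr <- study_tree()
  m <- matrix("CONSERVED", 2, tr$n_tip,
              dimnames = list(c("a", "b"), tr$ape$tip.label))
  m["a", "rat"] <- "MISSING"
  stats <- eligibility_counts(m, tr)
  b <- stats$branches
  expect_equal(b$N[b$branch == "MR"], 1L)
  # missing rat also removes the mouse branch: with its only separator
  # missing, a mouse loss would be re-inferred on the mouse-rat ancestor
  expect_equal(b$N[b$branch == "mouse"], 1L)
  expect_equal(b$N[b$branch == "guinea_pig"], 2L)
  # with no missing data every branch is eligible for every CNE
  m["a", "rat"] <- "CONSERVED"
  stats2 <- eligibility_counts(m, tr)
  expect_true(all(stats2$branches$N == 2L))
})

test_that("expected independent losses follow the f_A f_B N_AB formula", {
  stats <- structure(list(
    branches = data.frame(branch = c("A", "B", "C"),
                          L = c(10L, 20L, 0L), N = c(100L, 100L, 100L),
                          f = c(0.1, 0.2, 0)),
    combos = list(`2` = data.frame(combo = c("A+B", "A+C"),
                                   N_c = c(100L, 80L),
                                   O_c = c(3L, 0L))),
    n_cnes = 100L), class = "cne_branch_stats")
  res <- expected_independent(stats, 2)
  expect_equal(res$E, 0.1 * 0.2 * 100)  # f_C = 0 combinations contribute 0
  expect_equal(res$per_combo$expected, c(2.0, 0))
  stats$branches$N[1] <- 0L
  expect_error(expected_independent(stats, 2), "undefined")
})

test_that("empirical P uses the add-one estimator and flags sd = 0", {
  d <- c(rep(0, 999), 5)
  s <- summarize_null(6, d)
  expect_equal(s$p, 1 / 1001)
  expect_false(s$degenerate)
  s2 <- summarize_null(5, d)
  expect_equal(s2$p, 2 / 1001)
  # observed equal to every simulated value
  s3 <- summarize_null(3, rep(3, 100))
  expect_equal(s3$p, 1)
  expect_true(s3$degenerate)
  expect_true(is.na(s3$z))
  # degenerate all-zero distribution
  s4 <- summarize_null(5, rep(0, 10))
  expect_equal(s4$p, 1 / 11)
  expect_true(s4$degenerate)
})

test_that("every simulation iteration conserves the per-branch events", {
  ds <- generate_dataset(sim_config(seed = 32, n_cnes = 200))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  # verify = TRUE makes the conservation check a hard per-iteration
  # assertion inside the simulation
  sim <- simulate_null(NULL, st, ds$tree, iterations = 50, seed = 9,
                       verify = TRUE)
  expect_equal(nrow(sim$dist), 50L)
  expect_equal(sum(sim$per_branch), sim$n_events)
  ev <- infer_events(st, ds$tree)
  expect_equal(as.vector(sim$per_branch[sort(unique(ev$branch))]),
               as.vector(table(ev$branch)[sort(unique(ev$branch))]))
})

test_that("a single loss event can never produce an independent loss", {
  tr <- study_tree()
  m <- matrix("CONSERVED", 40, tr$n_tip,
              dimnames = list(sprintf("c%02d", 1:40), tr$ape$tip.label))
  m[1, "mouse"] <- "LOST"
  sim <- simulate_null(NULL, m, tr, iterations = 30, seed = 2)
  expect_true(all(sim$dist$n_indep == 0))
  expect_true(all(sim$dist$pairs == 0))
})

test_that("simulation is reproducible under a seed", {
  ds <- generate_dataset(sim_config(seed = 33, n_cnes = 150))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  a <- simulate_null(NULL, st, ds$tree, iterations = 20, seed = 4)
  b <- simulate_null(NULL, st, ds$tree, iterations = 20, seed = 4)
  expect_identical(a$dist, b$dist)
  c <- simulate_null(NULL, st, ds$tree, iterations = 20, seed = 5)
  expect_false(identical(a$dist, c$dist))
})

test_that("exact expectation agrees with the simulation mean", {
  ds <- generate_dataset(sim_config(
    seed = 34, n_cnes = 800,
    propensity = list(model = "uniform")))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  stats <- eligibility_counts(st, ds$tree)
  E2 <- expected_independent(stats, 2)$E
  sim <- simulate_null(stats$events, st, ds$tree, iterations = 400,
                       seed = 6)
  se <- sd(sim$dist$pairs) / sqrt(400)
  expect_lt(abs(E2 - mean(sim$dist$pairs)), 4 * se + 0.05)
})

test_that("event order does not change the simulated distribution", {
  ds <- generate_dataset(sim_config(seed = 35, n_cnes = 300))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  fwd <- simulate_null(NULL, st, ds$tree, iterations = 300, seed = 7)
  rev <- simulate_null(NULL, st, ds$tree, iterations = 300, seed = 8,
                       order = "reverse")
  rnd <- simulate_null(NULL, st, ds$tree, iterations = 300, seed = 9,
                       order = "random")
  expect_gt(suppressWarnings(
    stats::ks.test(fwd$dist$n2, rev$dist$n2)$p.value), 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(fwd$dist$n2, rnd$dist$n2)$p.value), 0.01)
})

test_that("loss-frequency vs branch-length reproduces the closed-form t", {
  # 11 branches engineered so cor(branch length, loss frequency) ~ 0.9
  nb <- 11
  set.seed(13)
  x <- seq(0.1, 0.6, length.out = nb)
  zx <- as.vector(scale(x))
  e <- rnorm(nb)
  ze <- as.vector(scale(residuals(lm(e ~ x))))
  f_target <- 0.9 * zx + sqrt(1 - 0.81) * ze   # cor(x, f_target) = 0.9
  nC <- 2000
  L <- round((f_target - min(f_target) + 0.2) / 20 * nC)  # positive counts
  nwk <- paste0("(", paste0("t", 1:nb, ":", x, collapse = ","),
                ",OUT:1.0);")
  tr <- parse_tree(nwk, roles = c(setNames(rep("loss_search", nb),
                                           paste0("t", 1:nb)),
                                  OUT = "outgroup"))
  m <- matrix("CONSERVED", nC, tr$n_tip,
              dimnames = list(sprintf("c%04d", 1:nC), tr$ape$tip.label))
  for (i in seq_len(nb)) if (L[i] > 0) m[1:L[i], paste0("t", i)] <- "LOST"
  stats <- eligibility_counts(m, tr, k = 2)
  res <- loss_frequency_vs_branch_length(stats, tr)
  expect_equal(res$df, nb - 2L)
  expect_equal(res$t, res$r * sqrt(res$df / (1 - res$r^2)))
  expect_equal(res$p, 2 * pt(-abs(res$t), res$df))
  # r is 0.9 up to count discretization; t approximately 6.19, in line
  # with 0.9 * sqrt(9 / 0.19)
  expect_lt(abs(res$r - 0.9), 0.02)
  expect_lt(abs(res$t - 6.19), 0.35)
  # perfectly proportional frequencies give r = 1 (degenerate t)
  m2 <- matrix("CONSERVED", nC, tr$n_tip,
               dimnames = list(sprintf("c%04d", 1:nC), tr$ape$tip.label))
  L2 <- round(x * 100)
  for (i in seq_len(nb)) m2[1:L2[i], paste0("t", i)] <- "LOST"
  res2 <- loss_frequency_vs_branch_length(
    eligibility_counts(m2, tr, k = 2), tr)
  expect_equal(res2$r, 1)
})

test_that("cne_loss_test assembles both null routes into one summary", {
  ds <- generate_dataset(sim_config(seed = 36, n_cnes = 400))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  fit <- cne_loss_test(st, ds$tree, iterations = 100, seed = 3)
  expect_s3_class(fit, "cne_loss_test")
  expect_equal(nrow(fit$summary), 2L)
  expect_equal(fit$summary$observed[1],
               sum(lengths(attr(fit$stats$events, "by_cne")) == 2))
  expect_true(all(fit$summary$p > 0 & fit$summary$p <= 1))
  expect_named(coef(fit), fit$stats$branches$branch)
  expect_output(print(fit), "Independent CNE loss test")
  expect_equal(sort(unique(fit$groups$group)),
               sort(unique(c("no_loss", fit$groups$group))))
})
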