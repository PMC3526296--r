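test_that("loss-group labels partition the catalog", {
  ev <- list(a = character(0), b = "MR", c = c("mouse", "guinea_pig"),
             d = c("mouse", "cow", "elephant"))
  g <- group_cnes(ev)
  expect_equal(g$group, c("no_loss", "lineage_specific", "independent",
                          "independent"))
  expect_equal(g$k, c(0L, 1L, 2L, 3L))
})

test_that("window clustering ranks planted clusters correctly", {
  sizes <- c(chrA = 2e7, chrB = 2e7)
  # cluster of 4 on chrA within 1 Mb, cluster of 2 on chrB
  cnes <- data.frame(
    chrom = c(rep("chrA", 4), rep("chrB", 2)),
    start = c(5e6, 5.2e6, 5.6e6, 5.9e6, 1e6, 1.4e6))
  cnes$end <- cnes$start + 200
  wc <- window_clusters(cnes, sizes, window = 5e6, step = 1e6)
  expect_equal(wc$count[1], 4L)
  expect_equal(wc$rank[1], 1L)
  expect_equal(max(wc$count[wc$chrom == "chrB"]), 2L)
  top_b <- min(wc$rank[wc$chrom == "chrB"])
  expect_gt(top_b, 1L)
  expect_equal(nrow(window_clusters(cnes[0, ], sizes)), 0L)
  # non-overlapping tiling conserves the total count
  wc2 <- window_clusters(cnes, sizes, window = 5e6, step = 5e6)
  expect_equal(sum(wc2$count), nrow(cnes))
})

test_that("adjacent co-lost CNEs are checked for conserved separators", {
  tr <- study_tree()
  ids <- sprintf("c%d", 1:5)
  m <- matrix("CONSERVED", 5, tr$n_tip,
              dimnames = list(ids, tr$ape$tip.label))
  m[c(1, 3, 5), "guinea_pig"] <- "LOST"
  m[c(1, 3, 5), "dog"] <- "LOST"
  cnes <- data.frame(id = ids, start = c(100, 200, 300, 400, 500))
  res <- verify_separate_events(cnes, m, c("guinea_pig", "dog"))
  expect_true(res$all_separate)
  expect_equal(nrow(res$pairs), 2L)
  # remove the separator between c3 and c5
  m[4, "guinea_pig"] <- "MISSING"
  res2 <- verify_separate_events(cnes, m, c("guinea_pig", "dog"))
  expect_false(res2$all_separate)
  expect_equal(res2$pairs$separated, c(TRUE, FALSE))
  # adjacent pair with nothing between is a single-deletion candidate
  m2 <- matrix("CONSERVED", 2, tr$n_tip,
               dimnames = list(c("a", "b"), tr$ape$tip.label))
  m2[, "guinea_pig"] <- "LOST"; m2[, "dog"] <- "LOST"
  res3 <- verify_separate_events(data.frame(id = c("a", "b"),
                                            start = c(1, 2)),
                                 m2, c("guinea_pig", "dog"))
  expect_false(res3$all_separate)
  expect_error(verify_separate_events(data.frame(id = c("a", "b"),
                                                 start = c(2, 1)),
                                      m2, c("guinea_pig", "dog")),
               "sorted")
})

test_that("nearest-TSS assignment matches the quadratic oracle", {
  tss <- data.frame(chrom = "chr1", pos = c(90, 300), gene = c("g1", "g2"))
  cnes <- data.frame(id = "c1", chrom = "chr1", start = 90, end = 110)
  a <- assign_nearest_tss(cnes, tss)
  expect_equal(a$gene, "g1")
  expect_equal(a$distance, -10)
  # equidistant: deterministic tie toward the smaller coordinate, flagged
  tss2 <- data.frame(chrom = "chr1", pos = c(50, 150), gene = c("g1", "g2"))
  a2 <- assign_nearest_tss(cnes, tss2)
  expect_equal(a2$gene, "g1")
  expect_true(a2$tie)
  expect_error(assign_nearest_tss(cnes, tss[0, ]), "empty")

  set.seed(17)
  cnes_r <- data.frame(id = sprintf("c%03d", 1:60),
                       chrom = sample(c("chr1", "chr2"), 60, TRUE),
                       start = sample.int(1e6, 60))
  cnes_r$end <- cnes_r$start + 100
  tss_r <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                      pos = sample.int(1e6, 40),
                      gene = sprintf("g%03d", 1:40))
  got <- assign_nearest_tss(cnes_r, tss_r)
  expect_equal(got$gene, nearest_tss_oracle(cnes_r, tss_r))
})

test_that("gene-loss association counts any/all absent species", {
  tr <- study_tree()
  evs <- list(c1 = c("mouse", "guinea_pig"), c2 = c("MR", "cow"),
              c3 = c("dog", "elephant"))
  assignments <- data.frame(cne_id = names(evs),
                            gene = c("g1", "g2", "g3"))
  orth <- expand.grid(gene = c("g1", "g2", "g3"),
                      species = c("mouse", "rat", "guinea_pig", "cow",
                                  "dog", "elephant"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  orth$status <- "present"
  # g1 absent in mouse only (one of two loss species)
  orth$status[orth$gene == "g1" & orth$species == "mouse"] <- "absent"
  # g3 absent in both loss species
  orth$status[orth$gene == "g3" &
                orth$species %in% c("dog", "elephant")] <- "absent"
  res <- gene_loss_association(assignments, orth, evs, tr)
  expect_equal(res$n_any, 2L)
  expect_equal(res$n_all, 1L)
  # gap entries are excluded from the all-species assessment: g3 stays
  # "absent in all assessable species" when dog becomes a gap, and a
  # CNE whose only absence turns into a gap drops out of both counts
  orth$status[orth$gene == "g3" & orth$species == "dog"] <- "gap"
  orth$status[orth$gene == "g1" & orth$species == "mouse"] <- "gap"
  res2 <- gene_loss_association(assignments, orth, evs, tr)
  expect_equal(res2$n_any, 1L)
  expect_equal(res2$n_all, 1L)
  # internal-branch events expand to all descendant loss species
  expect_equal(res$audit$n_loss_species[res$audit$cne_id == "c2"], 3L)
  expect_error(gene_loss_association(
    data.frame(cne_id = "c1", gene = "gX"), orth, evs, tr), "lacks")
})

test_that("size matching produces identical length multisets", {
  ind <- data.frame(id = c("i1", "i2"), length = c(100, 150))
  nl <- data.frame(id = sprintf("n%d", 1:6),
                   length = c(100, 100, 150, 150, 200, 250))
  ls <- data.frame(id = sprintf("l%d", 1:4),
                   length = c(100, 150, 150, 300))
  set.seed(2)
  res <- size_matched_sample(ind, nl, ls)
  expect_equal(sort(res$no_loss$length), c(100, 150))
  expect_equal(sort(res$lineage_specific$length), c(100, 150))
  # without replacement: duplicated lengths need distinct donors
  ind2 <- data.frame(id = c("i1", "i2"), length = c(100, 100))
  res2 <- size_matched_sample(ind2, nl, ls["length" != 0, ][c(1, 1), ])
  expect_equal(res2$no_loss$length, c(100, 100))
  expect_equal(anyDuplicated(res2$no_loss$id), 0L)
  # unmatched length is an error naming the length
  ind3 <- data.frame(id = "i1", length = 999)
  expect_error(size_matched_sample(ind3, nl, ls), "999")
  set.seed(8); a <- size_matched_sample(ind, nl, ls)
  set.seed(8); b <- size_matched_sample(ind, nl, ls)
  expect_identical(a, b)
})

test_that("characteristic comparisons use rank-sum and chi-square", {
  set.seed(4)
  g1 <- data.frame(length = rnorm(300, 240, 40),
                   constraint_rs = rbeta(300, 5, 6),
                   ancestry_pre_mammal = runif(300) < 0.25)
  res_same <- compare_characteristics(list(a = g1, b = g1))
  expect_true(all(res_same$tests$p[res_same$tests$test == "wilcoxon"] > 0.9,
                  na.rm = TRUE))
  # planted shorter / less constrained / younger second group
  g2 <- data.frame(length = rnorm(300, 150, 40),
                   constraint_rs = rbeta(300, 3.5, 6),
                   ancestry_pre_mammal = runif(300) < 0.12)
  res <- compare_characteristics(list(no_loss = g1, independent = g2))
  expect_true(all(res$tests$p[res$tests$feature %in%
                                c("length", "ancestry_pre_mammal")] < 0.05))
  expect_equal(nrow(res$summary), 2L)
  # cross-check the chi-square against the closed-form 2x2 statistic
  t_anc <- res$tests[res$tests$feature == "ancestry_pre_mammal", ]
  tab <- rbind(c(sum(g1$ancestry_pre_mammal), sum(!g1$ancestry_pre_mammal)),
               c(sum(g2$ancestry_pre_mammal), sum(!g2$ancestry_pre_mammal)))
  n <- sum(tab)
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(t_anc$p, pchisq(stat, 1, lower.tail = FALSE))
})

test_that("proportion differences of 0.25 vs 0.15 at n = 500 are detected", {
  g1 <- data.frame(ancestry_pre_mammal = rep(c(TRUE, FALSE),
                                             c(125, 375)))
  g2 <- data.frame(ancestry_pre_mammal = rep(c(TRUE, FALSE),
                                             c(75, 425)))
  res <- compare_characteristics(list(a = g1, b = g2))
  p <- res$tests$p[res$tests$feature == "ancestry_pre_mammal"]
  expect_lt(p, 0.01)
})
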