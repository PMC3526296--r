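ev_row <- function(cne = "c1", sp = "mouse", overlap = 0,
                   scaf = "mouse_s1", down_scaf = scaf, strand = "+",
                   up_q = c(1000, 1100), down_q = c(1300, 1400)) {
  data.frame(cne_id = cne, species = sp, ref_chrom = "chr1",
             up_ref_start = 0, up_ref_end = 100,
             down_ref_start = 1100, down_ref_end = 1200,
             up_scaffold = scaf, down_scaffold = down_scaf,
             up_q_start = up_q[1], up_q_end = up_q[2],
             down_q_start = down_q[1], down_q_end = down_q[2],
             strand = strand, cne_overlap_bp = overlap,
             stringsAsFactors = FALSE)
}

test_that("classify_status applies the loss filters with fixed precedence", {
  tr <- rodent_tree()
  # clean loss: co-syntenic flanks, no gap, no hit
  r <- classify_status("c1", "mouse", ev_row(), NULL, NULL, tr)
  expect_equal(r$status, "LOST")
  expect_equal(r$ref_flank_distance, 1000)
  expect_equal(r$query_flank_distance, 200)
  # aligned overlap -> CONSERVED regardless of flanks
  expect_equal(classify_status("c1", "mouse", ev_row(overlap = 50),
                               NULL, NULL, tr)$status, "CONSERVED")
  # gap inside the inter-flank interval
  gaps <- data.frame(scaffold = "mouse_s1", start = 1150, end = 1160)
  r2 <- classify_status("c1", "mouse", ev_row(), gaps, NULL, tr)
  expect_equal(r2$status, "MISSING")
  expect_equal(r2$reason, "assembly_gap")
  # gap outside the inter-flank interval does not block the call
  gaps2 <- data.frame(scaffold = "mouse_s1", start = 10, end = 900)
  expect_equal(classify_status("c1", "mouse", ev_row(), gaps2, NULL,
                               tr)$status, "LOST")
  # similarity hit
  hits <- data.frame(cne_id = "c1", species = "mouse", source = "trace",
                     score = 90)
  r3 <- classify_status("c1", "mouse", ev_row(), NULL, hits, tr)
  expect_equal(r3$reason, "similarity_hit")
  # absent flank
  ev <- ev_row(); ev$down_q_start <- NA; ev$down_q_end <- NA
  expect_equal(classify_status("c1", "mouse", ev, NULL, NULL, tr)$reason,
               "no_flank")
  expect_equal(classify_status("c1", "mouse", NULL, NULL, NULL, tr)$reason,
               "no_flank")
  # flanks on different scaffolds
  expect_equal(classify_status("c1", "mouse",
                               ev_row(down_scaf = "mouse_s2"),
                               NULL, NULL, tr)$reason, "not_cosyntenic")
  # inconsistent order for the plus strand
  expect_equal(classify_status("c1", "mouse",
                               ev_row(up_q = c(1300, 1400),
                                      down_q = c(1000, 1100)),
                               NULL, NULL, tr)$reason, "not_cosyntenic")
  # ... but that order is consistent on the minus strand
  expect_equal(classify_status("c1", "mouse",
                               ev_row(up_q = c(1300, 1400),
                                      down_q = c(1000, 1100),
                                      strand = "-"),
                               NULL, NULL, tr)$status, "LOST")
  # presence-only species never gets LOST
  expect_equal(classify_status("c1", "kangaroo_rat",
                               ev_row(sp = "kangaroo_rat"), NULL, NULL,
                               tr)$reason, "low_coverage_species")
  # gap + hit: gap wins by precedence
  r4 <- classify_status("c1", "mouse", ev_row(), gaps, hits, tr)
  expect_equal(r4$reason, "assembly_gap")
  # evidence for another element is rejected
  expect_error(classify_status("c9", "mouse", ev_row(), NULL, NULL, tr),
               "different CNE")
})

test_that("build_status_matrix agrees with per-cell classification", {
  ds <- generate_dataset(sim_config(seed = 21, n_cnes = 60))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  for (i in sample(nrow(st$status), 20)) {
    id <- rownames(st$status)[i]
    for (s in colnames(st$status)) {
      ev <- ds$evidence[ds$evidence$cne_id == id & ds$evidence$species == s, ]
      g <- ds$gaps[ds$gaps$species == s, c("scaffold", "start", "end")]
      r <- classify_status(id, s, if (nrow(ev)) ev else NULL, g, ds$hits,
                           ds$tree)
      expect_identical(st$status[i, s], r$status)
    }
  }
})

test_that("status cells partition into the three states with reason codes", {
  ds <- generate_dataset(sim_config(seed = 22, n_cnes = 300))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  expect_false(any(is.na(st$status)))
  is_missing <- st$status == "MISSING"
  expect_true(all(!is.na(st$reason[is_missing])))
  expect_true(all(is.na(st$reason[!is_missing])))
  expect_true(all(st$reason[is_missing] %in%
                    c("no_flank", "not_cosyntenic", "assembly_gap",
                      "similarity_hit", "low_coverage_species")))
  # LOST only in loss-search species
  ls <- names(ds$tree$leaf_roles[ds$tree$leaf_roles == "loss_search"])
  expect_equal(sum(st$status[, setdiff(colnames(st$status), ls)] == "LOST"),
               0L)
})

test_that("adding a gap or hit only moves cells from LOST to MISSING", {
  ds <- generate_dataset(sim_config(seed = 23, n_cnes = 120))
  st <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
  le <- st$loss_evidence
  expect_gt(nrow(le), 0)
  pick <- le[sample(nrow(le), 5), ]
  gaps2 <- rbind(ds$gaps,
                 data.frame(species = pick$species, scaffold = pick$scaffold,
                            start = pick$q_interflank_start + 1,
                            end = pick$q_interflank_start + 5))
  hits2 <- rbind(ds$hits,
                 data.frame(cne_id = pick$cne_id[1], species = pick$species[1],
                            source = "genome", score = 50))
  st2 <- build_status_matrix(ds$cnes, ds$evidence, gaps2, hits2, ds$tree)
  changed <- st$status != st2$status
  expect_true(all(st$status[changed] == "LOST"))
  expect_true(all(st2$status[changed] == "MISSING"))
  for (i in seq_len(nrow(pick)))
    expect_equal(st2$status[pick$cne_id[i], pick$species[i]], "MISSING")
})

test_that("duplicate evidence rows are rejected", {
  ds <- generate_dataset(sim_config(seed = 24, n_cnes = 20))
  expect_error(
    build_status_matrix(ds$cnes, rbind(ds$evidence, ds$evidence[1, ]),
                        ds$gaps, ds$hits, ds$tree),
    "duplicate")
})

test_that("deletion analysis recovers the flank-distance arithmetic", {
  calls <- data.frame(species = "mouse", ref_flank_distance = 1000,
                      query_flank_distance = 120)
  tab <- deletion_analysis(calls)
  expect_equal(tab$mean_deletion[tab$species == "mouse"], 880)
  # identity case: ref = query -> deletion 0, slope 1
  calls2 <- data.frame(species = "horse",
                       ref_flank_distance = c(100, 300, 800, 1500),
                       query_flank_distance = c(100, 300, 800, 1500))
  tab2 <- deletion_analysis(calls2)
  expect_equal(tab2$mean_deletion, c(0, 0))
  expect_equal(tab2$slope, c(1, 1))
  expect_equal(tab2$intercept, c(0, 0))
  expect_equal(nrow(deletion_analysis(calls[0, ])), 0L)
})

test_that("trace validation requires one read spanning region plus pads", {
  reads <- data.frame(start = c(900, 1200), end = c(1500, 1600))
  expect_equal(validate_with_traces(c(1000, 1400), reads), "validated")
  # 500 bp region is excluded (strict bound)
  expect_equal(validate_with_traces(c(1000, 1500), reads), "too_long")
  expect_equal(validate_with_traces(c(1000, 1499), reads), "not_validated")
  # two half-covering reads never validate
  halves <- data.frame(start = c(900, 1200), end = c(1250, 1600))
  expect_equal(validate_with_traces(c(1000, 1400), halves), "not_validated")
  # pads matter: read covering exactly the region is not enough
  tight <- data.frame(start = 1000, end = 1400)
  expect_equal(validate_with_traces(c(1000, 1400), tight), "not_validated")
  pad <- data.frame(start = 950, end = 1450)
  expect_equal(validate_with_traces(c(1000, 1400), pad), "validated")
  expect_equal(validate_with_traces(c(1000, 1100), NULL), "not_validated")
  expect_error(validate_with_traces(c(1000, 1100), reads, flank_pad = -1),
               ">= 0")
  # monotone in read length: extending a read cannot unvalidate
  expect_equal(validate_with_traces(c(1000, 1400),
                                    data.frame(start = 900, end = 1700)),
               "validated")
})

test_that("control-region sampling is seeded, exact-size and gap-free", {
  sizes <- c(s1 = 10000, s2 = 5000)
  gaps <- data.frame(chrom = "s1", start = 4000, end = 6000)
  set.seed(5); a <- sample_control_regions(300, sizes, gaps, n = 50)
  set.seed(5); b <- sample_control_regions(300, sizes, gaps, n = 50)
  expect_identical(a, b)
  expect_true(all(a$end - a$start == 300))
  hit_gap <- a$chrom == "s1" & a$start < 6000 & a$end > 4000
  expect_false(any(hit_gap))
  z <- sample_control_regions(0, sizes, gaps, n = 3)
  expect_true(all(z$end == z$start))
  expect_error(sample_control_regions(20000, sizes, gaps),
               "no feasible")
})

test_that("control-region starts are uniform over feasible positions", {
  sizes <- c(s1 = 2000, s2 = 1000)
  gaps <- data.frame(chrom = "s1", start = 900, end = 1100)
  set.seed(11)
  draws <- sample_control_regions(100, sizes, gaps, n = 10000)
  # exact feasible start enumeration, binned so expected counts stay large
  feas <- c(paste("s1", c(0:800, 1100:1900) %/% 100),
            paste("s2", (0:900) %/% 100))
  key <- paste(draws$chrom, draws$start %/% 100)
  expect_true(all(key %in% feas))
  lev <- sort(unique(feas))
  tab <- table(factor(key, levels = lev))
  expected <- table(factor(feas, levels = lev))
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(tab),
                      p = as.vector(expected) / sum(expected)))
  expect_gt(gof$p.value, 0.01)
})
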