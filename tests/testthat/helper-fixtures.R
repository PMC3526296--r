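# Shared fixtures and independent oracles used across the test files.

# small rodent tree used in many unit tests
rodent_tree <- function() {
  parse_tree(
    "((((mouse:0.35,rat:0.33)MR:0.06,kangaroo_rat:0.42)MRK:0.02,guinea_pig:0.23)ROD:0.1,dog:0.3)R;",
    roles = list(loss_search = c("mouse", "rat", "guinea_pig"),
                 presence_only = "kangaroo_rat",
                 outgroup = "dog"))
}

study_tree <- function() {
  tt <- default_study_tree()
  parse_tree(tt$newick, tt$roles)
}

# build a status vector: everything CONSERVED except the named overrides
status_vec <- function(tree, lost = character(), missing = character()) {
  sv <- setNames(rep("CONSERVED", tree$n_tip), tree$ape$tip.label)
  sv[lost] <- "LOST"
  sv[missing] <- "MISSING"
  sv
}

# Random battery tree: n loss-search leaves (t1..tn) plus one always-
# conserved outgroup attached at the root. Returns both the package tree
# and the underlying ape phylo of the same Newick string.
battery_tree <- function(n_leaves = 6) {
  phy <- ape::rtree(n_leaves, rooted = TRUE)
  nw <- ape::write.tree(phy)
  nw2 <- paste0("(", sub(";$", "", nw), ":0.5,OUT:1.0);")
  tree <- parse_tree(nw2, roles = c(
    setNames(rep("loss_search", n_leaves), phy$tip.label),
    OUT = "outgroup"))
  list(tree = tree, phy = ape::read.tree(text = nw2))
}

# ---------------------------------------------------------------------
# Independent brute-force Dollo oracle.
#
# Works on the raw ape phylo with tip-set bitmasks (phangorn supplies the
# descendant tips, a code path disjoint from the package's leaf-incidence
# matrix). A "qualifying" edge has no CONSERVED tip and >=1 LOST tip
# below. Minimal covers are found by exhaustive subset enumeration over
# qualifying edges in increasing size: a cover is a pairwise-disjoint set
# of qualifying edges whose tip union contains every LOST tip. The
# ancestral tie rule selects the cover whose edges are maximal (parent
# edge not qualifying).
dollo_oracle <- function(phy, sv) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  desc <- phangorn::Descendants(phy, seq_len(nn), type = "tips")
  mask <- vapply(desc, function(t) sum(bitwShiftL(1L, t - 1L)), numeric(1))
  sv <- sv[phy$tip.label]
  lost_mask <- sum(bitwShiftL(1L, which(sv == "LOST") - 1L))
  cons_mask <- sum(bitwShiftL(1L, which(sv == "CONSERVED") - 1L))
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]

  qual_of <- function(v) bitwAnd(mask[v], cons_mask) == 0 &&
    bitwAnd(mask[v], lost_mask) > 0
  nodes <- setdiff(seq_len(nn), root)
  qual <- nodes[vapply(nodes, qual_of, logical(1))]

  tipset <- function(v) sort(phy$tip.label[desc[[v]]])
  if (lost_mask == 0)
    return(list(min_size = 0L, covers = list(list()),
                ancestral = list()))
  covers <- list()
  min_size <- NA_integer_
  for (s in seq_along(qual)) {
    for (ss in utils::combn(qual, s, simplify = FALSE)) {
      msk <- mask[ss]
      disjoint <- TRUE
      if (s > 1) for (i in 1:(s - 1)) for (j in (i + 1):s)
        if (bitwAnd(msk[i], msk[j]) != 0) { disjoint <- FALSE }
      if (!disjoint) next
      u <- Reduce(bitwOr, msk)
      if (bitwAnd(u, lost_mask) == lost_mask)
        covers[[length(covers) + 1L]] <- ss
    }
    if (length(covers)) { min_size <- s; break }
  }
  ancestral <- Filter(function(v) {
    p <- parent[v]
    p == root || !qual_of(p)
  }, qual)
  # maximal qualifying nodes that contain a lost tip form the ancestral cover
  ancestral <- ancestral[vapply(ancestral, function(v)
    bitwAnd(mask[v], lost_mask) > 0, logical(1))]
  list(min_size = min_size,
       covers = lapply(covers, function(ss) lapply(ss, tipset)),
       ancestral = lapply(ancestral, tipset))
}

# leaf sets below the inferred branches, for oracle comparison
inferred_tipsets <- function(tree, branches) {
  lapply(branches, function(b) {
    v <- match(b, tree$labels)
    sort(tree$ape$tip.label[tree$leaves_below[[v]]])
  })
}

same_tipset_family <- function(a, b) {
  key <- function(x) sort(vapply(x, paste, character(1), collapse = "|"))
  identical(key(a), key(b))
}

# quadratic brute-force nearest-TSS oracle
nearest_tss_oracle <- function(cnes, tss) {
  out <- character(nrow(cnes))
  for (i in seq_len(nrow(cnes))) {
    mid <- (cnes$start[i] + cnes$end[i]) / 2
    cand <- tss[tss$chrom == cnes$chrom[i], ]
    d <- abs(cand$pos - mid)
    best <- which(d == min(d))
    out[i] <- cand$gene[best[which.min(cand$pos[best])]]
  }
  out
}

# random status matrix over a tree, respecting role invariants and
# guaranteeing a conserved outgroup
random_status_matrix <- function(tree, n, p_lost = 0.1, p_miss = 0.1) {
  tips <- tree$ape$tip.label
  m <- matrix("CONSERVED", n, length(tips),
              dimnames = list(sprintf("c%04d", seq_len(n)), tips))
  for (s in tips) {
    u <- runif(n)
    if (tree$leaf_roles[[s]] == "loss_search") {
      m[u < p_lost, s] <- "LOST"
      m[u >= p_lost & u < p_lost + p_miss, s] <- "MISSING"
    } else {
      m[u < p_miss, s] <- "MISSING"
    }
  }
  og <- tips[tree$leaf_roles == "outgroup"]
  bad <- rowSums(m[, og, drop = FALSE] == "CONSERVED") == 0
  m[bad, og[1]] <- "CONSERVED"
  m
}
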