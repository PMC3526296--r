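#' @importFrom stats median sd cor pt pchisq setNames runif rbinom rpois rlnorm
#' @importFrom utils read.table write.table head combn
NULL

# Status codes used throughout the package for one CNE in one species.
STATUS_CONSERVED <- "CONSERVED"
STATUS_LOST <- "LOST"
STATUS_MISSING <- "MISSING"

#' Parse a rooted species tree with leaf roles
#'
#' Builds the phylogeny object used by all loss-inference functions from a
#' Newick string. Every leaf must be assigned exactly one role:
#' \describe{
#'   \item{loss_search}{high-quality genome in which complete CNE losses are
#'     called.}
#'   \item{presence_only}{genome (typically low coverage) where alignment to a
#'     CNE counts as presence but absence is treated as missing data.}
#'   \item{outgroup}{species used to establish that a CNE is ancestral; never
#'     carries a loss call.}
#' }
#'
#' Unnamed internal nodes receive deterministic names built from the sorted
#' initials of their descendant leaves, so branch identities are stable across
#' runs and machines.
#'
#' @param newick_text single Newick string (branch lengths required).
#' @param roles either a named character vector (leaf -> role) or a list with
#'   elements `loss_search`, `presence_only`, `outgroup`, each a character
#'   vector of leaf names. Every leaf must be covered exactly once.
#' @return an object of class `cne_phylo`: a list with node tables
#'   (`labels`, `parent`, `children`, `branch_length`, `depth`, `root`),
#'   the leaf role map (`leaf_roles`), and precomputed leaf-incidence
#'   structures used by the inference routines.
#' @examples
#' tr <- parse_tree("((A:1,B:1)AB:1,C:2)R;",
#'                  roles = list(loss_search = c("A", "B"), outgroup = "C"))
#' tr
#' @export
parse_tree <- function(newick_text, roles) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  phy <- ape::read.tree(text = newick_text)
  if (is.null(phy)) stop("invalid Newick string")
  if (is.null(phy$edge.length)) stop("branch lengths are required")
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")

  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L

  roles <- .normalize_roles(roles)
  unknown <- setdiff(names(roles), phy$tip.label)
  if (length(unknown))
    stop("unknown leaf in roles map: ", paste(unknown, collapse = ", "))
  missing_role <- setdiff(phy$tip.label, names(roles))
  if (length(missing_role))
    stop("leaf missing a role: ", paste(missing_role, collapse = ", "))
  if (!any(roles == "outgroup"))
    stop("at least one outgroup leaf is required")

  parent <- rep(NA_integer_, n_node)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  branch_length <- rep(NA_real_, n_node)
  branch_length[phy$edge[, 2L]] <- phy$edge.length

  children <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <- c(children[[phy$edge[i, 1L]]], phy$edge[i, 2L])

  depth <- rep(NA_integer_, n_node)
  depth[root] <- 0L
  # edges in phy$edge are not guaranteed preorder; iterate until fixed point
  ord <- .preorder_nodes(root, children)
  for (v in ord[-1L]) depth[v] <- depth[parent[v]] + 1L

  # leaf sets below every node
  leaf_mat <- matrix(0, nrow = n_node, ncol = n_tip)
  for (v in rev(ord)) {
    if (v <= n_tip) leaf_mat[v, v] <- 1
    else for (ch in children[[v]]) leaf_mat[v, ] <- leaf_mat[v, ] + leaf_mat[ch, ]
  }
  leaf_mat <- (leaf_mat > 0) + 0

  labels <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[nl == ""] <- NA_character_
    labels[(n_tip + 1L):n_node] <- nl
  }
  # deterministic auto-names: sorted initials of descendant leaves
  for (v in (n_tip + 1L):n_node) {
    if (is.na(labels[v])) {
      tips <- phy$tip.label[leaf_mat[v, ] > 0]
      labels[v] <- paste(sort(toupper(substr(tips, 1L, 1L))), collapse = "")
    }
  }
  dup <- duplicated(labels)
  while (any(dup)) {
    labels[dup] <- paste0(labels[dup], "'")
    dup <- duplicated(labels)
  }

  leaves_below <- lapply(seq_len(n_node), function(v) which(leaf_mat[v, ] > 0))
  roles_vec <- roles[phy$tip.label]

  ls_tip <- which(roles_vec == "loss_search")
  capable <- vapply(seq_len(n_node), function(v) {
    !is.na(parent[v]) && all(leaves_below[[v]] %in% ls_tip)
  }, logical(1))

  # parent index with root mapped onto itself (convenient for matrix ops)
  parent_or_self <- parent
  parent_or_self[root] <- root

  tree <- list(
    ape = phy, n_tip = n_tip, n_node = n_node, root = root,
    labels = labels, parent = parent, parent_or_self = parent_or_self,
    children = children, branch_length = branch_length, depth = depth,
    leaf_roles = roles_vec, leaf_mat = leaf_mat, leaves_below = leaves_below,
    capable = which(capable), preorder = ord
  )
  class(tree) <- "cne_phylo"
  tree
}

.normalize_roles <- function(roles) {
  valid <- c("loss_search", "presence_only", "outgroup")
  if (is.list(roles)) {
    roles <- roles[intersect(names(roles), valid)]
    out <- unlist(lapply(names(roles), function(r) setNames(rep(r, length(roles[[r]])), roles[[r]])))
    if (anyDuplicated(names(out)))
      stop("leaf assigned more than one role: ",
           paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
    return(out)
  }
  if (!all(roles %in% valid))
    stop("roles must be one of: ", paste(valid, collapse = ", "))
  roles
}

.preorder_nodes <- function(root, children) {
  n <- length(children)
  ord <- integer(n)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- v
    if (!is.null(children[[v]])) stack <- c(stack, rev(children[[v]]))
  }
  ord[seq_len(k)]
}

#' @export
print.cne_phylo <- function(x, ...) {
  tab <- table(x$leaf_roles)
  cat("Rooted species phylogeny: ", x$n_tip, " leaves, ", x$n_node - x$n_tip,
      " internal nodes\n", sep = "")
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  loss-search-capable branches:",
      paste(x$labels[x$capable], collapse = ", "), "\n")
  invisible(x)
}

.node_id <- function(tree, name) {
  id <- match(name, tree$labels)
  if (anyNA(id)) stop("unknown node: ", paste(name[is.na(id)], collapse = ", "))
  id
}

#' Branch table of a phylogeny
#'
#' One row per non-root node (a branch is identified by its child node),
#' with its length, depth of the child node, and whether the branch is
#' loss-search capable (all leaves below it permit a loss call).
#'
#' @param tree a `cne_phylo`.
#' @return data.frame with columns `branch`, `parent`, `length`, `depth`,
#'   `capable`.
#' @export
tree_branches <- function(tree) {
  stopifnot(inherits(tree, "cne_phylo"))
  ids <- setdiff(seq_len(tree$n_node), tree$root)
  data.frame(
    branch = tree$labels[ids],
    parent = tree$labels[tree$parent[ids]],
    length = tree$branch_length[ids],
    depth = tree$depth[ids],
    capable = ids %in% tree$capable,
    stringsAsFactors = FALSE
  )
}

#' Loss-search-capable branches
#'
#' Branches on which a loss can be called: every leaf below must be a
#' loss-search species (a loss event cannot be placed above presence-only or
#' outgroup leaves because a LOST status is never assigned to them).
#'
#' @param tree a `cne_phylo`.
#' @return character vector of branch names, sorted.
#' @export
loss_capable_branches <- function(tree) {
  stopifnot(inherits(tree, "cne_phylo"))
  sort(tree$labels[tree$capable])
}

.check_status_vector <- function(sv, tree) {
  tips <- tree$ape$tip.label
  if (is.null(names(sv)) || !setequal(names(sv), tips))
    stop("status vector must name every leaf of the tree exactly once")
  sv <- sv[tips]
  ok <- sv %in% c(STATUS_CONSERVED, STATUS_LOST, STATUS_MISSING)
  if (!all(ok)) stop("invalid status value: ", paste(unique(sv[!ok]), collapse = ", "))
  lost <- sv == STATUS_LOST
  if (any(lost & tree$leaf_roles != "loss_search"))
    stop("LOST status on a non-loss-search leaf: ",
         paste(tips[lost & tree$leaf_roles != "loss_search"], collapse = ", "))
  sv
}

#' Infer loss branches for one CNE by parsimony with missing data
#'
#' Given the per-species status of a CNE (CONSERVED / LOST / MISSING), places
#' loss events on tree branches by Dollo-style parsimony: each maximal clade
#' all of whose leaves are LOST or MISSING and which contains at least one
#' LOST leaf receives a single loss on the branch above it. Equivalently,
#' MISSING leaves are pruned, maximal all-LOST clades are taken, and each is
#' mapped back to an original branch. Two reported branches are always
#' separated by at least one CONSERVED leaf.
#'
#' When a LOST leaf has only MISSING relatives the loss can be placed on
#' several nested branches. `rule = "ancestral"` (default) reports the most
#' ancestral consistent branch (the maximal lost-or-missing clade), so losses
#' on internal branches have a loss or missing data for all descendants;
#' `rule = "shallow"` reports the most recent common ancestor of the LOST
#' leaves only.
#'
#' @param sv named character vector leaf -> status in
#'   `c("CONSERVED","LOST","MISSING")`. LOST is only legal for loss-search
#'   leaves.
#' @param tree a `cne_phylo`.
#' @param rule tie rule for nested candidate branches, see Details.
#' @return sorted character vector of branch names (empty when no leaf is
#'   LOST).
#' @examples
#' tr <- parse_tree("(((mouse:1,rat:1)MR:1,guinea_pig:2)ROD:1,dog:3)R;",
#'                  roles = list(loss_search = c("mouse","rat","guinea_pig"),
#'                               outgroup = "dog"))
#' sv <- c(mouse = "LOST", rat = "LOST", guinea_pig = "CONSERVED",
#'         dog = "CONSERVED")
#' infer_loss_branches(sv, tr)  # single loss on the mouse-rat ancestor
#' @export
infer_loss_branches <- function(sv, tree, rule = c("ancestral", "shallow")) {
  rule <- match.arg(rule)
  stopifnot(inherits(tree, "cne_phylo"))
  sv <- .check_status_vector(sv, tree)
  lost <- matrix(sv == STATUS_LOST, nrow = 1L)
  cons <- matrix(sv == STATUS_CONSERVED, nrow = 1L)
  res <- .infer_batch(tree, lost, cons, rule)[[1L]]
  sort(tree$labels[res])
}

# Batched parsimony inference. lost_mat/cons_mat: n_case x n_tip logicals with
# columns in tip-id order. Returns a list of integer node-id vectors.
#
# A node "qualifies" when its subtree has no CONSERVED leaf and >=1 LOST leaf;
# reported (ancestral-rule) branches are the qualifying nodes whose parent
# does not qualify. Because LOST leaves exist only below qualifying nodes,
# every maximal qualifying node contains at least one reported branch and the
# reported set is exactly the set of maximal lost-or-missing clades.
.infer_batch <- function(tree, lost_mat, cons_mat, rule = "ancestral") {
  badBelow <- tree$leaf_mat %*% t(cons_mat) > 0
  lostCnt <- tree$leaf_mat %*% t(lost_mat)
  qual <- !badBelow & lostCnt > 0
  if (any(qual[tree$root, ]))
    stop("status vector with no CONSERVED leaf (no conserved outgroup): case(s) ",
         paste(which(qual[tree$root, ]), collapse = ", "))
  maximal <- qual & !qual[tree$parent_or_self, , drop = FALSE]
  out <- lapply(seq_len(ncol(maximal)), function(j) which(maximal[, j]))
  if (rule == "shallow") {
    out <- lapply(seq_along(out), function(j) {
      vapply(out[[j]], function(v) .mrca_of_lost(tree, v, lostCnt[, j]), integer(1))
    })
  }
  out
}

# walk down from node v to the MRCA of the LOST leaves in its subtree
.mrca_of_lost <- function(tree, v, lost_cnt) {
  target <- lost_cnt[v]
  repeat {
    ch <- tree$children[[v]]
    nxt <- ch[lost_cnt[ch] == target]
    if (length(nxt) != 1L) return(v)
    v <- nxt
  }
}

#' Classify a set of inferred loss branches
#'
#' Counts how many different branches carry a loss and labels the CNE:
#' no branch -> `no_loss`; one branch -> `lineage_specific`; two or more
#' branches (each pair separated by at least one conserving species) ->
#' `independent` with multiplicity k.
#'
#' @param branches character vector of branch names as returned by
#'   [infer_loss_branches()] for a single CNE.
#' @param tree a `cne_phylo`.
#' @return list with `label` (`no_loss`, `lineage_specific` or `independent`),
#'   `k` (number of loss branches) and `n_independent` (k when k >= 2, else 0).
#' @export
count_independent <- function(branches, tree) {
  stopifnot(inherits(tree, "cne_phylo"))
  if (length(branches) == 0L)
    return(list(label = "no_loss", k = 0L, n_independent = 0L))
  ids <- .node_id(tree, branches)
  if (length(ids) > 1L) {
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j &&
          any(tree$leaf_mat[ids[i], ] > 0 & tree$leaf_mat[ids[j], ] > 0))
        stop("branches overlap (not from a single inference call): ",
             branches[i], " / ", branches[j])
    }
  }
  if (length(ids) == 1L)
    return(list(label = "lineage_specific", k = 1L, n_independent = 0L))
  list(label = "independent", k = length(ids), n_independent = length(ids))
}

#' Is a set of branches a valid independent-loss combination?
#'
#' The single source of truth for "independent lineage combinations": a
#' combination of branches is valid for a CNE with a given missing-data set
#' iff (a) no leaf below any branch of the combination is missing, and (b)
#' labeling all leaves below the combination LOST and all other non-missing
#' leaves CONSERVED, parsimony re-inference returns exactly this combination.
#' For example, mouse + rat is never valid (parsimony merges the two losses
#' into a single loss in the mouse-rat ancestor), and mouse-rat ancestor +
#' guinea pig requires conservation of a species between them (for the
#' mammalian tree, kangaroo rat).
#'
#' @param tree a `cne_phylo`.
#' @param combo non-empty character vector of distinct branch names.
#' @param missing character vector of leaf names with missing data.
#' @param rule tie rule passed to [infer_loss_branches()].
#' @return TRUE or FALSE.
#' @export
is_valid_combination <- function(tree, combo, missing = character(),
                                 rule = "ancestral") {
  stopifnot(inherits(tree, "cne_phylo"), length(combo) >= 1L)
  if (anyDuplicated(combo)) stop("branches in a combination must be distinct")
  ids <- .node_id(tree, combo)
  if (length(missing)) .node_id(tree, missing)  # validate names
  below <- unique(unlist(tree$leaves_below[ids]))
  tips <- tree$ape$tip.label
  # a loss cannot be called above a non-loss-search leaf
  if (any(tree$leaf_roles[below] != "loss_search")) return(FALSE)
  miss_id <- match(intersect(missing, tips), tips)
  if (any(below %in% miss_id)) return(FALSE)
  sv <- setNames(rep(STATUS_CONSERVED, tree$n_tip), tips)
  sv[below] <- STATUS_LOST
  sv[miss_id] <- STATUS_MISSING
  if (!any(sv == STATUS_CONSERVED)) return(FALSE)
  inferred <- tryCatch(infer_loss_branches(sv, tree, rule = rule),
                       error = function(e) NULL)
  !is.null(inferred) && setequal(inferred, combo)
}

#' Enumerate all valid independent-loss combinations
#'
#' All k-subsets of loss-search-capable branches that form a valid
#' independent combination (with no missing data), in deterministic order
#' (branch names sorted within a combination, combinations sorted
#' lexicographically).
#'
#' @param tree a `cne_phylo`.
#' @param k 2 or 3 independent losses.
#' @return list of character vectors.
#' @export
enumerate_valid_combinations <- function(tree, k) {
  stopifnot(inherits(tree, "cne_phylo"), k %in% c(2L, 3L))
  br <- loss_capable_branches(tree)
  if (length(br) < k) return(list())
  combos <- combn(br, k, simplify = FALSE)
  Filter(function(cc) is_valid_combination(tree, cc), combos)
}

# chain of nodes from v up to the root, inclusive of v
.ancestors <- function(tree, v) {
  out <- v
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[v]
    out <- c(out, v)
  }
  out
}

# Sum of branch lengths along the path from ancestor node `from` down to the
# child node identifying `branch`. NA when `branch` is not below `from`.
.path_length <- function(tree, from_id, branch_id) {
  tot <- 0
  v <- branch_id
  while (!is.na(v) && v != from_id) {
    tot <- tot + tree$branch_length[v]
    v <- tree$parent[v]
  }
  if (is.na(v)) NA_real_ else tot
}
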