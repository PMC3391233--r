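# Neighbor-joining phylogeny from protein alignments, bootstrap support,
# supported-clade grouping, and sister-pair extraction. Trees are ape
# "phylo" objects (unrooted, represented rooted at a trifurcation).

#' Coerce and validate an alignment
#'
#' @param x Named character vector of equal-length aligned rows, an
#'   `AAStringSet`, or a FASTA path. Gaps are `-`.
#' @return Named character vector (upper case).
#' @export
as_alignment <- function(x) {
  aln <- as_seq_vector(x, "AA")
  if (length(unique(nchar(aln))) != 1) {
    abort("alignment rows must all have equal length")
  }
  aln
}

#' Uncorrected pairwise distances with pairwise deletion
#'
#' For each pair of rows, the distance is the proportion of mismatches over
#' the columns where both rows are ungapped. Pairs with zero comparable
#' columns are flagged as undefined (`NA`) with a warning; a tree cannot be
#' built from them.
#'
#' @param alignment See [as_alignment()].
#' @param model `"p"` for the uncorrected proportion (default) or
#'   `"poisson"` for the Poisson correction `-log(1 - p)`.
#' @return A symmetric distance matrix with attribute `sites` (per-pair
#'   compared-column counts).
#' @export
p_distance <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  aln <- as_alignment(alignment)
  if (length(aln) < 2) abort("need at least 2 taxa")
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  sites <- matrix(nchar(aln[1]), n, n,
                  dimnames = dimnames(d))
  undefined <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      ns <- sum(ok)
      sites[i, j] <- sites[j, i] <- ns
      if (ns == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        undefined <- c(undefined,
                       paste(names(aln)[c(i, j)], collapse = "/"))
      } else {
        p <- sum(m[i, ok] != m[j, ok]) / ns
        if (model == "poisson") p <- -log(1 - p)
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  if (length(undefined)) {
    warn(sprintf("undefined distances (no comparable sites): %s",
                 paste(undefined, collapse = ", ")))
  }
  attr(d, "sites") <- sites
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Classic neighbor joining on a symmetric distance matrix. Ties in the Q
#' criterion break deterministically on the lexicographically lowest pair of
#' cluster labels (a cluster is labeled by its alphabetically first taxon).
#' Negative branch-length estimates are clamped to zero with the deficit
#' transferred to the sibling edge, so path lengths are conserved. On an
#' additive matrix the returned tree's path metric reproduces the input
#' exactly.
#'
#' @param D Symmetric distance matrix with taxon dimnames (e.g. from
#'   [p_distance()]).
#' @return An unrooted `phylo` object (trifurcating root representation).
#' @export
neighbor_joining <- function(D) {
  if (anyNA(D)) {
    und <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    abort(sprintf("cannot build a tree: undefined distances for %s",
                  paste(rownames(D)[und[, 1]], colnames(D)[und[, 2]],
                        sep = "/", collapse = ", ")))
  }
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) abort("distance matrix needs taxon dimnames")
  # active clusters: newick fragment + representative (min) taxon label
  node_str <- labs
  node_rep <- labs
  d <- D
  fmt <- function(x) sprintf("%.15g", x)
  while (length(node_str) > 3) {
    k <- nrow(d)
    r <- rowSums(d)
    q <- (k - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= abs(qmin) * 1e-12 + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(z) {
      paste(sort(c(node_rep[cand[z, 1]], node_rep[cand[z, 2]])),
            collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    new_str <- sprintf("(%s:%s,%s:%s)",
                       node_str[i], fmt(vi), node_str[j], fmt(vj))
    new_rep <- min(node_rep[c(i, j)])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node_str <- c(node_str[keep], new_str)
    node_rep <- c(node_rep[keep], new_rep)
  }
  # final trifurcation: closed-form three-path solution
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(la, lb, lc), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node_str[1], fmt(v[1]), node_str[2], fmt(v[2]),
                 node_str[3], fmt(v[3]))
  ape::read.tree(text = nwk)
}

# canonical bipartition keys for the internal (non-root) nodes of a tree;
# the key is the tip side not containing the alphabetically first taxon
bipartition_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  universe <- sort(tree$tip.label)
  ref <- universe[1]
  pp <- ape::prop.part(tree)
  root <- ntip + 1L
  nodes <- setdiff(seq_len(tree$Nnode) + ntip, root)
  keys <- vapply(nodes, function(nd) {
    tips <- tree$tip.label[pp[[nd - ntip]]]
    side <- if (ref %in% tips) setdiff(universe, tips) else tips
    paste(sort(side), collapse = "|")
  }, character(1))
  setNames(keys, nodes)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, re-runs distance + neighbor
#' joining, and annotates each internal edge with the percentage of
#' replicate trees containing the same leaf bipartition. Replicates whose
#' resampled columns leave some pair with no comparable sites are dropped.
#'
#' @inheritParams p_distance
#' @param n_reps Bootstrap replicates (0 leaves support undefined).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @return A `phylo` with `node.label` carrying support (percent, `NA` at
#'   the root) and attribute `n_reps_used`.
#' @export
bootstrap_nj <- function(alignment, n_reps = 1000, seed = 1,
                         model = c("p", "poisson")) {
  model <- match.arg(model)
  aln <- as_alignment(alignment)
  tree <- neighbor_joining(p_distance(aln, model))
  ntip <- length(tree$tip.label)
  keys <- bipartition_keys(tree)
  counts <- setNames(rep(0L, length(keys)), keys)
  used <- 0L
  if (n_reps > 0) {
    m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    L <- ncol(m)
    withr::with_seed(seed, {
      for (rep in seq_len(n_reps)) {
        cols <- sample.int(L, L, replace = TRUE)
        res <- setNames(apply(m[, cols, drop = FALSE], 1, paste,
                              collapse = ""), names(aln))
        dmat <- suppressWarnings(p_distance(res, model))
        if (anyNA(dmat)) next
        rk <- bipartition_keys(neighbor_joining(dmat))
        used <- used + 1L
        hit <- intersect(keys, rk)
        counts[hit] <- counts[hit] + 1L
      }
    })
  }
  support <- rep(NA_real_, tree$Nnode)
  smap <- rep(NA_real_, length(keys))
  if (used > 0) {
    node_ids <- as.integer(names(keys))
    support[node_ids - ntip] <- 100 * counts / used
    smap <- 100 * counts / used
  }
  tree$node.label <- support
  attr(tree, "support_map") <- setNames(smap, unname(keys))
  attr(tree, "n_reps_used") <- used
  tree
}

# named support vector keyed by canonical bipartition, from the stored map
# or reconstructed from node labels
support_map <- function(tree) {
  sm <- attr(tree, "support_map")
  if (!is.null(sm)) return(sm)
  if (is.null(tree$node.label)) abort("tree carries no support values")
  ntip <- length(tree$tip.label)
  keys <- bipartition_keys(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  setNames(sup[as.integer(names(keys)) - ntip], unname(keys))
}

# canonical key for an arbitrary tip set
split_key <- function(tips, universe) {
  side <- if (universe[1] %in% tips) setdiff(universe, tips) else tips
  paste(sort(side), collapse = "|")
}

node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  unlist(lapply(node_children(tree, node), node_tips, tree = tree))
}

#' Assign family groups from supported clades
#'
#' Groups are the maximal clades whose subtending edge's bipartition
#' support passes the threshold (strict `>` by default, `>=` with
#' `inclusive = TRUE`), discovered top-down from the tree's root; taxa in
#' no such clade are labeled `"ungrouped"`. Neighbor-joining trees are
#' traversed from their natural trifurcating root, which for a family with
#' three or more well-separated subfamilies sits on the backbone, so each
#' subfamily surfaces as its own maximal clade.
#'
#' @param tree A `phylo` from [bootstrap_nj()] (or any tree with numeric
#'   `node.label` support in percent).
#' @param threshold Support threshold in percent.
#' @param inclusive Use `>=` instead of strict `>`.
#' @return Tibble (`taxon`, `group`), groups labeled G1, G2, ... in
#'   traversal order.
#' @export
assign_groups <- function(tree, threshold = 50, inclusive = FALSE) {
  smap <- support_map(tree)
  universe <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  passes <- function(tips) {
    s <- smap[split_key(tips, universe)]
    !is.na(s) && if (inclusive) s >= threshold else s > threshold
  }
  groups_under <- function(rooted) {
    group <- setNames(rep("ungrouped", ntip), rooted$tip.label)
    counter <- 0L
    visit <- function(node) {
      for (ch in node_children(rooted, node)) {
        if (ch > ntip) {
          tips <- rooted$tip.label[node_tips(rooted, ch)]
          if (length(tips) < ntip && passes(tips)) {
            counter <<- counter + 1L
            group[tips] <<- sprintf("G%d", counter)
          } else {
            visit(ch)
          }
        }
      }
    }
    visit(ntip + 1L)
    group[universe]
  }
  # an unrooted tree gives no preferred root: evaluate rooting at every
  # internal node and on every internal edge, keep the rooting that leaves
  # the fewest taxa ungrouped and then yields the most groups
  bare <- tree
  bare$node.label <- NULL
  candidates <- list(bare)
  for (nd in seq_len(tree$Nnode) + ntip) {
    if (nd != ntip + 1L) {
      candidates[[length(candidates) + 1L]] <-
        tryCatch(ape::root(bare, node = nd), error = function(e) NULL)
      side <- bare$tip.label[node_tips(bare, nd)]
      candidates[[length(candidates) + 1L]] <-
        tryCatch(ape::root(bare, outgroup = side, resolve.root = TRUE),
                 error = function(e) NULL)
    }
  }
  candidates <- keep(candidates, Negate(is.null))
  best <- NULL
  best_score <- c(Inf, -Inf)
  for (cand in candidates) {
    g <- groups_under(cand)
    score <- c(sum(g == "ungrouped"), -length(setdiff(unique(g), "ungrouped")))
    if (score[1] < best_score[1] ||
        (score[1] == best_score[1] && score[2] < best_score[2])) {
      best <- g
      best_score <- score
    }
  }
  out <- tibble(taxon = names(best), group = unname(best))
  arrange(out, match(.data$taxon, tree$tip.label))
}

#' Extract sister pairs (cherries)
#'
#' For an unrooted tree (the usual neighbor-joining output) a sister pair
#' is a two-taxon side of an internal bipartition, which does not depend on
#' the arbitrary stored rooting; for a genuinely rooted tree it is a
#' two-leaf clade.
#'
#' @param tree A `phylo`, with or without support labels.
#' @return Tibble (`taxon_a`, `taxon_b`, `support`) — one row per cherry,
#'   alphabetical within pair.
#' @export
sister_pairs <- function(tree) {
  ntip <- length(tree$tip.label)
  universe <- sort(tree$tip.label)
  smap <- tryCatch(support_map(tree), error = function(e) NULL)
  sides <- list()
  if (ape::is.rooted(tree)) {
    for (nd in seq_len(tree$Nnode) + ntip) {
      ch <- node_children(tree, nd)
      if (length(ch) == 2 && all(ch <= ntip)) {
        side <- tree$tip.label[ch]
        sides[[paste(sort(side), collapse = "|")]] <-
          list(pair = sort(side), key = split_key(side, universe))
      }
    }
  } else {
    pp <- ape::prop.part(tree)
    root <- ntip + 1L
    for (nd in setdiff(seq_len(tree$Nnode) + ntip, root)) {
      tips <- tree$tip.label[pp[[nd - ntip]]]
      for (side in list(tips, setdiff(universe, tips))) {
        if (length(side) == 2) {
          sides[[paste(sort(side), collapse = "|")]] <-
            list(pair = sort(side), key = split_key(side, universe))
        }
      }
    }
  }
  if (!length(sides)) {
    return(tibble(taxon_a = character(), taxon_b = character(),
                  support = numeric()))
  }
  out <- tibble(
    taxon_a = unname(map_chr(sides, ~.x$pair[1])),
    taxon_b = unname(map_chr(sides, ~.x$pair[2])),
    support = if (is.null(smap)) NA_real_ else
      unname(smap[map_chr(sides, "key")])
  )
  arrange(out, .data$taxon_a, .data$taxon_b)
}

#' Write a tree as newick with support as internal node labels
#'
#' @param tree A `phylo` (support in `node.label`, optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_support_tree <- function(tree, path) {
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(lab), "", format(round(lab, 1)))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
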