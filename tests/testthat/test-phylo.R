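# Distances with pairwise deletion, neighbor joining, bootstrap support,
# grouping and sister pairs.

test_that("p-distance counts mismatches over pairwise-deleted columns", {
  aln <- c(s1 = "AAAA", s2 = "AAAA")
  expect_equal(p_distance(aln)["s1", "s2"], 0)

  aln2 <- c(s1 = "AAAA", s2 = "AATT")
  expect_equal(p_distance(aln2)["s1", "s2"], 0.5)

  aln3 <- c(s1 = "A-CD", s2 = "AAC-")
  d3 <- p_distance(aln3)
  expect_equal(d3["s1", "s2"], 0)
  expect_equal(attr(d3, "sites")["s1", "s2"], 2)

  # Poisson correction: -log(1 - p)
  expect_equal(p_distance(aln2, model = "poisson")["s1", "s2"], -log(0.5))
})

test_that("pairs with no comparable sites are flagged and block tree building", {
  aln <- c(s1 = "AA--", s2 = "--AA", s3 = "AAAA")
  expect_warning(d <- p_distance(aln), "s1/s2")
  expect_true(is.na(d["s1", "s2"]))
  expect_error(neighbor_joining(d), "undefined")
})

test_that("three-taxon trees solve the path equations in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  pm <- ape::cophenetic.phylo(tree)
  expect_equal(pm[rownames(d), colnames(d)], d, tolerance = 1e-12)
  # closed form: la = (dAB + dAC - dBC)/2 = 1, lb = 2, lc = 3
  lens <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("a four-taxon additive matrix is recovered with topology and lengths", {
  # cherries (A,B) and (C,D), internal edge 1.0
  true <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:1):0.5);")
  d <- ape::cophenetic.phylo(true)
  tree <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  pairs <- sister_pairs(tree)
  expect_equal(pairs$taxon_a, c("A", "C"))
  expect_equal(pairs$taxon_b, c("B", "D"))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("random additive matrices are reproduced exactly (path metric and topology)", {
  withr::with_seed(31, {
    for (i in 1:20) {
      ref <- random_additive_matrix(8)
      tree <- neighbor_joining(ref$d)
      expect_equal(ape::cophenetic.phylo(tree)[rownames(ref$d),
                                               colnames(ref$d)],
                   ref$d, tolerance = 1e-8)
      expect_equal(phangorn::RF.dist(tree, ref$tree), 0)
      expect_true(all(tree$edge.length >= 0))
    }
  })
})

test_that("our neighbor joining agrees topologically with the ape reference", {
  withr::with_seed(17, {
    for (i in 1:10) {
      ref <- random_additive_matrix(9)
      mine <- neighbor_joining(ref$d)
      theirs <- ape::nj(ref$d)
      expect_equal(phangorn::RF.dist(mine, theirs), 0)
    }
  })
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  aln <- generate_alignment(list(A = c("t1", "t2", "t3"),
                                 B = c("t4", "t5", "t6")),
                            length = 150, n_mutations = 4, seed = 3)
  t1 <- bootstrap_nj(aln$alignment, n_reps = 200, seed = 11)
  t2 <- bootstrap_nj(aln$alignment, n_reps = 200, seed = 11)
  expect_identical(attr(t1, "support_map"), attr(t2, "support_map"))

  t0 <- bootstrap_nj(aln$alignment, n_reps = 0, seed = 11)
  expect_true(all(is.na(t0$node.label)))
})

test_that("perfectly congruent signal yields full support on planted edges", {
  # two clades separated by many fixed differences in every column block
  aln <- generate_alignment(list(A = c("t1", "t2", "t3"),
                                 B = c("t4", "t5", "t6")),
                            length = 300, n_mutations = 2, seed = 5)
  tree <- bootstrap_nj(aln$alignment, n_reps = 100, seed = 2)
  smap <- attr(tree, "support_map")
  key <- paste(sort(c("t4", "t5", "t6")), collapse = "|")
  expect_equal(unname(smap[key]), 100)
})

test_that("supports are invariant to taxon input order", {
  aln <- generate_alignment(list(A = c("t1", "t2", "t3"),
                                 B = c("t4", "t5", "t6")),
                            length = 200, n_mutations = 4, seed = 9)$alignment
  t_fwd <- bootstrap_nj(aln, n_reps = 100, seed = 4)
  t_rev <- bootstrap_nj(rev(aln), n_reps = 100, seed = 4)
  key <- paste(sort(c("t4", "t5", "t6")), collapse = "|")
  # the planted deep bipartition is certain either way
  expect_equal(unname(attr(t_fwd, "support_map")[key]),
               unname(attr(t_rev, "support_map")[key]))
})

test_that("grouping recovers planted clades and respects the threshold", {
  clades <- list(G1 = paste0("a", 1:4), G2 = paste0("b", 1:4),
                 G3 = paste0("c", 1:4))
  aln <- generate_alignment(clades, length = 300, n_mutations = 3, seed = 13)
  tree <- bootstrap_nj(aln$alignment, n_reps = 200, seed = 6)
  groups <- assign_groups(tree, threshold = 50)
  joined <- dplyr::left_join(groups, aln$plan, by = "taxon")
  # each planted clade maps onto exactly one recovered group
  tab <- table(joined$clade, joined$group)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(length(unique(joined$group)), 3)

  # all supports below threshold -> everything ungrouped
  low <- tree
  attr(low, "support_map")[] <- 10
  all_un <- assign_groups(low, threshold = 50)
  expect_true(all(all_un$group == "ungrouped"))

  # strict vs inclusive threshold at the boundary
  edge <- tree
  attr(edge, "support_map")[] <- 50
  expect_true(all(assign_groups(edge, threshold = 50)$group == "ungrouped"))
  expect_false(all(assign_groups(edge, threshold = 50,
                                 inclusive = TRUE)$group == "ungrouped"))
})

test_that("sister pairs are read correctly from rooted and unrooted trees", {
  rooted <- ape::read.tree(text = "(((A,B),C),D);")
  expect_equal(nrow(sister_pairs(rooted)), 1)
  expect_equal(sister_pairs(rooted)$taxon_a, "A")

  both <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(nrow(sister_pairs(both)), 2)

  # planted cherries in a larger unrooted tree are recovered exactly
  withr::with_seed(8, {
    clades <- setNames(lapply(1:10, function(i) {
      paste0("t", i, c("x", "y"))
    }), paste0("cl", 1:10))
    aln <- generate_alignment(clades, length = 400, n_mutations = 2,
                              seed = 44)
    tree <- neighbor_joining(p_distance(aln$alignment))
    pairs <- sister_pairs(tree)
    planted <- t(vapply(clades, sort, character(2)))
    found <- paste(pairs$taxon_a, pairs$taxon_b)
    expect_true(all(paste(planted[, 1], planted[, 2]) %in% found))
  })
})

test_that("newick output carries supports as internal node labels", {
  aln <- generate_alignment(list(A = c("t1", "t2"), B = c("t3", "t4")),
                            length = 100, n_mutations = 2, seed = 1)
  tree <- bootstrap_nj(aln$alignment, n_reps = 50, seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, paste0("t", 1:4))
  expect_true(any(back$node.label != ""))
})
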