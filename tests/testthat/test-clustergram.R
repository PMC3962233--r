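test_that("ward_cluster handles the elementary geometries", {
  # identical rows merge first at height 0
  M <- rbind(c(1, 0), c(1, 0), c(0, 1))
  tr <- ward_cluster(M)
  expect_equal(tr$height[1], 0)
  expect_identical(tree_member_sets(tr)[[1]], c(1L, 2L))
  # separated pairs on a line: {0,1} then {10,11}
  tr2 <- ward_cluster(matrix(c(0, 1, 10, 11), 4, 1))
  ms <- tree_member_sets(tr2)
  expect_identical(ms[[1]], c(1L, 2L))
  expect_identical(ms[[2]], c(3L, 4L))
  expect_error(ward_cluster(matrix(1, 1, 2)), "two rows")
})

test_that("merge sequence equals the exhaustive Ward-objective oracle", {
  set.seed(1)
  for (r in 1:40) {
    M <- matrix(rbinom(sample(5:7, 1) * 4, 1, 0.5), ncol = 4)
    tr <- ward_cluster(M)
    br <- ward_brute(M)
    expect_equal(tr$height, br$heights, tolerance = 1e-7)
    expect_identical(tree_member_sets(tr), br$merges)
    expect_true(all(diff(tr$height) >= -1e-10))  # Ward monotonicity
  }
})

test_that("clustering is invariant to row shuffling up to relabeling", {
  set.seed(2)
  M <- matrix(rbinom(8 * 5, 1, 0.4), 8, 5,
              dimnames = list(paste0("R", 1:8), NULL))
  coph <- function(tree) {
    sets <- tree_member_sets(tree)
    n <- length(tree$labels)
    D <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
    for (s in seq_along(sets)) {
      mem <- sets[[s]]
      for (i in mem) for (j in mem) {
        if (D[tree$labels[i], tree$labels[j]] == 0 && i != j)
          D[tree$labels[i], tree$labels[j]] <- tree$height[s]
      }
    }
    D
  }
  perm <- sample(8)
  a <- coph(ward_cluster(M))
  b <- coph(ward_cluster(M[perm, ]))
  expect_equal(a, b[rownames(a), colnames(a)], tolerance = 1e-10)
})

test_that("clustergram reorders without loss and drops empty rows", {
  S <- diag(3)
  dimnames(S) <- list(paste0("A", 1:3), paste0("E", 1:3))
  cg <- clustergram(S)
  expect_setequal(cg$row_order, rownames(S))
  expect_equal(sort(as.vector(cg$matrix)), sort(as.vector(S)))  # permutation only
  # block structure: all-ones "general" rows split from specific rows
  S2 <- rbind(gen1 = rep(1, 4), gen2 = rep(1, 4),
              sp1 = c(1, 0, 0, 0), sp2 = c(1, 0, 0, 0),
              sp3 = c(0, 0, 1, 0), none = rep(0, 4))
  colnames(S2) <- paste0("E", 1:4)
  expect_message(cg2 <- clustergram(S2), "dropping 1")
  # the final merge joins the general block to the specific block
  lab <- cg2$row_tree$labels
  first_group <- tree_member_sets(cg2$row_tree)
  sizes <- lengths(first_group)
  split_members <- lapply(cg2$row_tree$merge[nrow(cg2$row_tree$merge), ],
                          function(nd) if (nd < 0) lab[-nd] else lab[first_group[[nd]]])
  expect_true(setequal(split_members[[1]], c("gen1", "gen2")) ||
              setequal(split_members[[2]], c("gen1", "gen2")))
  expect_error(clustergram(matrix(0, 3, 3)), "fewer than 2")
})

test_that("newick serialization round-trips through ape", {
  skip_if_not_installed("ape")
  M <- rbind(A = c(0, 0), B = c(0, 1), C = c(4, 4), D = c(4, 5))
  tr <- ward_cluster(M)
  nwk <- to_newick(tr)
  expect_match(nwk, ";$")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, rownames(M))
  # two-leaf minimal case: "(A:h,B:h);"
  t2 <- ward_cluster(M[1:2, ])
  expect_identical(to_newick(t2), sprintf("(A:%s,B:%s);",
                                          format(t2$height, digits = 10),
                                          format(t2$height, digits = 10)))
  # topology preserved: sister pairs match the merge sets
  sets <- lapply(tree_member_sets(tr), function(s) sort(rownames(M)[s]))
  expect_true(setequal(sets[[1]], c("A", "B")))
})
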