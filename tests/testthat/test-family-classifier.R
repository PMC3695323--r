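test_that("global alignment statistics are exact on hand-checkable cases", {
  self <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(self$identity, 1.0)
  expect_equal(self$P, 0)
  expect_equal(self$Q, 0)
  # one transversion column (T <-> A)
  aln <- global_align("ACGT", "ACGA")
  expect_equal(aln$identity, 0.75)
  expect_equal(aln$Q, 0.25)
  expect_equal(aln$P, 0)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment score matches an independent dynamic-programming oracle", {
  set.seed(131)
  for (i in 1:50) {
    la <- sample(30:200, 1); lb <- sample(30:200, 1)
    a <- random_dna(la); b <- random_dna(lb)
    expect_equal(global_align(a, b)$score, oracle_score(a, b))
  }
})

test_that("80-80-80 clustering matches a brute-force component oracle", {
  # A and B at ~90% identity over full length; C unrelated
  set.seed(141)
  a <- random_dna(100)
  b <- a
  for (p in sample(100, 10)) substr(b, p, p) <-
      sample(setdiff(c("A", "C", "G", "T"), substr(a, p, p)), 1)
  cc <- random_dna(100)
  fams <- cluster_families(c(A = a, B = b, C = cc))
  part <- split(fams$membership$element_id, fams$membership$family_id)
  expect_setequal(lapply(part, sort), list(c("A", "B"), "C"))

  # brute-force oracle: thresholded pairwise graph -> connected components
  seqs <- c(A = a, B = b, C = cc)
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    g <- global_align(seqs[[i]], seqs[[j]])
    adj[i, j] <- adj[j, i] <- g$identity >= 0.8 && g$coverage >= 0.8
  }
  reach <- diag(TRUE, n) | adj
  for (k in 1:n) reach <- reach | (reach %*% reach > 0)
  oracle_comp <- apply(reach, 1, function(r) min(which(r)))
  mine_comp <- fams$membership$family_id[match(names(seqs),
                                               fams$membership$element_id)]
  expect_equal(length(unique(oracle_comp)), length(unique(mine_comp)))
  expect_true(all(outer(mine_comp, mine_comp, "==") ==
                    outer(oracle_comp, oracle_comp, "==")))
})

test_that("synthetic families are recovered with correct membership", {
  sims <- lapply(1:3, function(f)
    generate_family(family_spec(family_id = sprintf("T%d", f),
                                divergence = 0.05, indel_rate = 0.002),
                    5, seed = 150 + f))
  elements <- do.call(rbind, lapply(sims, `[[`, "copies"))
  fams <- cluster_families(elements)
  expect_equal(length(fams$families), 3)
  m <- merge(fams$membership, elements[, c("copy_id", "family_id")],
             by.x = "element_id", by.y = "copy_id")
  tab <- table(m$family_id.x, m$family_id.y)
  expect_true(all(rowSums(tab > 0) == 1))  # each cluster is one true family
  # invariant under input permutation
  set.seed(160)
  perm <- cluster_families(elements[sample(nrow(elements)), ])
  part <- function(f) unname(lapply(
    split(f$membership$element_id, f$membership$family_id), sort))
  expect_setequal(part(perm), part(fams))
  expect_error(cluster_families(character(0)), "empty")
})

test_that("consensus building votes by majority with IUPAC ties", {
  expect_equal(build_consensus(c(x = "ACGTACGT")), "ACGTACGT")
  # T/C tie at one column -> Y
  seqs <- c(rep("ACGTTCGATT", 3), rep("ACGTCCGATT", 3))
  names(seqs) <- sprintf("s%d", 1:6)
  expect_equal(build_consensus(seqs), "ACGTYCGATT")
  # round trip: consensus of diverged copies is nearly the true consensus
  fam <- generate_family(family_spec(divergence = 0.05, indel_rate = 0.002),
                         10, seed = 171)
  rebuilt <- build_consensus(setNames(fam$copies$seq, fam$copies$copy_id))
  expect_gte(global_align(rebuilt, fam$consensus)$identity, 0.99)
})

test_that("K2P distance follows the closed form and its domain", {
  expect_equal(k2p_distance(0, 0), 0)
  # independent arithmetic: -1/2 log(1-2P-Q) - 1/4 log(1-2Q)
  expect_equal(k2p_distance(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-10)
  expect_equal(round(k2p_distance(0.1, 0.05), 5), 0.17018)
  expect_error(k2p_distance(0.5, 0), class = "k2p_saturation")
  # grid check against the independent form, plus strict monotonicity
  grid <- expand.grid(P = seq(0, 0.3, by = 0.05), Q = seq(0, 0.3, by = 0.05))
  grid <- grid[1 - 2 * grid$P - grid$Q > 1e-6 & 1 - 2 * grid$Q > 1e-6, ]
  d <- mapply(k2p_distance, grid$P, grid$Q)
  ref <- -0.5 * log(1 - 2 * grid$P - grid$Q) - 0.25 * log(1 - 2 * grid$Q)
  expect_true(all(abs(d - ref) < 1e-5))
  eps <- 1e-4
  for (r in sample(nrow(grid), 10)) {
    if (1 - 2 * (grid$P[r] + eps) - grid$Q[r] > 0)
      expect_gt(k2p_distance(grid$P[r] + eps, grid$Q[r]), d[r])
    if (1 - 2 * (grid$Q[r] + eps) > 0 && 1 - 2 * grid$P[r] - grid$Q[r] - eps > 0)
      expect_gt(k2p_distance(grid$P[r], grid$Q[r] + eps), d[r])
  }
})

test_that("neighbor joining is exact on small and additive inputs", {
  # 2 taxa: the single edge of length d (stored as two d/2 branches)
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(d2)
  expect_equal(sum(t2$edge.length), 0.3)
  expect_equal(unname(ape::cophenetic.phylo(t2)["a", "b"]), 0.3)
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3["a", "b"] <- d3["b", "a"] <- 0.4
  d3["a", "c"] <- d3["c", "a"] <- 0.6
  d3["b", "c"] <- d3["c", "b"] <- 0.8
  t3 <- neighbor_joining(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.4 + 0.6 - 0.8) / 2)
  expect_equal(unname(bl["b"]), (0.4 + 0.8 - 0.6) / 2)
  expect_equal(unname(bl["c"]), (0.6 + 0.8 - 0.4) / 2)
  expect_error(neighbor_joining(matrix(c(0, -1, -1, 0), 2)), "negative")

  # additive matrices from random trees are reproduced exactly
  set.seed(191)
  for (n in c(5, 8, 10)) {
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
    mine <- neighbor_joining(dm)
    back <- ape::cophenetic.phylo(mine)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(back - dm)), 1e-9)
    # topology agrees with the independent NJ implementation in ape
    ref <- ape::nj(as.dist(dm))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("newick serialization round-trips losslessly", {
  set.seed(201)
  dm <- ape::cophenetic.phylo(ape::rtree(6))
  tree <- neighbor_joining(dm)
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, tmp)
  again <- ape::read.tree(tmp)
  expect_identical(ape::write.tree(again), ape::write.tree(tree))
  expect_setequal(again$tip.label, tree$tip.label)
})

test_that("TIR consensus reports degenerate codes and the conserved run", {
  # identical TIRs: consensus equals them, run = full length
  same <- c(F1 = "CTCCCTACGT", F2 = "CTCCCTACGT")
  tc <- tir_consensus(same)
  expect_equal(tc$consensus, "CTCCCTACGT")
  expect_equal(tc$conserved_terminal_run, 10L)
  # {A, G} column -> R; {T, C} -> Y
  tc2 <- tir_consensus(c(F1 = "CTCCCTAT", F2 = "CTCCCTGC"))
  expect_equal(tc2$consensus, "CTCCCTRY")
  expect_equal(tc2$conserved_terminal_run, 6L)
  # synthetic families sharing the planted terminus conserve >= 6 columns
  tirs <- vapply(1:4, function(f) {
    fam <- generate_family(family_spec(family_id = sprintf("G%d", f)), 1,
                           seed = 210 + f)
    substr(fam$consensus, 1, 16)
  }, "")
  names(tirs) <- sprintf("G%d", 1:4)
  expect_gte(tir_consensus(tirs)$conserved_terminal_run, 6L)
  expect_error(tir_consensus(c(F1 = "")), "left-TIR")
})
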