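test_that("SSC descriptors handle constant images and are contrast invariant", {
  flat <- ImageVolume(array(7, rep(10, 3)))
  dsc <- sscDescriptor(flat)
  expect_true(all(dsc@codes == 0L))   # ties binarise to 0
  img <- ImageVolume(withr::with_seed(31, array(rnorm(12^3, 100, 50),
                                                rep(12, 3))))
  d1 <- sscDescriptor(img)
  d2 <- sscDescriptor(img)
  expect_identical(d1@codes, d2@codes)
  # affine intensity rescaling a*I + b with a > 0 leaves descriptors intact
  resc <- ImageVolume(2.7 * voxels(img) + 113)
  expect_identical(sscDescriptor(resc)@codes, d1@codes)
  expect_error(sscDescriptor(ImageVolume(array(0, c(3, 3, 3)))), "small")
})

test_that("unary costs vanish for the true shift and respect the bit bound", {
  img <- ImageVolume(withr::with_seed(32, array(rnorm(20^3, 0, 30),
                                                rep(20, 3))))
  dsc <- sscDescriptor(img)
  cps <- rbind(c(10, 10, 10), c(8, 12, 9))
  labels <- displacementLabels(2L, 1L)
  costs <- unaryCosts(dsc, dsc, cps, labels)
  zi <- which(labels[, 1] == 0 & labels[, 2] == 0 & labels[, 3] == 0)
  expect_equal(costs[, zi], c(0, 0))
  expect_true(all(costs[is.finite(costs)] >= 0))
  expect_true(all(costs[is.finite(costs)] <= 12))
  # target = reference shifted: argmin at the constructed shift
  arr <- voxels(img)
  sh <- array(0, dim(arr))
  sh[3:20, , ] <- arr[1:18, , ]
  dscT <- sscDescriptor(ImageVolume(sh))
  costsT <- unaryCosts(dsc, dscT, rbind(c(10, 10, 10)), labels)
  best <- labels[which.min(costsT), ]
  expect_equal(unname(unlist(best)), c(2, 0, 0))
  expect_error(unaryCosts(dsc, dsc, cps, labels[0, , drop = FALSE]),
               "empty")
})

test_that("the MST of a chain is the chain and edge count is n-1", {
  tree <- buildMst(c(5L, 1L, 1L), nodeValues = c(5, 4, 7, 1, 2))
  expect_equal(sum(!is.na(tree$parent)), 4L)
  # chain topology: each node's parent is its lattice neighbour
  for (i in 2:5) expect_true(abs(tree$parent[i] - i) == 1)
  expect_error(buildMst(c(2L, 2L, 1L), nodeValues = 1:3), "length")
})

test_that("small-lattice MST matches exhaustive spanning-tree enumeration", {
  # 2x2 lattice: 4 nodes, 4 edges, spanning trees = all 3-edge acyclic sets
  vals <- withr::with_seed(33, runif(4, 0, 10))
  tree <- buildMst(c(2L, 2L, 1L), vals)
  w <- function(a, b) abs(vals[a] - vals[b])
  edges <- rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  combs <- combn(4, 3)
  best <- Inf
  for (ci in seq_len(ncol(combs))) {
    es <- edges[combs[, ci], , drop = FALSE]
    g <- igraph::graph_from_edgelist(es, directed = FALSE)
    if (igraph::vcount(g) < 4 || !igraph::is_connected(g)) next
    best <- min(best, sum(apply(es, 1, function(e) w(e[1], e[2]))))
  }
  got <- sum(vapply(which(!is.na(tree$parent)), function(i)
    w(i, tree$parent[i]), 0))
  expect_equal(got, best)
})

test_that("min-sum limits: independent argmin and consensus labeling", {
  costs <- withr::with_seed(34, matrix(runif(4 * 5), 4, 5))
  labels <- cbind(u = c(-2, -1, 0, 1, 2), v = 0, w = 0)
  tree <- list(parent = c(NA, 1L, 1L, 2L), order = 1:4)
  sol0 <- mstMinSum(costs, tree, labels, 0)
  expect_equal(sol0$labels, apply(costs, 1, which.min))
  solBig <- mstMinSum(costs, tree, labels, 1e6)
  expect_equal(length(unique(solBig$labels)), 1L)
  shared <- which.min(colSums(costs))
  expect_equal(solBig$labels[1], shared)
  bad <- costs; bad[2, ] <- Inf
  expect_error(mstMinSum(bad, tree, labels, 1), "finite")
})

test_that("min-sum equals exhaustive search on random small instances", {
  for (seedling in 1:100) {
    withr::with_seed(seedling, {
      nn <- sample(2:4, 1)
      nl <- sample(2:4, 1)
      labels <- matrix(runif(nl * 3, -2, 2), nl, 3)
      costs <- matrix(runif(nn * nl, 0, 5), nn, nl)
      parent <- c(NA_integer_,
                  vapply(2:nn, function(i) sample(i - 1L, 1), 1L))
      theta <- runif(1, 0, 2)
    })
    tree <- list(parent = parent, order = seq_len(nn))
    sol <- mstMinSum(costs, tree, labels, theta)
    # brute force over all label assignments
    allf <- as.matrix(do.call(expand.grid, rep(list(seq_len(nl)), nn)))
    vals <- apply(allf, 1, function(f) {
      v <- sum(costs[cbind(seq_len(nn), f)])
      for (i in 2:nn)
        v <- v + theta * sum((labels[f[i], ] - labels[f[parent[i]], ])^2)
      v
    })
    expect_equal(sol$objective, min(vals), tolerance = 1e-10)
  }
})

test_that("increasing theta never increases the tree smoothness term", {
  withr::with_seed(35, {
    nn <- 6L; nl <- 7L
    labels <- matrix(sample(-2:2, nl * 3, TRUE), nl, 3)
    costs <- matrix(runif(nn * nl, 0, 6), nn, nl)
    parent <- c(NA_integer_, vapply(2:nn, function(i) sample(i - 1L, 1), 1L))
  })
  tree <- list(parent = parent, order = seq_len(nn))
  smoothTerm <- function(sol) {
    s <- 0
    for (i in 2:nn)
      s <- s + sum((labels[sol$labels[i], ] -
                      labels[sol$labels[parent[i]], ])^2)
    s
  }
  prev <- Inf
  for (theta in c(0, 0.1, 0.5, 1, 5, 50)) {
    cur <- smoothTerm(mstMinSum(costs, tree, labels, theta))
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("DEEDS defaults and degenerate input handling", {
  expect_equal(eval(formals(registerDEEDS)$spacings), c(8L, 7L, 6L, 5L, 4L))
  expect_equal(eval(formals(registerDEEDS)$theta, list(spacings = 1)), 0.5)
  small <- ImageVolume(array(0, c(16, 16, 16)))
  expect_error(registerDEEDS(small, small), "smaller")
})

test_that("DEEDS registration of identical images is the identity", {
  ph <- generatePhantom(phantomSpec(gridShape = 48L, aShort = 12,
                                    aLong = 16, wall = 4, noiseSd = 10,
                                    nFrames = 2L))
  ref <- ph$frames[[1]]
  fld <- registerDEEDS(ref, ref, spacings = c(8L, 6L, 4L))
  expect_lt(max(abs(fieldArray(fld))), 0.1)
})

test_that("DEEDS recovers a 3-voxel translation in the interior", {
  ph <- generatePhantom(phantomSpec(gridShape = 48L, aShort = 12,
                                    aLong = 16, wall = 4, noiseSd = 10,
                                    nFrames = 2L))
  ref <- ph$frames[[1]]
  tgt <- translateImage(ref, 3L)
  fld <- registerDEEDS(ref, tgt)
  fa <- fieldArray(fld)
  interior <- 13:36
  err <- sqrt((fa[interior, interior, interior, 1] - 3)^2 +
                fa[interior, interior, interior, 2]^2 +
                fa[interior, interior, interior, 3]^2)
  expect_lt(mean(err), 0.75)
})
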