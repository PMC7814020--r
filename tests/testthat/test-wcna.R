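test_that("expression transforms drop degenerate proteins and keep shape", {
  ds <- toyDataset()
  # P2 detected in only 2 samples -> dropped at minDetect 3
  expect_message(expr <- makeExpression(ds), "dropped")
  expect_true(!"P2" %in% rownames(expr))
  expect_equal(ncol(expr), 10)
  expect_equal(attr(expr, "derivation_tag"), "nsaf_log")

  raw <- suppressMessages(makeExpression(ds, transform = "raw",
                                         minDetect = 1))
  expect_equal(raw["P1", ], spcCounts(ds)["P1", ] * 1.0)

  tiny <- SpectralCountExperiment(
    matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("S1", "S2"))),
    c(A = 10, B = 10), c(S1 = 1, S2 = 0))
  expect_error(makeExpression(tiny), "3 samples")
})

test_that("correlation matrix is symmetric with exact hand values", {
  ex <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  colnames(ex) <- paste0("S", 1:4)
  r <- correlationMatrix(ex)
  expect_equal(r["a", "b"], 0.8)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_identical(r, t(r))
  exz <- rbind(ex, d = rep(2, 4))
  expect_error(correlationMatrix(exz), "zero-variance")
})

test_that("soft-thresholded adjacency follows the similarity convention", {
  corr <- matrix(c(1, -0.9, -0.9, 1), 2, 2)
  expect_equal(adjacencyFromCor(corr, power = 2)[1, 2], 0.81)
  expect_equal(adjacencyFromCor(corr, power = 7)[1, 1], 1)
  corrNeg <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(adjacencyFromCor(corrNeg, power = 3,
                                networkType = "signed")[1, 2], 0)
  expect_equal(adjacencyFromCor(matrix(1, 2, 2), power = 9)[1, 2], 1)
  expect_error(adjacencyFromCor(corr, power = 0), "positive")
})

test_that("TOM matches the brute-force definition and its bounds", {
  # fully connected triple: overlap is perfect
  a3 <- matrix(1, 3, 3)
  expect_equal(tomSimilarity(a3), matrix(1, 3, 3))
  # disconnected pair with no shared neighbours
  a0 <- diag(4)
  a0[1, 2] <- a0[2, 1] <- 0   # explicit: nothing shared
  tom0 <- suppressMessages(tomSimilarity(a0))
  expect_equal(tom0[1, 2], 0)
  set.seed(99)
  for (i in 1:20) {
    a <- randomAdjacency(15)
    tom <- tomSimilarity(a)
    expect_equal(unname(tom), tomBrute(a), tolerance = 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_identical(tom, t(tom))
  }
})

test_that("soft-threshold selection reports fits and picks the smallest
           adequate power", {
  # graded loadings produce a heavy-tailed connectivity distribution
  set.seed(5)
  n <- 300; ns <- 12
  l <- runif(n)^0.3 * 0.95
  f <- rnorm(ns)
  ex <- l %o% f + sqrt(1 - l^2) * matrix(rnorm(n * ns), n, ns)
  dimnames(ex) <- list(paste0("G", 1:n), paste0("S", 1:ns))
  sft <- pickSoftThreshold(ex, powers = 1:20)
  tab <- sft$fit_table
  expect_true(sft$power %in% 1:20)
  expect_gte(tab$r2_signed[tab$power == sft$power], 0.8)
  smaller <- tab$r2_signed[tab$power < sft$power]
  expect_true(all(is.na(smaller) | smaller < 0.8))
  # mean connectivity decreases with the power
  expect_true(all(diff(tab$mean_k) <= 1e-10))

  # degenerate input: all correlations ~1, constant connectivity
  exDup <- matrix(rep(rnorm(8), each = 6), 6, 8) +
    matrix(rnorm(48, sd = 1e-8), 6, 8)
  dimnames(exDup) <- list(paste0("d", 1:6), paste0("S", 1:8))
  expect_warning(sftD <- pickSoftThreshold(exDup, powers = c(2, 4)),
                 "undefined|best-fitting")
  expect_true(all(is.na(sftD$fit_table$r2_signed)))
})

test_that("planted blocks are recovered and detection is order-invariant", {
  sim <- simulateDataset(threeBlockConfig())
  expr <- suppressMessages(makeExpression(sim$dataset))
  r <- correlationMatrix(expr)
  b1 <- sim$truth$module_of[rownames(expr)] == 1
  # construction check: strong within-block correlation
  expect_gt(mean(r[b1, b1][upper.tri(r[b1, b1])]), 0.8)
  net <- buildNetwork(expr)
  part <- detectModules(net)
  truth <- sim$truth$module_of[names(moduleLabels(part))]
  expect_gte(adjustedRand(moduleLabels(part), truth), 0.9)

  # permuting protein order changes nothing up to relabelling
  perm <- sample(nrow(expr))
  tomP <- tomMatrix(net)[perm, perm]
  partP <- detectModules(tomP)
  expect_equal(adjustedRand(moduleLabels(partP),
                            moduleLabels(part)[rownames(tomP)]), 1)
})

test_that("higher deepSplit cuts at least as many modules on separable
           structure", {
  sim <- simulateDataset(threeBlockConfig())
  expr <- suppressMessages(makeExpression(sim$dataset))
  net <- buildNetwork(expr)
  n0 <- length(unique(moduleLabels(detectModules(net, deepSplit = 0))))
  n4 <- length(unique(moduleLabels(detectModules(net, deepSplit = 4))))
  expect_gte(n4, n0)
})

test_that("eigenproteins are oriented unit-norm first components", {
  ns <- 8
  prof <- sin(seq_len(ns))
  ex <- rbind(a = prof, b = prof, c = prof, d = -prof,
              e = rnorm(ns))
  colnames(ex) <- paste0("S", 1:ns)
  labels <- setNames(c(1L, 1L, 1L, 2L, 0L), rownames(ex))
  # module 2 has a single member: constructor must refuse
  expect_error(moduleEigenproteins(ex, labels), "fewer than 2")
  labels <- setNames(c(1L, 1L, 1L, 1L, 0L), rownames(ex))
  eig <- moduleEigenproteins(ex, labels)
  expect_equal(sum(eig["WM1", ]^2), 1, tolerance = 1e-12)
  kme <- moduleMembership(ex, eig)
  # identical profiles: each member has |kME| = 1 and positive orientation
  expect_equal(unname(kme[c("a", "b", "c"), "WM1"]), rep(1, 3),
               tolerance = 1e-8)
  expect_equal(unname(kme["d", "WM1"]), -1, tolerance = 1e-8)

  # flipping all member profiles flips the eigenprotein, not member kMEs
  exFlip <- ex
  exFlip[1:4, ] <- -exFlip[1:4, ]
  eigF <- moduleEigenproteins(exFlip, labels)
  expect_equal(unname(eigF["WM1", ]), unname(-eig["WM1", ]),
               tolerance = 1e-8)
  kmeF <- moduleMembership(exFlip, eigF)
  expect_equal(kmeF[1:4, "WM1"], kme[1:4, "WM1"], tolerance = 1e-8)
  expect_true(all(abs(kme) <= 1 + 1e-12))
})

test_that("the eigenprotein explains at least as much variance as any
           member profile", {
  set.seed(12)
  ex <- matrix(rnorm(6 * 10), 6, 10,
               dimnames = list(paste0("p", 1:6), paste0("S", 1:10)))
  labels <- setNames(rep(1L, 6), rownames(ex))
  eig <- moduleEigenproteins(ex, labels)
  z <- t(scale(t(ex)))
  explained <- function(v) sum(cor(v, t(z))^2)
  best <- max(vapply(seq_len(nrow(z)), function(j) explained(z[j, ]),
                     numeric(1)))
  expect_gte(explained(eig[1, ]) + 1e-10, best)
})

test_that("module merging unifies near-identical eigenproteins", {
  sim <- simulateDataset(threeBlockConfig())
  expr <- suppressMessages(makeExpression(sim$dataset))
  part <- detectModules(buildNetwork(expr))
  # split module 1 artificially and let the merge step re-unify it
  labels <- moduleLabels(part)
  m1 <- names(labels)[labels == 1]
  labels[m1[seq_len(floor(length(m1) / 2))]] <- max(labels) + 1L
  partSplit <- wpcna:::.newPartition(labels, part@dendrogram, 5L)
  merged <- mergeModules(expr, partSplit)
  expect_lt(length(unique(moduleLabels(merged))),
            length(unique(labels)))
  expect_equal(adjustedRand(moduleLabels(merged), moduleLabels(part)), 1)
})
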