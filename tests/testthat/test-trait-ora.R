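test_that("module-trait correlation classifies with strict thresholds", {
  trait <- setNames(rep(c(1, 0), each = 5), paste0("S", 1:10))
  zt <- as.vector(scale(trait))
  # orthonormal direction to the trait
  v <- rnorm(10)
  v <- v - zt * sum(v * zt) / sum(zt^2)
  v <- as.vector(scale(v))
  mk <- function(rho) rho * zt + sqrt(1 - rho^2) * v
  eig <- rbind(WM1 = trait, WM2 = v, WM3 = mk(0.45))
  colnames(eig) <- names(trait)
  mt <- moduleTraitCorrelation(eig, trait)
  expect_equal(mt$r[1], 1)
  expect_equal(mt$classification[1], "significant")
  expect_equal(mt$r[2], 0, tolerance = 1e-12)
  expect_equal(mt$p[2], 1, tolerance = 1e-10)
  expect_equal(mt$r[3], 0.45, tolerance = 1e-12)
  expect_equal(mt$classification[3], "moderate")
  expect_true(mt$p[3] > 0.1 && mt$p[3] < 0.3)
  eigC <- rbind(WM1 = rep(1, 10))
  colnames(eigC) <- names(trait)
  expect_warning(mtC <- moduleTraitCorrelation(eigC, trait), "constant")
  expect_true(is.na(mtC$r[1]))
})

test_that("gene significance is |cor with trait| and affine-invariant", {
  trait <- setNames(rep(c(1, 0), each = 4), paste0("S", 1:8))
  balanced <- c(1, 2, 3, 4, 4, 3, 2, 1)  # equal group means
  ex <- rbind(a = as.numeric(trait), b = balanced, c = rnorm(8))
  colnames(ex) <- names(trait)
  gs <- geneSignificance(ex, trait)
  expect_equal(unname(gs["a"]), 1)
  expect_equal(unname(gs["b"]), 0, tolerance = 1e-12)
  exScaled <- ex * 3.7 - 11
  expect_equal(geneSignificance(exScaled, trait), gs, tolerance = 1e-12)
  expect_true(all(gs >= 0 & gs <= 1))
})

test_that("MM-GS correlation matches a hand formula and handles nulls", {
  # 3-member module with hand-picked (kME, GS) pairs
  kme <- c(A = 0.9, B = 0.5, C = 0.1)
  gs <- c(A = 0.8, B = 0.4, C = 0.2)
  out <- mmGsCorrelation(kme, gs, c("A", "B", "C"))
  handR <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  expect_equal(out$r, handR(kme, gs), tolerance = 1e-12)
  expect_equal(mmGsCorrelation(kme, kme, names(kme))$r, 1)
  expect_error(mmGsCorrelation(kme[1:2], gs[1:2], c("A", "B")),
               "too small")
  # permuted GS decorrelates on average
  set.seed(31)
  kBig <- runif(40, 0.2, 0.95)
  names(kBig) <- paste0("P", 1:40)
  rs <- replicate(300, mmGsCorrelation(kBig, setNames(sample(kBig),
                                                      names(kBig)),
                                       names(kBig))$r)
  expect_lt(abs(mean(rs)), 0.05)
  expect_gt(mean(abs(rs) < 0.4), 0.9)
})

test_that("hypergeometric overlap equals exhaustive enumeration", {
  expect_equal(hypergeomOverlap(0, 5, 4, 20), 1)
  expect_equal(hypergeomOverlap(6, 6, 6, 6), 1)
  expect_equal(hypergeomOverlap(3, 5, 4, 20), 496 / 15504,
               tolerance = 1e-12)
  for (N in c(5, 7, 9)) for (m in seq_len(N)) {
    cmb <- utils::combn(N, m)
    for (g in seq_len(N)) {
      ov <- colSums(cmb <= g)
      for (k in 0:min(m, g))
        expect_equal(hypergeomOverlap(k, m, g, N), mean(ov >= k),
                     tolerance = 1e-12)
    }
  }
  expect_error(hypergeomOverlap(5, 4, 4, 20), "exceeds")
  expect_error(hypergeomOverlap(1, 25, 4, 20), "larger than the universe")
})

test_that("the ORA screen computes joint BH cells and both aggregates", {
  prot <- sprintf("P%02d", 1:40)
  labels <- setNames(rep(0L, 40), prot)
  labels[1:10] <- 1L        # module 1 == hot_unique exactly
  labels[11:18] <- 2L       # module 2 disjoint from every group
  groups <- list(hot_unique = prot[1:10], cold_unique = prot[21:25],
                 hot_up = prot[26:30], cold_up = character(0),
                 universe = prot)
  expect_warning(scr <- oraScreen(labels, groups), "empty protein group")
  cells <- scr$cells
  # q is the step-up BH of the joint p vector
  expect_equal(cells$q, bhStepUp(cells$p_hyper), tolerance = 1e-12)
  m1hot <- cells$p_hyper[cells$module == "WM1" &
                         cells$group == "hot_unique"]
  expect_equal(m1hot, min(cells$p_hyper))
  mods <- scr$modules
  expect_true(mods$passes_screen[mods$module == "WM1"])
  expect_false(mods$passes_screen[mods$module == "WM2"])
  expect_true(all(mods$screen_min_q <= mods$screen_max_q))
  # max_q aggregation is stricter
  scrMax <- suppressWarnings(oraScreen(labels, groups,
                                       aggregate = "max_q"))
  expect_false(scrMax$modules$passes_screen[
    scrMax$modules$module == "WM1"])

  # verdicts invariant to module relabelling and protein order
  relab <- labels
  relab[labels == 1L] <- 7L
  relab[labels == 2L] <- 3L
  perm <- sample(seq_along(relab))
  scrP <- suppressWarnings(oraScreen(relab[perm], groups))
  expect_equal(sort(scrP$modules$screen_min_q),
               sort(mods$screen_min_q), tolerance = 1e-12)

  # all modules disjoint from all groups: nothing passes
  labD <- setNames(rep(0L, 40), prot)
  labD[31:40] <- 1L
  grD <- list(hot_unique = prot[1:5], cold_unique = prot[6:10],
              hot_up = prot[11:15], cold_up = prot[16:20],
              universe = prot)
  expect_false(any(oraScreen(labD, grD)$modules$passes_screen))
})
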