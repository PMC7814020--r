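# shared fixtures and independent oracles

# tiny literal dataset used across the io tests
toyDataset <- function() {
  cnt <- matrix(c(3, 0, 1, 0, 0,  0, 0, 0, 0, 0,
                  0, 0, 0, 0, 0,  0, 2, 0, 1, 0,
                  0, 0, 0, 0, 0,  0, 0, 0, 2, 5,
                  5, 2, 3, 1, 4,  2, 1, 3, 2, 2),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("P", 1:4),
                                c(paste0("H", 1:5), paste0("C", 1:5))))
  SpectralCountExperiment(cnt,
                          setNames(c(100, 250, 300, 180), paste0("P", 1:4)),
                          setNames(rep(c(1, 0), each = 5),
                                   c(paste0("H", 1:5), paste0("C", 1:5))))
}

# brute-force topological overlap, straight from the definition
tomBrute <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    den <- min(ki, kj) + 1 - a[i, j]
    out[i, j] <- if (den <= 0) 0 else (l + a[i, j]) / den
  }
  out
}

randomAdjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# exhaustive hypergeometric tail: enumerate every m-subset of 1..N and
# count how often it overlaps the group {1..g} in at least k elements
hyperEnum <- function(k, m, g, N) {
  cmb <- utils::combn(N, m)
  ov <- colSums(cmb <= g)
  mean(ov >= k)
}

# step-up Benjamini-Hochberg written out from the definition
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n * p[o[i]] / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# small config for fast end-to-end runs
smallConfig <- function(seed = 1, ...) {
  simConfig(nProteins = 240, moduleSizes = c(40, 30, 20), loading = 0.9,
            traitModules = 1, traitShift = 1.5, nHotUnique = 25,
            nColdUnique = 10, nHotUp = 20, nColdUp = 10,
            librarySize = 20000, profileSd = 2, seed = seed, ...)
}

# high-signal three-block dataset: within-block correlation ~0.9
threeBlockConfig <- function(seed = 11) {
  simConfig(nProteins = 60, moduleSizes = c(30, 20, 10), loading = 0.95,
            profileSd = 3, librarySize = 200000, dispersion = 0.01,
            traitModules = integer(0), traitShift = 0,
            nHotUnique = 0, nColdUnique = 0, nHotUp = 0, nColdUp = 0,
            seed = seed)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
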