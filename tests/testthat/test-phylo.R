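# independent TN93 oracle: formula evaluated from substitution-class counts
# tallied by simple table arithmetic (no shared code with the implementation)
tn93_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  L <- length(a)
  g <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * L)
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / L
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / L
  Q <- sum(a != b) / L - P1 - P2
  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["C"] * g["T"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["C"] * g["T"] * gR / gY)
  unname(-k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
         k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
         k3 * log(1 - Q / (2 * gR * gY)))
}

test_that("TN93: zero for identical pairs, matches the closed-form oracle and ape", {
  set.seed(61)
  s <- rand_dna(200)
  expect_equal(tn93_distance(s, s), 0)

  for (rep in 1:10) {
    L <- 240
    a <- strsplit(rand_dna(L, c("A", "C", "G", "T")), "")[[1]]
    b <- a
    idx <- sample(L, 20)
    for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), a[i]), 1)
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    expect_equal(tn93_distance(sa, sb), tn93_oracle(sa, sb), tolerance = 1e-12)
    bin <- ape::as.DNAbin(matrix(c(tolower(a), tolower(b)), 2, byrow = TRUE))
    expect_equal(tn93_distance(sa, sb),
                 as.numeric(ape::dist.dna(bin, "TN93", pairwise.deletion = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("TN93 collapses to Jukes-Cantor under uniform composition and balanced classes", {
  # base sequence with exactly equal base composition; apply one reciprocal
  # substitution of every ordered type so composition and class balance hold
  set.seed(14)
  L <- 120
  a <- sample(rep(c("A", "C", "G", "T"), L / 4))
  b <- a
  types <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                c("A", "C"), c("C", "A"), c("A", "T"), c("T", "A"),
                c("C", "G"), c("G", "C"), c("G", "T"), c("T", "G"))
  pos <- sample(L, 12)
  used <- 0
  for (ty in types) {
    i <- which(a == ty[1] & seq_len(L) %in% pos & b == a)[1]
    if (is.na(i)) i <- which(a == ty[1] & b == a)[1]
    b[i] <- ty[2]
  }
  sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
  p <- mean(a != b)
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(tn93_distance(sa, sb), jc, tolerance = 1e-12)
})

test_that("TN93 is bounded below by p-distance and saturates to the ceiling", {
  set.seed(88)
  for (rep in 1:10) {
    a <- rand_dna(150)
    b <- rand_dna(150)
    chars_a <- strsplit(a, "")[[1]]; chars_b <- strsplit(b, "")[[1]]
    p <- mean(chars_a != chars_b)
    d <- suppressWarnings(tn93_distance(a, b))
    expect_gte(d + 1e-12, p)
  }
  # near-total divergence in the transversion class forces saturation
  x <- strrep("A", 100); y <- strrep("C", 100)
  expect_warning(d <- tn93_distance(x, y), "saturated")
  expect_equal(d, 5.0)
  expect_equal(suppressWarnings(tn93_distance(x, y, ceiling = 2)), 2)
})

test_that("NJ reproduces the worked 4-taxon additive matrix exactly", {
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  # additivity: path lengths reproduce every input distance
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-12)
  # pendant branches 1,2,3,4 and internal branch 1
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
})

test_that("three taxa resolve by the closed-form three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(unname(len["x"]), (2 + 3 - 5) / 2)
  expect_equal(unname(len["y"]), (2 + 5 - 3) / 2)
  expect_equal(unname(len["z"]), (3 + 5 - 2) / 2)
})

test_that("NJ exactly recovers random additive trees up to n = 12", {
  set.seed(123)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    t0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    t0 <- ape::unroot(t0)
    d <- as.matrix(ape::cophenetic.phylo(t0))
    tr <- neighbor_joining(d)
    expect_equal(ape::dist.topo(tr, t0), 0, ignore_attr = TRUE)
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
                 d, tolerance = 1e-9)
  }
  # ultrametric (coalescent) trees are additive too; NJ must match their
  # topology, which is what average-linkage clustering would give
  for (rep in 1:3) {
    t0 <- ape::rcoal(8)
    d <- as.matrix(ape::cophenetic.phylo(t0))
    tr <- neighbor_joining(d)
    expect_equal(ape::dist.topo(tr, ape::unroot(t0)), 0, ignore_attr = TRUE)
  }
})

test_that("NJ validates its input and never returns negative branch lengths", {
  d <- matrix(runif(16), 4, 4)
  expect_error(neighbor_joining(d), "not symmetric")
  d2 <- matrix(0, 3, 3); d2[1, 2] <- d2[2, 1] <- Inf
  expect_error(neighbor_joining(d2), "non-finite")
  set.seed(9)
  # noisy (non-additive) matrices can produce negative NJ lengths; they must
  # be clamped with the pair's path length preserved
  for (rep in 1:10) {
    n <- 6
    m <- matrix(runif(n * n, 0.1, 1), n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    tr <- neighbor_joining(m)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("newick output: 3-leaf form, quoting, and round-trip to 1e-10", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  s <- newick_string(tr)
  expect_match(s, "^\\([A-C]:[0-9.]+,[A-C]:[0-9.]+,[A-C]:[0-9.]+\\);$")

  set.seed(55)
  t0 <- ape::rtree(9)
  f <- tempfile(fileext = ".nwk")
  write_newick(t0, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(t0)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(t0$edge.length), tolerance = 1e-10)

  tq <- tr
  tq$tip.label <- c("plain", "ha(plo):1", "with space")
  sq <- newick_string(tq)
  expect_match(sq, "'ha\\(plo\\):1'", fixed = FALSE)
  expect_match(sq, "'with space'")
  # annotations appended as label suffixes
  sa <- newick_string(tr, annotations = c(A = "CS|Ecuador"))
  expect_match(sa, "A|CS|Ecuador", fixed = TRUE)
})
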