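# Sequence alignment, Kabsch superposition, TM-score machinery.

rodrigues <- function(v) {
  # rotation matrix from a rotation vector (independent of kabsch internals)
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

test_that("global alignment handles identity, deletions and mismatches", {
  a <- "MKTAYIAKQR"
  self <- align_sequences(a, a)
  expect_equal(self[, "i"], 1:10)
  expect_equal(self[, "j"], 1:10)

  # single deletion: D of ACDEFG is skipped
  corr <- align_sequences("ACDEFG", "ACEFG")
  expect_equal(nrow(corr), 5L)
  expect_equal(corr[, "i"], c(1L, 2L, 4L, 5L, 6L))
  expect_equal(corr[, "j"], 1:5)

  # all-mismatch still yields a correspondence of bounded length
  mm <- align_sequences("AAAA", "CCCC")
  expect_lte(nrow(mm), 4L)

  expect_error(align_sequences("", "ACD"), "non-empty")
})

test_that("alignment scores agree with an independent global aligner", {
  set.seed(42)
  for (k in 1:10) {
    a <- rand_seq(sample(10:40, 1))
    b <- rand_seq(sample(10:40, 1))
    corr <- align_sequences(a, b)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 0, gapExtension = 6,
      type = "global", scoreOnly = TRUE)
    expect_equal(attr(corr, "score"), ref)
    # matched columns strictly increasing in both sequences
    if (nrow(corr) > 1L) {
      expect_true(all(diff(corr[, "i"]) > 0))
      expect_true(all(diff(corr[, "j"]) > 0))
    }
  }
})

test_that("kabsch recovers exact rigid motions and rejects bad input", {
  set.seed(7)
  P <- matrix(rnorm(30), 10L)
  expect_equal(kabsch(P, P)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch(P, P)$rotation, diag(3), tolerance = 1e-9)

  R90 <- rodrigues(c(0, 0, pi / 2))
  Q <- sweep(P %*% t(R90), 2L, c(5, 0, 0), `+`)
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
  # recovered transform actually maps Q onto P
  expect_lt(max(abs(binderclust:::apply_superposition(Q, fit) - P)), 1e-9)

  expect_error(kabsch(P, P[1:5, ]), "identical dimensions")
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "3 points")
})

test_that("kabsch handles reflection-prone point sets with det +1", {
  set.seed(8)
  for (k in 1:10) {
    P <- matrix(rnorm(15), 5L)
    Q <- P %*% diag(c(-1, 1, 1))       # mirrored copy
    fit <- kabsch(P, Q)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
})

test_that("tm_d0 follows the closed form with its clamp", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(21), 0.5)
  d0 <- tm_d0(1:1000)
  expect_true(all(diff(d0) >= 0))
  expect_error(tm_d0(0), "at least 1")
})

test_that("structural alignment: self, noisy homolog, wrong fold", {
  s <- rand_seq(100, seed = 9)
  clean <- fold_chain(0L, 100L, s)
  self <- structural_align(clean, clean)
  expect_equal(self$tm_1, 1.0)
  expect_equal(self$tm_2, 1.0)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$coverage, 1.0)

  noisy <- fold_chain(0L, 100L, s, sigma = 0.5, seed = 10)
  hom <- structural_align(clean, noisy)
  expect_gte(hom$tm_1, 0.9)
  expect_lte(hom$rmsd, 1.5)

  hairpin <- fold_chain(1L, 100L, s)
  decoy <- structural_align(clean, hairpin)
  expect_lt(min(decoy$tm_1, decoy$tm_2), 0.5)

  short <- chain_structure("B", substr(s, 1, 4), make_fold(0L, 10L)[1:4, ])
  expect_error(structural_align(clean, short), "at least 5 residues")
})

test_that("rmsd is invariant under a common rigid transform", {
  set.seed(12)
  s <- rand_seq(40)
  s1 <- fold_chain(0L, 40L, s, sigma = 0.4)
  s2 <- fold_chain(0L, 40L, s, sigma = 0.4)
  base <- structural_align(s1, s2)
  for (k in 1:5) {
    R <- rodrigues(rnorm(3))
    t <- rnorm(3, 0, 10)
    move <- function(ch) chain_structure(ch$chain_id, ch$sequence,
                                         sweep(ch$ca %*% t(R), 2L, t, `+`))
    res <- structural_align(move(s1), move(s2))
    expect_equal(res$rmsd, base$rmsd, tolerance = 1e-9)
    expect_equal(res$tm_1, base$tm_1, tolerance = 1e-9)
  }
})

test_that("tm_1 equals tm_2 for equal lengths; normalization differs otherwise", {
  set.seed(13)
  s <- rand_seq(30)
  a <- fold_chain(0L, 30L, s, sigma = 0.3)
  b <- fold_chain(0L, 30L, s, sigma = 0.3)
  res <- structural_align(a, b)
  expect_equal(res$tm_1, res$tm_2, tolerance = 1e-12)

  long_s <- rand_seq(50, seed = 14)
  long <- fold_chain(0L, 50L, long_s)
  res2 <- structural_align(a, long)
  expect_false(isTRUE(all.equal(res2$tm_1, res2$tm_2)))
})

test_that("iterative refinement is near the exhaustive subset optimum", {
  set.seed(15)
  for (k in 1:5) {
    s <- rand_seq(6)
    a <- fold_chain(0L, 6L, s, sigma = 0.8)
    # force at least 5 residues: use length 6 with matching sequence
    b <- fold_chain(0L, 6L, s, sigma = 0.8)
    res <- structural_align(a, b)
    n <- res$n_pairs
    kept <- sum(sqrt(rowSums((a$ca[res$correspondence[, 1], ] -
      binderclust:::apply_superposition(
        b$ca[res$correspondence[, 2], ], res$superposition))^2)) <
      max(4.5, tm_d0(6)) + 1e-9)
    # exhaustive search over all pair subsets of the final subset size
    sizes <- max(3L, kept)
    combos <- utils::combn(n, sizes)
    best <- min(apply(combos, 2L, function(ix) {
      kabsch(a$ca[res$correspondence[ix, 1], , drop = FALSE],
             b$ca[res$correspondence[ix, 2], , drop = FALSE])$rmsd
    }))
    expect_lte(res$rmsd, 1.05 * best + 1e-12)
  }
})

test_that("all_vs_all computes each pair once, symmetrically, any cpu count", {
  set.seed(16)
  ids <- sprintf("m%02d", 1:5)
  s <- rand_seq(30)
  members <- setNames(lapply(seq_along(ids), function(i) {
    toy_trimmed(ids[i], 0L, 30L, s, sigma = 0.4)
  }), ids)
  pt <- all_vs_all(members, cpus = 1L)
  expect_equal(nrow(pt$table), 5L + choose(5, 2))
  diag <- pt$table[pt$table$id1 == pt$table$id2, ]
  expect_true(all(diag$rmsd == 0 & diag$tm_1 == 1))

  pt4 <- all_vs_all(members, cpus = 4L)
  expect_identical(pt$table, pt4$table)

  # orientation symmetry of rmsd on raw alignments
  for (k in 1:3) {
    i <- sample(5, 2)
    ab <- structural_align(members[[i[1]]]$target, members[[i[2]]]$target)
    ba <- structural_align(members[[i[2]]]$target, members[[i[1]]]$target)
    expect_equal(ab$rmsd, ba$rmsd, tolerance = 1e-9)
    expect_equal(ab$tm_1, ba$tm_2, tolerance = 1e-9)
  }

  # three members give exactly three off-diagonal entries
  pt3 <- all_vs_all(members[1:3], cpus = 1L)
  expect_equal(sum(pt3$table$id1 != pt3$table$id2), 3L)
})
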