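# Greedy sequence/structure clustering, joint merging, representatives,
# and the clustering-stage tables.

test_that("sequence clustering groups families and respects extremes", {
  s <- rand_seq(40, seed = 50)
  seqs <- setNames(rep(s, 5), sprintf("a%d", 1:5))
  p <- cluster_sequences(seqs)
  expect_length(unique(p$labels), 1L)

  # two synthetic families: heavy within-family identity, none across
  set.seed(51)
  fam1 <- rand_seq(40); fam2 <- rand_seq(40)
  mut <- function(s) binderclust:::mutate_sequence(s, 0.1)
  seqs2 <- c(setNames(replicate(4, mut(fam1)), sprintf("f1_%d", 1:4)),
             setNames(replicate(4, mut(fam2)), sprintf("f2_%d", 1:4)))
  p2 <- cluster_sequences(seqs2, min_id = 0.3)
  expect_length(unique(p2$labels), 2L)
  expect_length(unique(p2$labels[1:4]), 1L)
  expect_length(unique(p2$labels[5:8]), 1L)

  # identity threshold 1.0 on distinct sequences -> all singletons
  set.seed(52)
  seqs3 <- setNames(replicate(4, rand_seq(30)), sprintf("s%d", 1:4))
  p3 <- cluster_sequences(seqs3, min_id = 1.0)
  expect_length(unique(p3$labels), 4L)

  expect_error(cluster_sequences(seqs, min_id = 1.2), "min_id")
})

test_that("structure clustering is rigid-motion invariant and threshold-sensitive", {
  set.seed(53)
  s <- rand_seq(40)
  base <- make_fold(0L, 40L)
  rot <- function() {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  members <- setNames(lapply(1:4, function(i) {
    xyz <- sweep(base %*% t(rot()), 2L, rnorm(3, 0, 20), `+`)
    tc <- toy_trimmed(sprintf("r%d", i), 0L, 40L, s)
    tc$target <- chain_structure("B", s, xyz)
    tc
  }), sprintf("r%d", 1:4))
  p <- cluster_structures(members, min_tm = 0.5)
  expect_length(unique(p$labels), 1L)

  # helix family vs hairpin family separate at TM 0.5
  sh <- rand_seq(40, 55); sp <- rand_seq(40, 56)
  set.seed(54)
  two <- c(lapply(1:3, function(i) toy_trimmed(sprintf("h%d", i), 0L, 40L,
                                               sh, 0.3)),
           lapply(1:3, function(i) toy_trimmed(sprintf("p%d", i), 1L, 40L,
                                               sp, 0.3)))
  names(two) <- vapply(two, `[[`, character(1), "complex_id")
  p2 <- cluster_structures(two, min_tm = 0.5)
  expect_length(unique(p2$labels), 2L)
  expect_length(unique(p2$labels[c("h1", "h2", "h3")]), 1L)

  # absurdly strict threshold on noisy copies -> singletons
  set.seed(57)
  noisy <- setNames(lapply(1:3, function(i) {
    toy_trimmed(sprintf("n%d", i), 0L, 40L, s, sigma = 0.5)
  }), sprintf("n%d", 1:3))
  p3 <- cluster_structures(noisy, min_tm = 0.999)
  expect_length(unique(p3$labels), 3L)
})

test_that("merging joins clusters that share members", {
  # seq {A,B},{C}; struct {B,C},{A} -> all three connect through B and C
  seq_p <- binderclust:::new_partition(
    c(A = "s1", B = "s1", C = "s2"), "sequence")
  struct_p <- binderclust:::new_partition(
    c(A = "t2", B = "t1", C = "t1"), "structure")
  m <- merge_partitions(seq_p, struct_p)
  expect_length(unique(m$labels), 1L)
  expect_equal(unname(m$labels[["A"]]), "A")   # smallest member id

  # identical partitions merge to themselves
  same <- binderclust:::new_partition(c(A = "x", B = "x", C = "y"), "sequence")
  same2 <- binderclust:::new_partition(c(A = "x", B = "x", C = "y"), "structure")
  m2 <- merge_partitions(same, same2)
  expect_equal(length(unique(m2$labels)), 2L)
  expect_length(unique(m2$labels[c("A", "B")]), 1L)

  bad <- binderclust:::new_partition(c(A = "x", B = "x"), "structure")
  expect_error(merge_partitions(same, bad), "different id sets")
})

test_that("merging equals the transitive-closure oracle on random inputs", {
  set.seed(58)
  ids <- sprintf("id%02d", 1:30)
  for (trial in 1:20) {
    p1 <- binderclust:::new_partition(
      setNames(sprintf("s%d", sample(1:8, 30, TRUE)), ids), "sequence")
    p2 <- binderclust:::new_partition(
      setNames(sprintf("t%d", sample(1:8, 30, TRUE)), ids), "structure")
    m <- merge_partitions(p1, p2)
    # oracle: repeated pairwise union until fixpoint
    groups <- as.list(ids)
    repeat {
      changed <- FALSE
      for (i in seq_along(groups)) {
        if (i > length(groups)) break
        j <- i + 1L
        while (j <= length(groups)) {
          share <- any(p1$labels[groups[[i]]] %in% p1$labels[groups[[j]]]) ||
            any(p2$labels[groups[[i]]] %in% p2$labels[groups[[j]]])
          if (share) {
            groups[[i]] <- c(groups[[i]], groups[[j]])
            groups[[j]] <- NULL
            changed <- TRUE
          } else j <- j + 1L
        }
      }
      if (!changed) break
    }
    oracle <- unlist(lapply(groups, function(g) setNames(rep(min(g), length(g)), g)))
    expect_identical(unname(m$labels[ids]), unname(oracle[ids]))
  }
})

test_that("representative selection follows median rmsd with tie rules", {
  # constructed table: AB=1, AC=2, BC=3 -> medians A=1.5, B=2, C=2.5
  pt <- fake_pairwise(c("A", "B", "C"),
                      matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3L))
  sel <- select_representative(c("A", "B", "C"), pt)
  expect_equal(sel$representative, "A")
  med <- setNames(sel$medians$median_rmsd, sel$medians$complex_id)
  expect_equal(unname(med[c("A", "B", "C")]), c(1.5, 2, 2.5))

  # all-equal rmsd: ties fall through tm to the lexicographically smallest
  pt2 <- fake_pairwise(c("b", "a", "c"), matrix(1, 3L, 3L) - diag(3))
  sel2 <- select_representative(c("b", "a", "c"), pt2)
  expect_equal(sel2$representative, "a")

  # higher median tm wins before the lexicographic rule
  tm <- matrix(0.5, 3, 3); tm[2, ] <- 0.9; tm[, 2] <- 0.9
  pt3 <- fake_pairwise(c("a", "b", "c"), matrix(1, 3, 3) - diag(3), tm)
  expect_equal(select_representative(c("a", "b", "c"), pt3)$representative, "b")

  # degenerate pairs (NA rmsd) are excluded from medians
  rm <- matrix(c(0, 1, NA, 1, 0, 2, NA, 2, 0), 3L)
  pt4 <- fake_pairwise(c("a", "b", "c"), rm)
  sel4 <- select_representative(c("a", "b", "c"), pt4)
  expect_equal(sel4$medians$median_rmsd[sel4$medians$complex_id == "a"], 1)

  # singleton: sole member is representative with missing medians
  sel5 <- select_representative("only", NULL)
  expect_equal(sel5$representative, "only")
  expect_true(is.na(sel5$medians$median_rmsd))
})

test_that("representative argmin matches brute force on random tables", {
  set.seed(59)
  ids <- sprintf("m%d", 1:5)
  for (trial in 1:15) {
    rm <- matrix(0, 5, 5)
    rm[upper.tri(rm)] <- round(runif(10, 0.5, 5), 2)
    rm <- rm + t(rm)
    tm <- matrix(0, 5, 5)
    tm[upper.tri(tm)] <- round(runif(10, 0.3, 1), 2)
    tm <- tm + t(tm)
    pt <- fake_pairwise(ids, rm, tm)
    got <- select_representative(ids, pt)$representative
    # brute force with the stated tie rules
    meds_r <- vapply(1:5, function(i) median(rm[i, -i]), numeric(1))
    meds_t <- vapply(1:5, function(i) median(tm[-i, i]), numeric(1))
    ord <- order(meds_r, -meds_t, ids)
    expect_equal(got, ids[ord[1]])
  }
})

test_that("merged partition coarsens both inputs within count bounds", {
  set.seed(60)
  ids <- sprintf("x%02d", 1:20)
  for (trial in 1:10) {
    p1 <- binderclust:::new_partition(
      setNames(sprintf("s%d", sample(1:5, 20, TRUE)), ids), "sequence")
    p2 <- binderclust:::new_partition(
      setNames(sprintf("t%d", sample(1:5, 20, TRUE)), ids), "structure")
    m <- merge_partitions(p1, p2)
    expect_setequal(names(m$labels), ids)
    # each seq/struct cluster maps into exactly one merged cluster
    for (p in list(p1, p2)) {
      per <- tapply(m$labels[names(p$labels)], p$labels, function(v) length(unique(v)))
      expect_true(all(per == 1L))
    }
    n_m <- length(unique(m$labels))
    expect_gte(n_m, 1L)
    expect_lte(n_m, min(length(unique(p1$labels)), length(unique(p2$labels))))
  }
})

test_that("cluster tables land on disk sorted, flagged and reproducible", {
  screen <- fixture_screen("small", small_spec())
  recs <- suppress_logs(load_screen(screen))
  gated <- filter_by_iptm(recs)
  tr <- suppress_logs(trim_screen(gated))
  trimmed <- tr$trimmed
  seqs <- vapply(trimmed, function(tc) tc$target$sequence, character(1))
  sp <- cluster_sequences(seqs)
  st <- cluster_structures(trimmed)
  mg <- merge_partitions(sp, st)
  summ <- cluster_summaries(mg, trimmed)
  out1 <- withr::local_tempdir()
  write_cluster_tables(gated[names(trimmed)], sp, st, mg, summ, out1)
  csv <- file.path(out1, "merged_clusters", "merged_clusters.csv")
  tab <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 12L)                       # 3 families x 4 members
  expect_length(unique(tab$merged_cluster), 3L)
  expect_equal(sum(tab$is_representative == "true"), 3L)
  # every complex appears in exactly one cluster of each kind
  expect_false(any(duplicated(tab$complex_id)))
  expect_false(any(is.na(tab$seq_cluster) | is.na(tab$struct_cluster)))

  out2 <- withr::local_tempdir()
  write_cluster_tables(gated[names(trimmed)], sp, st, mg, summ, out2)
  expect_identical(readLines(csv),
                   readLines(file.path(out2, "merged_clusters",
                                       "merged_clusters.csv")))
})

test_that("a single complex yields one row with empty medians", {
  rec <- toy_record(planted_pae(15L, 25L, c(5L, 20L)), id = "solo")
  tr <- suppress_logs(trim_screen(list(rec)))
  trimmed <- tr$trimmed
  sp <- cluster_sequences(c(solo = trimmed$solo$target$sequence))
  st <- cluster_structures(trimmed)
  mg <- merge_partitions(sp, st)
  summ <- cluster_summaries(mg, trimmed)
  out <- withr::local_tempdir()
  write_cluster_tables(list(solo = rec), sp, st, mg, summ, out)
  lines <- readLines(file.path(out, "merged_clusters", "merged_clusters.csv"))
  expect_length(lines, 2L)
  tab <- read.csv(text = lines, stringsAsFactors = FALSE,
                  colClasses = c(median_rmsd = "character"))
  expect_equal(tab$median_rmsd, "")
  expect_equal(tab$is_representative, "true")
})

test_that("representative choice ignores member input order", {
  set.seed(61)
  s <- rand_seq(40)
  members <- setNames(lapply(1:4, function(i) {
    toy_trimmed(sprintf("m%d", i), 0L, 40L, s, sigma = 0.5, seed = 70 + i)
  }), sprintf("m%d", 1:4))
  pt <- all_vs_all(members)
  base <- select_representative(names(members), pt)$representative
  for (k in 1:3) {
    perm <- sample(names(members))
    expect_equal(select_representative(perm, pt)$representative, base)
  }
})
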