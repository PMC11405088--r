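# Sequence-guided rigid-body structural comparison.
#
# Cluster members are homologous by construction (they reach the all-vs-all
# step only after sequence/fold clustering), so the residue correspondence is
# seeded by a global sequence alignment rather than a sequence-independent
# search. The superposition is then refined TM-align-style: superpose on the
# current pair subset, re-measure inter-pair distances, keep the close pairs,
# repeat to a fixed point. TM-scores are computed over all aligned pairs with
# the final superposition; RMSD is reported over the final kept subset.

.blosum62_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.blosum62_env$mat)) {
    utils::data("BLOSUM62", package = "Biostrings", envir = .blosum62_env)
    .blosum62_env$mat <- .blosum62_env$BLOSUM62
  }
  .blosum62_env$mat
}

#' Global sequence alignment correspondence
#'
#' Needleman--Wunsch with BLOSUM62 substitution scores and a linear gap
#' penalty of -6. Traceback is deterministic with fixed precedence
#' diagonal > up > left, so equal-scoring paths always resolve the same way.
#'
#' @param a,b non-empty amino-acid strings.
#' @return integer matrix with columns `i` (position in `a`) and `j`
#'   (position in `b`), 1-based, one row per matched (non-gap) column; both
#'   columns strictly increasing. Attribute `ncol_aln` carries the total
#'   alignment length including gap columns (used for identity denominators).
#' @export
align_sequences <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  gap <- -6
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- blosum62()
  sub <- S[av, bv, drop = FALSE]
  # F: (n+1) x (m+1) DP matrix; ptr: 0 diag, 1 up (consume a), 2 left
  F <- matrix(0, n + 1L, m + 1L)
  ptr <- matrix(0L, n + 1L, m + 1L)
  F[1, ] <- gap * (0:m); F[, 1] <- gap * (0:n)
  ptr[1, -1] <- 2L; ptr[-1, 1] <- 1L
  for (i in 2:(n + 1L)) {
    Fi1 <- F[i - 1L, ]
    Fi <- F[i, ]
    si <- sub[i - 1L, ]
    for (j in 2:(m + 1L)) {
      d <- Fi1[j - 1L] + si[j - 1L]
      u <- Fi1[j] + gap
      l <- Fi[j - 1L] + gap
      if (d >= u && d >= l) { Fi[j] <- d; ptr[i, j] <- 0L }
      else if (u >= l)      { Fi[j] <- u; ptr[i, j] <- 1L }
      else                  { Fi[j] <- l; ptr[i, j] <- 2L }
    }
    F[i, ] <- Fi
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  pi <- integer(0); pj <- integer(0); ncol_aln <- 0L
  while (i > 1L || j > 1L) {
    ncol_aln <- ncol_aln + 1L
    p <- ptr[i, j]
    if (p == 0L) { pi <- c(i - 1L, pi); pj <- c(j - 1L, pj); i <- i - 1L; j <- j - 1L }
    else if (p == 1L) i <- i - 1L
    else j <- j - 1L
  }
  structure(cbind(i = pi, j = pj), ncol_aln = ncol_aln,
            score = F[n + 1L, m + 1L])
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `Q` onto
#' `P`, via SVD of the covariance matrix with reflection correction (the
#' smallest singular direction is flipped when needed so the determinant is
#' +1).
#'
#' @param P,Q numeric matrices of matched points (rows), same size, at least
#'   3 points.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3), and
#'   `rmsd`. A point `q` maps to `rotation %*% q + translation`; for
#'   row-matrices, `Q %*% t(rotation) + translation`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stopf("point sets must have identical dimensions")
  if (nrow(P) < 3L) stopf("at least 3 points are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- t(Qc) %*% Pc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Qr <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pc - Qr)^2)))
  list(rotation = R, translation = as.numeric(cp - R %*% cq), rmsd = rmsd)
}

apply_superposition <- function(X, sup) {
  sweep(X %*% t(sup$rotation), 2L, sup$translation, `+`)
}

invert_superposition <- function(sup) {
  Rt <- t(sup$rotation)
  list(rotation = Rt, translation = as.numeric(-Rt %*% sup$translation))
}

#' TM-score distance scale d0
#'
#' The length-dependent normalization distance of the TM-score:
#' `1.24 * (L - 15)^(1/3) - 1.8` for `L > 21`, clamped below at 0.5 Angstrom.
#'
#' @param L reference length in residues (`L >= 1`).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  if (any(L < 1)) stopf("L must be at least 1")
  d0 <- ifelse(L > 21, 1.24 * (L - 15)^(1/3) - 1.8, 0.5)
  pmax(d0, 0.5)
}

#' Sequence-seeded iterative structural alignment
#'
#' Aligns two CA traces: the residue correspondence comes from
#' [align_sequences]; the superposition is refined by repeatedly superposing
#' on the current pair subset and keeping pairs closer than
#' `max(4.5, d0(min(L1, L2)))` Angstrom, to a fixed point (at most 20
#' rounds; subset ties resolve by residue index, and the subset never drops
#' below the 3 closest pairs). TM-scores are computed over all correspondence
#' pairs under the final superposition, normalized by each structure's
#' length; RMSD is over the final kept subset.
#'
#' @param s1,s2 [chain_structure] objects with at least 5 residues.
#' @return list of class `alignment_result`: `rmsd`, `tm_1`, `tm_2`,
#'   `coverage` (pairs / shorter length), `n_pairs`, `superposition` (maps
#'   `s2` coordinates onto `s1`'s frame). With fewer than 3 correspondence
#'   pairs, `rmsd`/`tm_*` are `NA` (undefined, never fabricated).
#' @export
structural_align <- function(s1, s2) {
  L1 <- chain_length(s1); L2 <- chain_length(s2)
  if (L1 < 5L || L2 < 5L) stopf("structures must have at least 5 residues")
  corr <- align_sequences(s1$sequence, s2$sequence)
  n_pairs <- nrow(corr)
  cov <- n_pairs / min(L1, L2)
  if (n_pairs < 3L) {
    return(structure(list(rmsd = NA_real_, tm_1 = NA_real_, tm_2 = NA_real_,
                          coverage = cov, n_pairs = n_pairs,
                          superposition = NULL, correspondence = corr),
                     class = "alignment_result"))
  }
  P <- s1$ca[corr[, 1L], , drop = FALSE]
  Q <- s2$ca[corr[, 2L], , drop = FALSE]
  cutoff <- max(4.5, tm_d0(min(L1, L2)))
  keep <- seq_len(n_pairs)
  sup <- NULL
  for (it in seq_len(20L)) {
    sup <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    d <- sqrt(rowSums((P - apply_superposition(Q, sup))^2))
    newkeep <- which(d < cutoff)
    if (length(newkeep) < 3L) newkeep <- sort(order(d, seq_along(d))[1:3])
    if (identical(newkeep, keep)) break
    keep <- newkeep
  }
  sup <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
  d_all <- sqrt(rowSums((P - apply_superposition(Q, sup))^2))
  tm <- function(L) sum(1 / (1 + (d_all / tm_d0(L))^2)) / L
  structure(list(rmsd = sup$rmsd, tm_1 = tm(L1), tm_2 = tm(L2),
                 coverage = cov, n_pairs = n_pairs,
                 superposition = sup[c("rotation", "translation")],
                 correspondence = corr),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> rmsd %.3f A, TM %.3f/%.3f, %d pairs, coverage %.2f\n",
              x$rmsd, x$tm_1, x$tm_2, x$n_pairs, x$coverage))
  invisible(x)
}

# TM-score normalized by the shorter structure.
tm_shorter <- function(res, L1, L2) if (L1 <= L2) res$tm_1 else res$tm_2

#' All-vs-all structural alignment of trimmed targets
#'
#' Computes every unordered pair exactly once (optionally across forked
#' workers; results are identical for any worker count) and returns a
#' long-format table plus the pairwise superpositions.
#'
#' @param members named list of `trimmed_complex` (at least 2).
#' @param cpus worker count for `parallel::mclapply`; 1 runs serially.
#' @return object of class `pairwise_table`: `table` is a data frame with
#'   columns id1, id2, rmsd, tm_1, tm_2, coverage, n_pairs (including
#'   diagonal self rows with TM 1 and RMSD 0); `sup` maps `"id1|id2"` to the
#'   superposition of id2 onto id1.
#' @export
all_vs_all <- function(members, cpus = 1L) {
  ids <- sort(names(members))
  if (length(ids) < 2L) stopf("all_vs_all needs at least 2 members")
  pairs <- utils::combn(ids, 2L)
  one <- function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    structural_align(members[[a]]$target, members[[b]]$target)
  }
  res <- if (cpus > 1L) {
    parallel::mclapply(seq_len(ncol(pairs)), one, mc.cores = cpus,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(ncol(pairs)), one)
  }
  off <- data.frame(
    id1 = pairs[1L, ], id2 = pairs[2L, ],
    rmsd = vapply(res, `[[`, numeric(1), "rmsd"),
    tm_1 = vapply(res, `[[`, numeric(1), "tm_1"),
    tm_2 = vapply(res, `[[`, numeric(1), "tm_2"),
    coverage = vapply(res, `[[`, numeric(1), "coverage"),
    n_pairs = vapply(res, `[[`, integer(1), "n_pairs"),
    stringsAsFactors = FALSE)
  diag <- data.frame(
    id1 = ids, id2 = ids, rmsd = 0, tm_1 = 1, tm_2 = 1, coverage = 1,
    n_pairs = vapply(ids, function(i) chain_length(members[[i]]$target),
                     integer(1)),
    stringsAsFactors = FALSE)
  sup <- stats::setNames(lapply(res, `[[`, "superposition"),
                         paste(pairs[1L, ], pairs[2L, ], sep = "|"))
  structure(list(table = rbind(diag, off), sup = sup, ids = ids),
            class = "pairwise_table")
}

# Look up the alignment row for an unordered id pair; returns the row with
# id1/id2 as stored (id1 < id2 for off-diagonal entries).
pair_row <- function(pt, a, b) {
  tab <- pt$table
  hit <- (tab$id1 == a & tab$id2 == b) | (tab$id1 == b & tab$id2 == a)
  tab[which(hit)[1L], , drop = FALSE]
}

# TM-score of the pair (a, b) normalized by member a's length.
pair_tm_for <- function(row, member_id) {
  if (row$id1 == member_id) row$tm_1 else row$tm_2
}

# Superposition mapping member's coordinates onto ref's frame.
pair_superposition <- function(pt, ref, member) {
  if (ref == member) {
    return(list(rotation = diag(3), translation = c(0, 0, 0)))
  }
  key <- paste(min(ref, member), max(ref, member), sep = "|")
  sup <- pt$sup[[key]]
  if (is.null(sup)) return(NULL)
  if (ref < member) sup else invert_superposition(sup)
}
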