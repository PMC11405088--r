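# Shared in-code fixtures: parametric fold chains, crafted PAE complexes and
# cached synthetic screens. Everything is generated at test time; nothing is
# stored on disk beyond tempdir().

AA20 <- binderclust:::AA20

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

fold_chain <- function(family, L, seq, sigma = 0, chain_id = "B",
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xyz <- make_fold(family, max(L, 10L))[seq_len(L), , drop = FALSE]
  if (sigma > 0) xyz <- xyz + matrix(stats::rnorm(L * 3, 0, sigma), ncol = 3)
  chain_structure(chain_id, seq, xyz)
}

# Deterministic sequence without touching the RNG stream.
fixed_seq <- function(n) paste(rep(AA20, length.out = n), collapse = "")

# A complex with a hand-crafted PAE matrix (bait residues first).
toy_record <- function(pae, id = "cpx", bait_len = 15L, target_len = NULL,
                       iptm = 0.9) {
  n <- nrow(pae)
  if (is.null(target_len)) target_len <- n - bait_len
  bait <- fold_chain(0L, bait_len, fixed_seq(bait_len), chain_id = "A")
  target <- fold_chain(0L, target_len, fixed_seq(target_len), chain_id = "B")
  complex_record(id, bait, target,
                 score_set(iptm, 0.85, 0.8 * iptm + 0.17, rep(80, n), pae))
}

# PAE with uniform background and a low block over target residues
# span[1]..span[2]-1 (0-based), both orientations.
planted_pae <- function(bait_len, target_len, span, low = 4, high = 28) {
  n <- bait_len + target_len
  pae <- matrix(high, n, n)
  cols <- bait_len + (span[1] + 1L):span[2]
  pae[seq_len(bait_len), cols] <- low
  pae[cols, seq_len(bait_len)] <- low
  pae
}

# Bare trimmed complex for clustering-level tests. The target is built
# first so a caller-set RNG state drives its noise.
toy_trimmed <- function(id, family, L, seq, sigma = 0, seed = NULL) {
  target <- fold_chain(family, L, seq, sigma, seed = seed)
  structure(list(complex_id = id,
                 bait = fold_chain(0L, 20L, fixed_seq(20), chain_id = "A"),
                 target = target,
                 bait_kept = matrix(c(0L, 20L), 1L),
                 target_kept = matrix(c(0L, L), 1L)),
            class = "trimmed_complex")
}

small_spec <- function(seed = 7L, n_decoys = 5L, members = 4L) {
  screen_spec(n_families = 3L, members_per_family = members,
              n_decoys = n_decoys, bait_length = 30L, target_length = 50L,
              interface_span = c(8L, 40L), seed = seed)
}

.screen_cache <- new.env(parent = emptyenv())

# Generate (once per test run) and return a synthetic screen directory.
fixture_screen <- function(key, spec) {
  if (is.null(.screen_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("bc_screen_", key))
    unlink(dir, recursive = TRUE)
    generate_screen(spec, dir)
    .screen_cache[[key]] <- dir
  }
  .screen_cache[[key]]
}

# Build a pairwise_table from an explicit symmetric RMSD matrix (and
# optional TM matrix) over given ids, mimicking all_vs_all output.
fake_pairwise <- function(ids, rmsd_mat, tm_mat = NULL, cov = 1) {
  if (is.null(tm_mat)) tm_mat <- matrix(0.8, length(ids), length(ids))
  rows <- list()
  for (i in seq_along(ids)) {
    rows[[length(rows) + 1L]] <- data.frame(
      id1 = ids[i], id2 = ids[i], rmsd = 0, tm_1 = 1, tm_2 = 1,
      coverage = 1, n_pairs = 10L, stringsAsFactors = FALSE)
    if (i < length(ids)) {
      for (j in (i + 1L):length(ids)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], rmsd = rmsd_mat[i, j],
          tm_1 = tm_mat[i, j], tm_2 = tm_mat[j, i], coverage = cov,
          n_pairs = 10L, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(table = do.call(rbind, rows), sup = list(), ids = ids),
            class = "pairwise_table")
}

suppress_logs <- function(expr) {
  old <- set_log_level("warn")
  on.exit(set_log_level(old))
  suppressMessages(expr)
}
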