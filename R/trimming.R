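# ipTM gating and PAE-based interface trimming.
#
# A screen model earns a place in clustering only if AlphaFold is confident
# about the interface (ipTM gate), and only the parts of each chain that are
# confidently positioned relative to the partner chain are kept (inter-chain
# PAE trimming). Trimming both chains to the interacting domains removes
# floppy tails and unengaged domains that would otherwise dominate sequence
# and fold comparisons.

#' Gate complexes by ipTM
#'
#' Retains complexes whose interface confidence is at or above the threshold
#' (the boundary is inclusive). Input order is preserved.
#'
#' @param records list of [complex_record].
#' @param threshold ipTM threshold in `[0, 1]`; default 0.75.
#' @return the retained sub-list.
#' @export
filter_by_iptm <- function(records, threshold = 0.75) {
  check_fraction(threshold, "threshold")
  keep <- vapply(records, function(r) r$scores$iptm >= threshold, logical(1))
  records[keep]
}

#' Per-residue interface confidence from the PAE matrix
#'
#' For each residue of one chain, the confidence of its placement relative to
#' the partner chain: the minimum over all partner residues of the
#' symmetrized inter-chain PAE (the smaller of the two orientations, since
#' PAE is asymmetric). Lower values mean more confident placement.
#'
#' @param pae square PAE matrix, bait residues first.
#' @param bait_len number of bait residues (rows/cols `1..bait_len`).
#' @return list with numeric vectors `target` (length `n - bait_len`) and
#'   `bait` (length `bait_len`).
#' @export
interface_confidence <- function(pae, bait_len) {
  pae <- as.matrix(pae)
  n <- nrow(pae)
  if (bait_len >= n || bait_len < 1L) {
    stopf("bait_len (%d) must be positive and smaller than the PAE side (%d)",
          bait_len, n)
  }
  bt <- pae[seq_len(bait_len), (bait_len + 1L):n, drop = FALSE]  # bait rows
  tb <- pae[(bait_len + 1L):n, seq_len(bait_len), drop = FALSE]  # target rows
  sym <- pmin(bt, t(tb))   # element-wise min of the two orientations
  list(target = apply(sym, 2L, min),
       bait = apply(sym, 1L, min))
}

# Seed-and-extend segmentation of a confidence vector: residues at or below
# the cutoff seed segments; seed runs separated by at most max_gap
# unconfident residues are bridged; runs still shorter than min_segment are
# dropped; surviving runs are padded and clipped to the chain.
# Returns 0-based half-open intervals.
segment_confident <- function(conf, pae_cutoff, pad, max_gap, min_segment) {
  n <- length(conf)
  seeds <- which(conf <= pae_cutoff) - 1L        # 0-based
  if (length(seeds) == 0L) return(indices_to_intervals(integer(0)))
  iv <- indices_to_intervals(seeds)
  # bridge runs across short unconfident gaps
  if (nrow(iv) > 1L) {
    merged <- iv[1, , drop = FALSE]
    for (k in 2:nrow(iv)) {
      gap <- iv[k, 1L] - merged[nrow(merged), 2L]
      if (gap <= max_gap) {
        merged[nrow(merged), 2L] <- iv[k, 2L]
      } else {
        merged <- rbind(merged, iv[k, , drop = FALSE])
      }
    }
    iv <- merged
  }
  iv <- iv[(iv[, 2L] - iv[, 1L]) >= min_segment, , drop = FALSE]
  if (nrow(iv) == 0L) return(iv)
  iv[, 1L] <- pmax(iv[, 1L] - pad, 0L)
  iv[, 2L] <- pmin(iv[, 2L] + pad, n)
  # padding may make neighbours touch; re-normalize
  indices_to_intervals(intervals_to_indices(iv))
}

#' Trim a complex to its confidently interacting regions
#'
#' Both chains are trimmed by the same procedure against the partner chain's
#' PAE block: residues with interface confidence at or below `pae_cutoff`
#' seed segments, seed runs separated by at most `max_gap` unconfident
#' residues are bridged, runs shorter than `min_segment` are dropped, and
#' surviving segments are padded by `pad` residues on each side (clipped to
#' the chain). If either chain retains nothing, the complex is discarded.
#'
#' @param rec a [complex_record].
#' @param pae_cutoff PAE threshold in Angstrom; default 12.
#' @param pad flanking residues kept around each segment; default 2.
#' @param max_gap largest unconfident gap bridged between seed runs; default 5.
#' @param min_segment shortest retained segment (before padding); default 10.
#' @return an object of class `trimmed_complex`, or `NULL` (with a logged
#'   reason) when nothing confident remains on one of the chains.
#' @export
trim_complex <- function(rec, pae_cutoff = 12, pad = 2L, max_gap = 5L,
                         min_segment = 10L) {
  if (min_segment < 1L) stopf("min_segment must be positive")
  if (pad < 0L || max_gap < 0L) stopf("pad and max_gap must be non-negative")
  bl <- chain_length(rec$bait)
  conf <- interface_confidence(rec$scores$pae, bl)
  bait_iv <- segment_confident(conf$bait, pae_cutoff, pad, max_gap, min_segment)
  target_iv <- segment_confident(conf$target, pae_cutoff, pad, max_gap, min_segment)
  if (nrow(bait_iv) == 0L || nrow(target_iv) == 0L) {
    side <- if (nrow(bait_iv) == 0L) "bait" else "target"
    bc_log("info", "discarding %s: no confident interface segment on the %s",
           rec$complex_id, side)
    return(NULL)
  }
  structure(list(complex_id = rec$complex_id,
                 bait_kept = bait_iv, target_kept = target_iv,
                 bait = chain_slice(rec$bait, intervals_to_indices(bait_iv)),
                 target = chain_slice(rec$target, intervals_to_indices(target_iv)),
                 scores = rec$scores),
            class = "trimmed_complex")
}

#' @export
print.trimmed_complex <- function(x, ...) {
  fmt_iv <- function(iv) paste(sprintf("[%d,%d)", iv[, 1], iv[, 2]),
                               collapse = " ")
  cat(sprintf("<trimmed %s> bait %d aa %s | target %d aa %s\n",
              x$complex_id, chain_length(x$bait), fmt_iv(x$bait_kept),
              chain_length(x$target), fmt_iv(x$target_kept)))
  invisible(x)
}

#' Trim a list of complexes, tracking discards
#'
#' @inheritParams trim_complex
#' @param records list of [complex_record].
#' @return list with `trimmed` (named list of `trimmed_complex`) and
#'   `discarded` (data frame of complex_id and reason), suitable for the
#'   sidecar audit CSV.
#' @export
trim_screen <- function(records, pae_cutoff = 12, pad = 2L, max_gap = 5L,
                        min_segment = 10L) {
  trimmed <- list()
  disc_id <- character(0); disc_reason <- character(0)
  for (rec in records) {
    tc <- trim_complex(rec, pae_cutoff, pad, max_gap, min_segment)
    if (is.null(tc)) {
      disc_id <- c(disc_id, rec$complex_id)
      disc_reason <- c(disc_reason, "no confident interface segment")
    } else {
      trimmed[[rec$complex_id]] <- tc
    }
  }
  list(trimmed = trimmed,
       discarded = data.frame(complex_id = disc_id, reason = disc_reason,
                              stringsAsFactors = FALSE))
}

#' Write trimmed models and sequences for the clustering stage
#'
#' Each complex becomes `<id>.pdb` (two chains, renumbered `1..n` per chain,
#' original author numbers preserved in REMARK 999 lines) and the trimmed
#' target sequences are pooled into `targets.fasta`.
#'
#' @param trimmed named list of `trimmed_complex`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_trimmed <- function(trimmed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- character(0)
  for (id in sort(names(trimmed))) {
    tc <- trimmed[[id]]
    renum <- function(ch) chain_structure(ch$chain_id, ch$sequence, ch$ca)
    remarks <- c(sprintf("ORIGINAL RESNO CHAIN %s %s", tc$bait$chain_id,
                         paste(tc$bait$resno, collapse = " ")),
                 sprintf("ORIGINAL RESNO CHAIN %s %s", tc$target$chain_id,
                         paste(tc$target$resno, collapse = " ")))
    write_pdb_chains(list(renum(tc$bait), renum(tc$target)),
                     file.path(out_dir, paste0(id, ".pdb")),
                     remarks = remarks)
    fasta <- c(fasta, paste0(">", id), tc$target$sequence)
  }
  writeLines(fasta, file.path(out_dir, "targets.fasta"))
  invisible(out_dir)
}
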