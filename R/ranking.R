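# Cluster ranking, optional subclustering of top clusters, and per-cluster
# viewer output. A plausible true binder family shows up as a large merged
# cluster whose members superpose tightly, so the default ordering is
# lexicographic: size (down), representative's median RMSD (up), median TM
# (down), representative coverage (down), label. An optional weighted
# composite score is available for users who prefer a single scalar.

#' Rank merged clusters
#'
#' Clusters smaller than `min_cluster_size` are excluded (families with too
#' few homologs in the screened proteome cannot be told apart from noise by
#' cluster size). The remainder are ordered by size descending, then the
#' representative's median RMSD ascending, median TM descending,
#' representative coverage descending, label ascending. With
#' `composite = TRUE` the order is instead by a weighted score
#' `w_size*log1p(size) + w_tm*median_tm - w_rmsd*median_rmsd +
#' w_cov*rep_coverage` (descending), ties by label.
#'
#' @param summaries list of cluster summary lists (from
#'   [cluster_summaries]`$summaries`).
#' @param min_cluster_size smallest ranked cluster; default 4.
#' @param composite use the weighted composite score instead of the
#'   lexicographic order; off by default.
#' @param weights named numeric vector with entries size, tm, rmsd, cov.
#' @return data frame with columns rank, label, size, median_rmsd,
#'   median_tm, rep_coverage, representative; one row per ranked cluster.
#' @export
rank_clusters <- function(summaries, min_cluster_size = 4L,
                          composite = FALSE,
                          weights = c(size = 1, tm = 1, rmsd = 1, cov = 1)) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(label = s$label, size = s$size,
               median_rmsd = s$median_rmsd %||% NA_real_,
               median_tm = s$median_tm %||% NA_real_,
               rep_coverage = s$rep_coverage %||% NA_real_,
               representative = s$representative, stringsAsFactors = FALSE)
  }))
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(rank = integer(0), label = character(0),
                      size = integer(0), median_rmsd = numeric(0),
                      median_tm = numeric(0), rep_coverage = numeric(0),
                      representative = character(0)))
  }
  df <- df[df$size >= min_cluster_size, , drop = FALSE]
  if (nrow(df) == 0L) return(cbind(rank = integer(0), df))
  na_last <- function(x, worst) ifelse(is.na(x), worst, x)
  if (composite) {
    score <- weights[["size"]] * log1p(df$size) +
      weights[["tm"]] * na_last(df$median_tm, 0) -
      weights[["rmsd"]] * na_last(df$median_rmsd, Inf) +
      weights[["cov"]] * na_last(df$rep_coverage, 0)
    ord <- order(-score, df$label)
  } else {
    ord <- order(-df$size, na_last(df$median_rmsd, Inf),
                 -na_last(df$median_tm, -Inf), -na_last(df$rep_coverage, -Inf),
                 df$label)
  }
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  cbind(rank = seq_len(nrow(df)), df)
}

#' Structure-only subclustering within a cluster
#'
#' Re-clusters one (typically top-ranked) cluster's members by fold alone at
#' a stricter TM threshold, separating distinct binding-competent
#' conformations or topologies that sequence similarity had merged.
#'
#' @param member_ids ids of the parent cluster's members (at least 2).
#' @param trimmed named list of `trimmed_complex` covering them.
#' @param min_tm stricter TM threshold; default 0.7.
#' @param min_cov coverage threshold; default 0.8.
#' @return a `partition` over the members, or `NULL` (logged) for
#'   single-member clusters.
#' @export
subcluster_structures <- function(member_ids, trimmed, min_tm = 0.7,
                                  min_cov = 0.8) {
  if (length(member_ids) < 2L) {
    bc_log("info", "subclustering skipped: cluster has fewer than 2 members")
    return(NULL)
  }
  cluster_structures(trimmed[sort(member_ids)], min_tm = min_tm,
                     min_cov = min_cov)
}

# One PyMOL 4x4 ttt matrix literal from a superposition.
pml_matrix <- function(sup) {
  m <- rbind(cbind(sup$rotation, sup$translation), c(0, 0, 0, 1))
  paste0("[", paste(sprintf("%.6f", as.numeric(t(m))), collapse = ", "), "]")
}

#' Write per-cluster directories with viewer command scripts
#'
#' For each of the `top_n` ranked clusters, creates `rank<r>_<label>/`
#' containing the members' trimmed PDB files and a `view_cluster.pml`
#' command script that loads every member, rigidly moves each member onto
#' the representative using the stored pairwise superposition of their
#' target chains, colors bait chains blue and target chains gray, and groups
#' the members. Scripts are plain text and byte-deterministic.
#'
#' @param ranked data frame from [rank_clusters].
#' @param merged the merged `partition` (for member lookup).
#' @param tables named list of per-cluster `pairwise_table` objects.
#' @param trimmed_dir directory holding the trimmed PDB files.
#' @param out_dir output directory.
#' @param top_n number of clusters to emit; default 5.
#' @return character vector of created directories, invisibly.
#' @export
write_viewer_sessions <- function(ranked, merged, tables, trimmed_dir,
                                  out_dir, top_n = 5L) {
  groups <- partition_members(merged)
  made <- character(0)
  for (k in seq_len(min(top_n, nrow(ranked)))) {
    r <- ranked[k, ]
    dir <- file.path(out_dir, sprintf("rank%d_%s", r$rank, r$label))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    members <- sort(groups[[r$label]])
    rep_id <- r$representative
    pt <- tables[[r$label]]
    lines <- c("# viewer script: one object per member, superposed on the",
               sprintf("# representative %s via the target-chain alignment", rep_id),
               "bg_color white")
    for (m in members) {
      src <- file.path(trimmed_dir, paste0(m, ".pdb"))
      file.copy(src, file.path(dir, paste0(m, ".pdb")), overwrite = TRUE)
      lines <- c(lines, sprintf("load %s.pdb, %s", m, m))
      sup <- if (is.null(pt)) NULL else pair_superposition(pt, rep_id, m)
      if (!is.null(sup) && m != rep_id) {
        lines <- c(lines, sprintf("transform_object %s, %s", m,
                                  pml_matrix(sup)))
      }
    }
    lines <- c(lines,
               "color marine, chain A",
               "color gray70, chain B",
               sprintf("group cluster_%s, %s", r$label,
                       paste(members, collapse = " ")),
               "zoom")
    writeLines(lines, file.path(dir, "view_cluster.pml"))
    made <- c(made, dir)
  }
  invisible(made)
}
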