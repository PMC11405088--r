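# Joint sequence + fold clustering of the trimmed targets.
#
# Both clusterings are greedy incremental with representative founding, in
# the spirit of the linear-time proteome clusterers: ids are visited by
# decreasing trimmed length (ties by id), each candidate joins the first
# founded cluster whose representative it matches, otherwise it founds its
# own. Sequence and structure partitions are then merged into joint clusters
# by connected components over shared members, which is what lets remote
# homologs caught by only one of the two criteria end up together.

new_partition <- function(labels, kind) {
  structure(list(labels = labels, kind = kind), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<%s partition> %d ids in %d clusters\n", x$kind,
              length(x$labels), length(unique(x$labels))))
  invisible(x)
}

partition_members <- function(p) split(names(p$labels), p$labels)

greedy_cluster <- function(ids, length_of, matches_rep) {
  ord <- ids[order(-vapply(ids, length_of, numeric(1)), ids)]
  reps <- character(0)
  labels <- character(0)
  for (id in ord) {
    assigned <- NA_character_
    for (r in reps) {
      if (matches_rep(r, id)) { assigned <- r; break }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      assigned <- id
    }
    labels[[id]] <- assigned
  }
  labels[ids]
}

#' Greedy sequence clustering of trimmed targets
#'
#' Ids are visited by decreasing sequence length (ties by id); each sequence
#' joins the first cluster whose founding representative it matches at
#' pairwise identity `>= min_id` (matches / alignment columns, counting gap
#' columns) with bidirectional coverage `>= min_cov` (matched columns /
#' length, for both sequences), else founds a new cluster.
#'
#' @param seqs named character vector (complex id -> trimmed target sequence).
#' @param min_id minimum pairwise identity fraction; default 0.30.
#' @param min_cov minimum coverage fraction of both sequences; default 0.8.
#' @return a `partition` of kind `"sequence"`; cluster labels are the
#'   founding representative ids.
#' @export
cluster_sequences <- function(seqs, min_id = 0.30, min_cov = 0.8) {
  if (length(seqs) == 0L) stopf("no sequences to cluster")
  check_fraction(min_id, "min_id"); check_fraction(min_cov, "min_cov")
  ids <- names(seqs)
  matches <- function(r, id) {
    corr <- align_sequences(seqs[[r]], seqs[[id]])
    np <- nrow(corr)
    if (np == 0L) return(FALSE)
    ra <- strsplit(seqs[[r]], "")[[1]][corr[, 1L]]
    ca <- strsplit(seqs[[id]], "")[[1]][corr[, 2L]]
    ident <- sum(ra == ca) / attr(corr, "ncol_aln")
    cov_r <- np / nchar(seqs[[r]]); cov_c <- np / nchar(seqs[[id]])
    ident >= min_id && cov_r >= min_cov && cov_c >= min_cov
  }
  new_partition(greedy_cluster(ids, function(id) nchar(seqs[[id]]), matches),
                "sequence")
}

#' Greedy structural clustering of trimmed targets
#'
#' Same greedy scheme as [cluster_sequences], with the membership test on
#' fold: [structural_align] against the founding representative must reach a
#' TM-score (normalized by the shorter structure) `>= min_tm` and coverage
#' `>= min_cov`.
#'
#' @param members named list of `trimmed_complex`.
#' @param min_tm minimum TM-score (shorter-normalized); default 0.5, the
#'   conventional same-fold threshold.
#' @param min_cov minimum aligned coverage of the shorter structure;
#'   default 0.8.
#' @return a `partition` of kind `"structure"`.
#' @export
cluster_structures <- function(members, min_tm = 0.5, min_cov = 0.8) {
  if (length(members) == 0L) stopf("no structures to cluster")
  check_fraction(min_tm, "min_tm"); check_fraction(min_cov, "min_cov")
  ids <- names(members)
  matches <- function(r, id) {
    t1 <- members[[r]]$target; t2 <- members[[id]]$target
    res <- structural_align(t1, t2)
    tm <- tm_shorter(res, chain_length(t1), chain_length(t2))
    !is.na(tm) && tm >= min_tm && res$coverage >= min_cov
  }
  new_partition(
    greedy_cluster(ids, function(id) chain_length(members[[id]]$target),
                   matches),
    "structure")
}

#' Merge sequence and structure partitions into joint clusters
#'
#' Two ids share a merged cluster iff they are connected in the bipartite
#' graph whose nodes are sequence clusters and structure clusters and whose
#' edges join clusters sharing at least one id (connected components). A
#' structure cluster can thereby bridge two sequence clusters (and vice
#' versa), which is how remote homologs end up in one joint cluster.
#'
#' @param seq,struct `partition` objects over the identical id universe.
#' @return a `partition` of kind `"merged"`; each merged label is the
#'   lexicographically smallest member id of its component.
#' @export
merge_partitions <- function(seq, struct) {
  ids <- sort(names(seq$labels))
  if (!identical(ids, sort(names(struct$labels)))) {
    stopf("sequence and structure partitions cover different id sets")
  }
  snodes <- paste0("s:", seq$labels[ids])
  tnodes <- paste0("t:", struct$labels[ids])
  g <- igraph::graph_from_data_frame(data.frame(from = snodes, to = tnodes),
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  comp_of_id <- comp[snodes]
  labels <- vapply(split(ids, comp_of_id), min, character(1))[as.character(comp_of_id)]
  new_partition(stats::setNames(labels, ids), "merged")
}

#' Select a cluster representative by lowest median RMSD
#'
#' For each member, the median over its pairwise alignments to all other
#' members of RMSD and of TM-score (normalized by that member's length). The
#' representative is the member with the lowest median RMSD; ties break by
#' higher median TM, then lexicographically smaller id. Pairs with undefined
#' RMSD (degenerate alignments) are excluded from that member's medians; a
#' member with no defined pair has missing medians and cannot be
#' representative.
#'
#' @param member_ids ids of the cluster members (at least 1).
#' @param table a `pairwise_table` from [all_vs_all] covering the members.
#' @return list with `representative` and `medians`, a data frame of
#'   complex_id, median_rmsd, median_tm, median_coverage.
#' @export
select_representative <- function(member_ids, table) {
  ids <- sort(member_ids)
  if (length(ids) == 1L) {
    return(list(representative = ids,
                medians = data.frame(complex_id = ids,
                                     median_rmsd = NA_real_,
                                     median_tm = NA_real_,
                                     median_coverage = NA_real_,
                                     stringsAsFactors = FALSE)))
  }
  med <- lapply(ids, function(m) {
    others <- setdiff(ids, m)
    rows <- lapply(others, function(o) pair_row(table, m, o))
    rmsds <- vapply(rows, `[[`, numeric(1), "rmsd")
    tms <- vapply(rows, pair_tm_for, numeric(1), member_id = m)
    covs <- vapply(rows, `[[`, numeric(1), "coverage")
    ok <- !is.na(rmsds)
    data.frame(complex_id = m,
               median_rmsd = if (any(ok)) stats::median(rmsds[ok]) else NA_real_,
               median_tm = if (any(ok)) stats::median(tms[ok]) else NA_real_,
               median_coverage = if (any(ok)) stats::median(covs[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  med <- do.call(rbind, med)
  eligible <- med[!is.na(med$median_rmsd), , drop = FALSE]
  if (nrow(eligible) == 0L) {
    rep_id <- ids[1L]
  } else {
    ord <- order(eligible$median_rmsd, -eligible$median_tm,
                 eligible$complex_id)
    rep_id <- eligible$complex_id[ord[1L]]
  }
  list(representative = rep_id, medians = med)
}

#' Summarize merged clusters
#'
#' Runs the all-vs-all alignment within every merged cluster of size >= 2
#' and selects representatives.
#'
#' @param merged a `partition` of kind `"merged"`.
#' @param trimmed named list of `trimmed_complex`.
#' @param cpus workers for the all-vs-all step.
#' @return list with `summaries` (list of per-cluster summary lists: label,
#'   members, size, representative, median_rmsd, median_tm, rep_coverage),
#'   `medians` (per-member data frame), and `tables` (per-cluster
#'   `pairwise_table`, named by label).
#' @export
cluster_summaries <- function(merged, trimmed, cpus = 1L) {
  groups <- partition_members(merged)
  summaries <- list(); tables <- list(); med_rows <- list()
  for (lab in sort(names(groups))) {
    ids <- sort(groups[[lab]])
    if (length(ids) >= 2L) {
      pt <- all_vs_all(trimmed[ids], cpus = cpus)
      sel <- select_representative(ids, pt)
      tables[[lab]] <- pt
    } else {
      sel <- select_representative(ids, NULL)
    }
    rep_row <- sel$medians[sel$medians$complex_id == sel$representative, ]
    summaries[[lab]] <- list(
      label = lab, members = ids, size = length(ids),
      representative = sel$representative,
      median_rmsd = rep_row$median_rmsd,
      median_tm = rep_row$median_tm,
      rep_coverage = rep_row$median_coverage)
    med_rows[[lab]] <- sel$medians
  }
  list(summaries = summaries, medians = do.call(rbind, med_rows),
       tables = tables)
}

#' Write the clustering-stage CSV tables
#'
#' Produces `merged_clusters/merged_clusters.csv` (one row per complex:
#' AlphaFold scores, sequence/structure/merged cluster labels, per-member
#' median RMSD and TM against the rest of its merged cluster, representative
#' flag; rows sorted by merged-cluster size descending, then label, then
#' complex id; missing medians are empty fields), plus
#' `sequence_clusters.csv`, `structure_clusters.csv`, a per-cluster summary
#' table and the serialized pairwise alignments.
#'
#' @param records named list of [complex_record] (for the score columns).
#' @param seq_part,struct_part,merged `partition` objects.
#' @param summ result of [cluster_summaries].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cluster_tables <- function(records, seq_part, struct_part, merged,
                                 summ, out_dir) {
  mc_dir <- file.path(out_dir, "merged_clusters")
  dir.create(mc_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sort(names(merged$labels))
  sizes <- table(merged$labels)
  med <- summ$medians
  rownames(med) <- med$complex_id
  reps <- vapply(summ$summaries, `[[`, character(1), "representative")
  df <- data.frame(
    complex_id = ids,
    iptm = fmt_num(vapply(ids, function(i) records[[i]]$scores$iptm, numeric(1)), 4L),
    iptm_ptm = fmt_num(vapply(ids, function(i) records[[i]]$scores$combined, numeric(1)), 4L),
    seq_cluster = unname(seq_part$labels[ids]),
    struct_cluster = unname(struct_part$labels[ids]),
    merged_cluster = unname(merged$labels[ids]),
    median_rmsd = fmt_num(med[ids, "median_rmsd"], 4L),
    median_tm = fmt_num(med[ids, "median_tm"], 4L),
    is_representative = tolower(ids %in% reps),
    stringsAsFactors = FALSE)
  ord <- order(-as.integer(sizes[df$merged_cluster]), df$merged_cluster,
               df$complex_id)
  write_csv_det(df[ord, ], file.path(mc_dir, "merged_clusters.csv"))

  part_df <- function(p) {
    data.frame(complex_id = ids, cluster = unname(p$labels[ids]),
               stringsAsFactors = FALSE)
  }
  write_csv_det(part_df(seq_part), file.path(out_dir, "sequence_clusters.csv"))
  write_csv_det(part_df(struct_part), file.path(out_dir, "structure_clusters.csv"))

  labs <- sort(names(summ$summaries))
  cs <- do.call(rbind, lapply(labs, function(l) {
    s <- summ$summaries[[l]]
    data.frame(label = s$label, size = s$size,
               representative = s$representative,
               median_rmsd = fmt_num(s$median_rmsd, 4L),
               median_tm = fmt_num(s$median_tm, 4L),
               rep_coverage = fmt_num(s$rep_coverage, 4L),
               stringsAsFactors = FALSE)
  }))
  cs <- cs[order(-cs$size, cs$label), ]
  write_csv_det(cs, file.path(mc_dir, "cluster_summaries.csv"))
  write_pairwise_tables(summ$tables, file.path(out_dir, "pairwise"))
  invisible(out_dir)
}

write_pairwise_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln <- list(); sups <- list()
  for (lab in sort(names(tables))) {
    pt <- tables[[lab]]
    tab <- pt$table
    tab <- tab[order(tab$id1, tab$id2), ]
    aln[[lab]] <- data.frame(
      cluster = lab, id1 = tab$id1, id2 = tab$id2,
      rmsd = fmt_num(tab$rmsd, 4L), tm_1 = fmt_num(tab$tm_1, 4L),
      tm_2 = fmt_num(tab$tm_2, 4L), coverage = fmt_num(tab$coverage, 4L),
      n_pairs = tab$n_pairs, stringsAsFactors = FALSE)
    keys <- sort(names(pt$sup))
    sups[[lab]] <- do.call(rbind, lapply(keys, function(k) {
      s <- pt$sup[[k]]
      if (is.null(s)) return(NULL)
      idp <- strsplit(k, "|", fixed = TRUE)[[1]]
      m <- cbind(s$rotation, s$translation)
      data.frame(id1 = idp[1], id2 = idp[2],
                 t(stats::setNames(as.numeric(t(m)),
                                   c("r11","r12","r13","t1","r21","r22","r23",
                                     "t2","r31","r32","r33","t3"))),
                 stringsAsFactors = FALSE)
    }))
  }
  aln_df <- do.call(rbind, aln) %||% data.frame()
  write_csv_det(aln_df, file.path(dir, "alignments.csv"))
  sup_df <- do.call(rbind, Filter(Negate(is.null), sups))
  if (is.null(sup_df)) {
    sup_df <- data.frame(id1 = character(0), id2 = character(0))
  } else {
    num_cols <- setdiff(names(sup_df), c("id1", "id2"))
    for (cc in num_cols) sup_df[[cc]] <- sprintf("%.9f", sup_df[[cc]])
  }
  write_csv_det(sup_df, file.path(dir, "superpositions.csv"))
  invisible(dir)
}
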