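# Readers and writers for one-against-many AlphaFold-Multimer screen output:
# a ranking JSON per complex (the ranking_debug.json schema: an "order" list
# plus a map from model name to ipTM+pTM confidence), a two-chain PDB
# coordinate file for the best model, and a JSON score file carrying iptm,
# ptm, per-residue plddt and the NxN PAE matrix.  AlphaFold itself writes the
# scores as a pickle; converting one to this dialect is a single line of
# Python:
#   json.dump({k: v.tolist() if hasattr(v, "tolist") else float(v)
#              for k, v in pickle.load(open(f, "rb")).items()
#              if k in ("iptm", "ptm", "plddt",
#                       "predicted_aligned_error")}, out)
# (the key "predicted_aligned_error" is accepted as a synonym of "pae").

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", X = "UNK")
AA1 <- stats::setNames(names(AA3), AA3)
AA20 <- names(AA3)[1:20]

#' Construct a single-chain CA-trace structure
#'
#' The pipeline's structural unit: one chain reduced to its C-alpha trace,
#' with a one-letter sequence and the author residue numbers from the
#' coordinate file. All structural math (trimming, superposition, TM-scores)
#' operates on these traces.
#'
#' @param chain_id single-character chain label.
#' @param sequence one-letter amino-acid string (20 standard letters plus X).
#' @param ca_coords numeric matrix, one row per residue, columns x/y/z in
#'   Angstrom.
#' @param residue_numbers strictly increasing author residue numbers; defaults
#'   to `1..n`.
#' @return an object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, sequence, ca_coords,
                            residue_numbers = NULL) {
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  colnames(ca_coords) <- c("x", "y", "z")
  n <- nrow(ca_coords)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  x <- structure(list(chain_id = as.character(chain_id),
                      sequence = as.character(sequence),
                      ca = ca_coords,
                      resno = as.integer(residue_numbers)),
                 class = "chain_structure")
  validate_chain(x)
  x
}

validate_chain <- function(x) {
  n <- nchar(x$sequence)
  if (n != nrow(x$ca) || n != length(x$resno)) {
    stopf("chain %s: sequence length (%d), coordinates (%d) and residue numbers (%d) disagree",
          x$chain_id, n, nrow(x$ca), length(x$resno))
  }
  if (n > 1L && any(diff(x$resno) <= 0L)) {
    stopf("chain %s: residue numbers must be strictly increasing", x$chain_id)
  }
  bad <- setdiff(strsplit(x$sequence, "")[[1]], c(AA20, "X"))
  if (length(bad) > 0L) {
    stopf("chain %s: non-standard residue letters: %s", x$chain_id,
          paste(unique(bad), collapse = ""))
  }
  invisible(x)
}

chain_length <- function(x) nrow(x$ca)

# Subset a chain to 0-based residue indices (keeps order).
chain_slice <- function(x, idx0) {
  idx <- as.integer(idx0) + 1L
  chain_structure(x$chain_id,
                  paste(strsplit(x$sequence, "")[[1]][idx], collapse = ""),
                  x$ca[idx, , drop = FALSE],
                  x$resno[idx])
}

#' Construct a model score set
#'
#' @param iptm interface predicted TM-score in `[0, 1]`.
#' @param ptm predicted TM-score in `[0, 1]`.
#' @param combined the ipTM+pTM ranking confidence in `[0, 1]`.
#' @param plddt per-residue local confidence in `[0, 100]`, over bait then
#'   target residues.
#' @param pae square predicted-aligned-error matrix (Angstrom), side equal to
#'   the total residue count.
#' @return an object of class `score_set`.
#' @export
score_set <- function(iptm, ptm, combined, plddt, pae) {
  pae <- as.matrix(pae)
  x <- structure(list(iptm = as.numeric(iptm), ptm = as.numeric(ptm),
                      combined = as.numeric(combined),
                      plddt = as.numeric(plddt), pae = pae),
                 class = "score_set")
  for (f in c("iptm", "ptm", "combined")) check_fraction(x[[f]], f)
  if (nrow(pae) != ncol(pae)) {
    stopf("PAE matrix must be square, got %d x %d", nrow(pae), ncol(pae))
  }
  if (any(pae < 0)) stopf("PAE entries must be non-negative")
  if (length(x$plddt) != nrow(pae)) {
    stopf("plddt length (%d) must equal PAE side (%d)",
          length(x$plddt), nrow(pae))
  }
  x
}

#' Construct a bait--target complex record
#'
#' One modeled complex from the screen: the bait chain (first chain in the
#' coordinate file), the candidate target chain, and the model's scores. The
#' PAE matrix is indexed bait residues first, then target residues.
#'
#' @param complex_id identifier string (e.g. a UniProt accession).
#' @param bait,target [chain_structure] objects.
#' @param scores a [score_set]; its PAE side must equal the summed chain
#'   lengths.
#' @return an object of class `complex_record`.
#' @export
complex_record <- function(complex_id, bait, target, scores) {
  x <- structure(list(complex_id = as.character(complex_id), bait = bait,
                      target = target, scores = scores),
                 class = "complex_record")
  validate_chain(bait); validate_chain(target)
  ntot <- chain_length(bait) + chain_length(target)
  if (nrow(scores$pae) != ntot) {
    stopf("complex %s: PAE side %d does not match bait+target residues %d",
          complex_id, nrow(scores$pae), ntot)
  }
  x
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf("<complex %s> bait %s (%d aa), target %s (%d aa), ipTM %.3f\n",
              x$complex_id, x$bait$chain_id, chain_length(x$bait),
              x$target$chain_id, chain_length(x$target), x$scores$iptm))
  invisible(x)
}

#' Read an AlphaFold ranking file
#'
#' Parses the `ranking_debug.json` schema: an `"order"` list of model names
#' (best first) and a map from model name to the ipTM+pTM ranking confidence
#' (under `"iptm+ptm"`, or the first map-valued key otherwise).
#'
#' @param path path to the ranking JSON.
#' @return named numeric vector of confidences, with attribute `best` set to
#'   the first name of the order list.
#' @export
read_ranking <- function(path) {
  dat <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stopf("cannot parse ranking file %s: %s",
                                            path, conditionMessage(e)))
  if (is.null(dat$order) || length(dat$order) == 0L) {
    stopf("ranking file %s has an empty or missing order list", path)
  }
  conf <- dat[["iptm+ptm"]]
  if (is.null(conf)) {
    maps <- Filter(function(v) is.list(v) || (is.numeric(v) && !is.null(names(v))),
                   dat[setdiff(names(dat), "order")])
    if (length(maps) == 0L) stopf("ranking file %s has no confidence map", path)
    conf <- maps[[1]]
  }
  conf <- unlist(conf)
  structure(conf, best = dat$order[[1]])
}

read_score_json <- function(path) {
  dat <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stopf("cannot parse score file %s: %s",
                                            path, conditionMessage(e)))
  pae <- dat$pae %||% dat$predicted_aligned_error
  for (f in c("iptm", "ptm", "plddt")) {
    if (is.null(dat[[f]])) stopf("score file %s lacks field '%s'", path, f)
  }
  if (is.null(pae)) stopf("score file %s lacks field 'pae'", path)
  list(iptm = dat$iptm, ptm = dat$ptm, plddt = as.numeric(dat$plddt),
       pae = as.matrix(pae))
}

write_score_json <- function(scores, path) {
  jsonlite::write_json(list(iptm = scores$iptm, ptm = scores$ptm,
                            plddt = scores$plddt, pae = scores$pae),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Parse a two-chain CA-trace PDB into a pair of chain_structure objects.
# Residues lacking a CA atom are dropped (with a warning) because every
# downstream operation is CA-based.
read_pdb_chains <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  atoms <- pdb$atom
  chains <- unique(atoms$chain)
  if (length(chains) != 2L) {
    stopf("%s: expected exactly 2 chains, found %d (%s)", path,
          length(chains), paste(chains, collapse = ","))
  }
  lapply(chains, function(ch) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    n_res <- length(unique(sub$resno))
    ca <- sub[sub$elety == "CA", , drop = FALSE]
    if (nrow(ca) < n_res) {
      bc_log("warn", "%s chain %s: dropped %d residue(s) without CA atoms",
             basename(path), ch, n_res - nrow(ca))
    }
    seq1 <- AA1[ca$resid]
    seq1[is.na(seq1)] <- "X"
    chain_structure(ch, paste(seq1, collapse = ""),
                    cbind(ca$x, ca$y, ca$z), ca$resno)
  })
}

# Canonical fixed-width PDB writer for CA traces.  bio3d is used for reading;
# writing goes through this formatter so that emitted files are byte-stable
# and can carry REMARK lines (original author numbering of trimmed chains).
write_pdb_chains <- function(chains, path, plddt = NULL, remarks = character(0)) {
  lines <- character(0)
  if (length(remarks) > 0L) lines <- sprintf("REMARK 999 %s", remarks)
  serial <- 0L
  offset <- 0L
  for (ch in chains) {
    n <- chain_length(ch)
    aa <- AA3[strsplit(ch$sequence, "")[[1]]]
    b <- if (is.null(plddt)) rep(0, n) else plddt[offset + seq_len(n)]
    for (i in seq_len(n)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, aa[i], ch$chain_id, ch$resno[i],
        ch$ca[i, 1], ch$ca[i, 2], ch$ca[i, 3], 1.00, b[i]))
    }
    lines <- c(lines, "TER")
    offset <- offset + n
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read one bait--target complex
#'
#' @param pdb_path two-chain PDB coordinate file; the bait must be the first
#'   chain. Only CA atoms are retained.
#' @param scores_path JSON score file with fields `iptm`, `ptm`, `plddt` and
#'   `pae`; the PAE side must equal the total residue count.
#' @param complex_id identifier; defaults to the parent directory name of
#'   `pdb_path`.
#' @param combined the ipTM+pTM ranking confidence (from [read_ranking]);
#'   defaults to `0.8*iptm + 0.2*ptm`, AlphaFold-Multimer's ranking formula.
#' @return a [complex_record].
#' @export
read_complex <- function(pdb_path, scores_path, complex_id = NULL,
                         combined = NULL) {
  if (is.null(complex_id)) complex_id <- basename(dirname(pdb_path))
  chains <- read_pdb_chains(pdb_path)
  sc <- read_score_json(scores_path)
  if (is.null(combined)) combined <- 0.8 * sc$iptm + 0.2 * sc$ptm
  complex_record(complex_id, chains[[1]], chains[[2]],
                 score_set(sc$iptm, sc$ptm, combined, sc$plddt, sc$pae))
}

#' Write one complex back to disk
#'
#' Emits the same layout [read_complex] consumes: `<model_name>.pdb` and
#' `<model_name>_scores.json` inside `dir`. Per-residue pLDDT is placed in
#' the B-factor column.
#'
#' @param rec a [complex_record].
#' @param dir output directory (created if absent).
#' @param model_name file stem for the model.
#' @return `dir`, invisibly.
#' @export
write_complex <- function(rec, dir, model_name = "model_1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb_chains(list(rec$bait, rec$target),
                   file.path(dir, paste0(model_name, ".pdb")),
                   plddt = rec$scores$plddt)
  write_score_json(rec$scores,
                   file.path(dir, paste0(model_name, "_scores.json")))
  invisible(dir)
}

#' Load a whole screen directory
#'
#' Expects one sub-directory per complex, each holding a
#' `ranking_debug.json`, plus `<model>.pdb` and `<model>_scores.json` for the
#' best model named by the ranking's order list. Complexes that fail
#' validation are skipped with a logged warning, never fatal, so one corrupt
#' model does not sink a screen.
#'
#' @param models_dir directory of per-complex sub-directories.
#' @return list of [complex_record], sorted lexicographically by complex id
#'   (invariant to filesystem enumeration order).
#' @export
load_screen <- function(models_dir) {
  if (!dir.exists(models_dir)) stopf("models directory %s does not exist", models_dir)
  subdirs <- sort(list.dirs(models_dir, recursive = FALSE))
  if (length(subdirs) == 0L) {
    bc_log("warn", "no complex directories found under %s", models_dir)
    return(list())
  }
  recs <- list()
  for (d in subdirs) {
    id <- basename(d)
    rec <- tryCatch({
      rk <- read_ranking(file.path(d, "ranking_debug.json"))
      best <- attr(rk, "best")
      read_complex(file.path(d, paste0(best, ".pdb")),
                   file.path(d, paste0(best, "_scores.json")),
                   complex_id = id, combined = unname(rk[[best]]))
    }, error = function(e) {
      bc_log("warn", "skipping complex %s: %s", id, conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) recs[[id]] <- rec
  }
  recs[order(names(recs))]
}
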