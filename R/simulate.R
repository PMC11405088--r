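# Synthetic screen generator with known ground truth.
#
# Emits exactly the directory layout the readers consume — per-complex PDB +
# score JSON + ranking JSON — for planted binder families (shared parametric
# fold, shared mutated consensus sequence, a contiguous low-PAE inter-chain
# interface, high ipTM) and decoys (random coil, uniform high PAE,
# sub-threshold ipTM), together with a manifest of the planted truth. Every
# complex draws from its own RNG stream seeded by (seed, complex index), so
# regenerating any subset is stable.

#' Specification of a synthetic screen
#'
#' Defaults define the documented reference screen: 3 planted binder
#' families of 12 members each, 50 decoys below the default ipTM gate, a
#' 40-residue planted interface on a 60-residue target, 0.5 Angstrom
#' coordinate noise and a 0.1 per-residue mutation rate.
#'
#' @param n_families number of planted binder families.
#' @param members_per_family members per family.
#' @param n_decoys decoy complexes.
#' @param bait_length,target_length chain lengths in residues.
#' @param interface_span 0-based half-open residue interval on the target
#'   given the low-PAE inter-chain block.
#' @param coord_noise_sigma per-coordinate Gaussian noise, Angstrom.
#' @param mutation_rate per-residue probability of mutating away from the
#'   family consensus.
#' @param iptm_true central ipTM of family members (jittered by +-0.02).
#' @param iptm_decoy ipTM assigned to decoys (below the default gate).
#' @param seed integer master seed.
#' @return a list of class `screen_spec`.
#' @export
screen_spec <- function(n_families = 3L, members_per_family = 12L,
                        n_decoys = 50L, bait_length = 50L,
                        target_length = 60L, interface_span = c(10L, 50L),
                        coord_noise_sigma = 0.5, mutation_rate = 0.1,
                        iptm_true = 0.85, iptm_decoy = 0.40, seed = 1L) {
  sp <- list(n_families = as.integer(n_families),
             members_per_family = as.integer(members_per_family),
             n_decoys = as.integer(n_decoys),
             bait_length = as.integer(bait_length),
             target_length = as.integer(target_length),
             interface_span = as.integer(interface_span),
             coord_noise_sigma = coord_noise_sigma,
             mutation_rate = mutation_rate,
             iptm_true = iptm_true, iptm_decoy = iptm_decoy,
             seed = as.integer(seed))
  if (sp$interface_span[1] < 0L || sp$interface_span[2] > sp$target_length ||
      sp$interface_span[1] >= sp$interface_span[2]) {
    stopf("interface_span must be a non-empty interval within [0, target_length)")
  }
  check_fraction(sp$mutation_rate, "mutation_rate")
  if (any(c(sp$n_families, sp$members_per_family, sp$n_decoys) < 0L)) {
    stopf("counts must be non-negative")
  }
  structure(sp, class = "screen_spec")
}

# Derived per-complex RNG seed; kept well below 2^31.
complex_seed <- function(seed, idx) {
  (as.integer(seed) %% 65011L) * 32749L + as.integer(idx)
}

#' Deterministic parametric CA fold
#'
#' Family 0 is an ideal alpha-helical trace (1.5 Angstrom rise, 2.3 Angstrom
#' radius, 100 degrees per residue); family 1 a beta-hairpin (two
#' antiparallel pleated strands, 3.3 Angstrom axial rise, 4.8 Angstrom
#' strand separation, one apex residue); families >= 2 are helix-turn-helix
#' variants whose second helix is tilted by a family-specific angle.
#' Consecutive CA-CA distances fall in [3.7, 3.9] Angstrom by construction.
#'
#' @param family non-negative integer fold family index.
#' @param length number of residues (>= 10).
#' @return numeric `length` x 3 coordinate matrix.
#' @export
make_fold <- function(family, length) {
  if (length < 10L) stopf("fold length must be at least 10")
  n <- as.integer(length)
  helix <- function(n, phase = 0) {
    i <- seq_len(n) - 1L
    ang <- (100 * i + phase) * pi / 180
    cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  }
  if (family == 0L) {
    xyz <- helix(n)
  } else if (family == 1L) {
    dx <- sqrt(3.8^2 - 3.3^2) / 2          # pleat amplitude: CA-CA = 3.8
    m <- (n - 1L) %/% 2L                   # up-strand residues
    i <- seq_len(m) - 1L
    up <- cbind(dx * (-1)^i, rep(0, m), 3.3 * i)
    ztop <- 3.3 * (m - 1L)
    apex <- c(0, 2.4, ztop + sqrt(3.8^2 - dx^2 - 2.4^2))
    k <- n - m - 1L                        # down-strand residues
    j <- seq_len(k) - 1L
    down <- cbind(dx * (-1)^j, rep(4.8, k), ztop - 3.3 * j)
    xyz <- rbind(up, matrix(apex, 1L), down)
  } else {
    # helix-turn-helix: second helix axis tilted about x by a family angle
    theta <- (25 + 40 * (family %% 6L)) * pi / 180
    m <- n %/% 2L
    h1 <- helix(m)
    rot <- rbind(c(1, 0, 0),
                 c(0, cos(theta), -sin(theta)),
                 c(0, sin(theta), cos(theta)))
    h2 <- helix(n - m) %*% t(rot)
    # place h2 so its first CA sits 3.8 A beyond h1's last CA along the
    # tilted axis
    axis2 <- as.numeric(rot %*% c(0, 0, 1))
    shift <- h1[m, ] + 3.8 * axis2 - h2[1L, ]
    xyz <- rbind(h1, sweep(h2, 2L, shift, `+`))
  }
  unname(xyz)
}

random_rotation <- function() {
  # QR-based uniform random rotation, reflection-corrected
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

random_sequence <- function(n) paste(sample(AA20, n, replace = TRUE),
                                     collapse = "")

mutate_sequence <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(s)) < rate
  if (any(hit)) {
    s[hit] <- vapply(s[hit],
                     function(a) sample(setdiff(AA20, a), 1L), character(1))
  }
  paste(s, collapse = "")
}

# Random-walk CA trace with 3.8 A steps (decoy "fold").
random_coil <- function(n) {
  steps <- matrix(stats::rnorm(3L * (n - 1L)), ncol = 3L)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
}

build_pae <- function(n_total, bait_len, span, interface = TRUE) {
  pae <- matrix(stats::runif(n_total^2, 25, 30), n_total)
  if (interface) {
    cols <- bait_len + (span[1] + 1L):span[2]
    rows <- seq_len(bait_len)
    k <- length(rows) * length(cols)
    pae[rows, cols] <- stats::runif(k, 2, 6)
    pae[cols, rows] <- stats::runif(k, 2, 6)
  }
  round(pae, 2L)
}

#' Generate a synthetic screen directory
#'
#' Writes one sub-directory per complex (`ranking_debug.json`,
#' `model_1.pdb`, `model_1_scores.json`) plus `manifest.csv` recording the
#' planted ground truth (complex_id, family, is_decoy, interface interval).
#' Family members share the family fold (plus Gaussian coordinate noise) and
#' a mutated consensus sequence, are placed beside a common helical bait,
#' and carry a low-PAE inter-chain block over the interface span with
#' gate-passing ipTM. Decoys get random-coil targets in random placements,
#' uniformly high PAE and sub-threshold ipTM. Byte-reproducible from the
#' seed.
#'
#' @param spec a [screen_spec].
#' @param out_dir output directory (created; must not already contain
#'   complexes with the same ids).
#' @return path to `manifest.csv`, invisibly.
#' @export
generate_screen <- function(spec, out_dir) {
  stopifnot(inherits(spec, "screen_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  span <- spec$interface_span
  bait_fold <- make_fold(0L, spec$bait_length)
  # family consensus sequences; depend only on (seed, family)
  consensus <- lapply(seq_len(spec$n_families), function(f) {
    set.seed(complex_seed(spec$seed, 100000L + f))
    random_sequence(spec$target_length)
  })
  set.seed(complex_seed(spec$seed, 100001L + spec$n_families))
  bait_seq <- random_sequence(spec$bait_length)

  man <- list()
  idx <- 0L
  emit <- function(id, target_chain, iptm, family, is_decoy, has_interface) {
    n_total <- spec$bait_length + chain_length(target_chain)
    pae <- build_pae(n_total, spec$bait_length, span, interface = has_interface)
    plddt <- round(if (is_decoy) stats::runif(n_total, 40, 60)
                   else stats::runif(n_total, 80, 95), 2L)
    ptm <- round(max(0, min(1, iptm - 0.05)), 4L)
    combined <- round(0.8 * iptm + 0.2 * ptm, 4L)
    bait_chain <- chain_structure("A", bait_seq, round(bait_fold, 3L))
    rec <- complex_record(id, bait_chain, target_chain,
                          score_set(iptm, ptm, combined, plddt, pae))
    d <- file.path(out_dir, id)
    write_complex(rec, d, "model_1")
    jsonlite::write_json(list(order = list("model_1"),
                              `iptm+ptm` = list(model_1 = combined)),
                         file.path(d, "ranking_debug.json"),
                         auto_unbox = TRUE, digits = NA)
    man[[id]] <<- data.frame(
      complex_id = id, family = if (is_decoy) NA_integer_ else family,
      is_decoy = is_decoy,
      interface_start = if (has_interface) span[1] else NA_integer_,
      interface_end = if (has_interface) span[2] else NA_integer_,
      stringsAsFactors = FALSE)
  }

  for (f in seq_len(spec$n_families)) {
    fold <- make_fold(f - 1L, spec$target_length)
    for (m in seq_len(spec$members_per_family)) {
      idx <- idx + 1L
      set.seed(complex_seed(spec$seed, idx))
      id <- sprintf("fam%d_mem%02d", f, m)
      xyz <- fold + matrix(stats::rnorm(length(fold), 0, spec$coord_noise_sigma),
                           ncol = 3L)
      xyz <- sweep(xyz, 2L, c(20, 0, 0), `+`)   # sit beside the bait
      seqm <- mutate_sequence(consensus[[f]], spec$mutation_rate)
      iptm <- round(max(0, min(1, spec$iptm_true + stats::runif(1, -0.02, 0.02))), 4L)
      emit(id, chain_structure("B", seqm, round(xyz, 3L)), iptm,
           family = f, is_decoy = FALSE, has_interface = TRUE)
    }
  }
  for (k in seq_len(spec$n_decoys)) {
    idx <- idx + 1L
    set.seed(complex_seed(spec$seed, idx))
    id <- sprintf("decoy%03d", k)
    xyz <- random_coil(spec$target_length) %*% t(random_rotation())
    xyz <- sweep(xyz, 2L, c(30, 0, 0) + stats::rnorm(3L, 0, 5), `+`)
    emit(id, chain_structure("B", random_sequence(spec$target_length),
                             round(xyz, 3L)),
         spec$iptm_decoy, family = NA_integer_, is_decoy = TRUE,
         has_interface = FALSE)
  }
  man_df <- do.call(rbind, man[sort(names(man))]) %||%
    data.frame(complex_id = character(0))
  path <- file.path(out_dir, "manifest.csv")
  write_csv_det(man_df, path)
  bc_log("info", "generated %d complexes under %s", idx, out_dir)
  invisible(path)
}
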