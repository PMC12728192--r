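# ---------------------------------------------------------------------------
# Geometric hydrogen-bond detection: strict donor-H-acceptor mode for
# structures with hydrogens, heavy-atom mode for deposited models without.
# ---------------------------------------------------------------------------

#' Hydrogen-bond acceptance criteria
#'
#' The angle criterion bounds the deviation from linearity of the
#' donor-H-acceptor angle: a 30 degree cutoff accepts bonds with
#' D-H...A >= 150 degrees. In heavy-atom mode (`require_hydrogen = FALSE`)
#' only the donor-acceptor distance applies, plus a donor-acceptor-antecedent
#' plausibility filter of >= 90 degrees.
#'
#' @param max_da_distance donor-acceptor heavy-atom distance cutoff
#'   (Angstrom, default 3.5).
#' @param max_angle_deviation accepted deviation from linear D-H...A
#'   (degrees, default 30).
#' @param require_hydrogen strict mode needing explicit hydrogens (default
#'   TRUE).
#' @return object of class `gatescope_hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_angle_deviation = 30,
                           require_hydrogen = TRUE) {
  if (max_da_distance <= 0) stop("distance cutoff must be positive")
  if (max_angle_deviation <= 0 || max_angle_deviation > 90)
    stop("angle deviation cutoff must be in (0, 90]")
  structure(list(max_da_distance = max_da_distance,
                 max_angle_deviation = max_angle_deviation,
                 require_hydrogen = isTRUE(require_hydrogen)),
            class = "gatescope_hbond_criteria")
}

.standard_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Bundled per-residue donor/acceptor template
#'
#' Backbone amide N is a donor (except proline), carbonyl O and terminal OXT
#' are acceptors, for every standard residue; side-chain polar atoms follow
#' the usual chemistry (Ser/Thr/Tyr hydroxyls both roles, Asn/Gln amides,
#' Lys/Arg/Trp/His nitrogens, Asp/Glu carboxylates).
#'
#' @return data frame with columns `res_name`, `atom`, `role`
#'   (`donor`/`acceptor`), `backbone` (logical).
#' @export
donor_acceptor_template <- function() {
  rows <- list()
  add <- function(res, atom, role, backbone = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(res_name = res, atom = atom,
                                            role = role, backbone = backbone)
  for (res in .standard_residues) {
    if (res != "PRO") add(res, "N", "donor", TRUE)
    add(res, "O", "acceptor", TRUE)
    add(res, "OXT", "acceptor", TRUE)
  }
  add("SER", "OG", "donor"); add("SER", "OG", "acceptor")
  add("THR", "OG1", "donor"); add("THR", "OG1", "acceptor")
  add("TYR", "OH", "donor"); add("TYR", "OH", "acceptor")
  add("ASN", "ND2", "donor"); add("ASN", "OD1", "acceptor")
  add("GLN", "NE2", "donor"); add("GLN", "OE1", "acceptor")
  add("LYS", "NZ", "donor")
  add("ARG", "NE", "donor"); add("ARG", "NH1", "donor"); add("ARG", "NH2", "donor")
  add("HIS", "ND1", "donor"); add("HIS", "ND1", "acceptor")
  add("HIS", "NE2", "donor"); add("HIS", "NE2", "acceptor")
  add("ASP", "OD1", "acceptor"); add("ASP", "OD2", "acceptor")
  add("GLU", "OE1", "acceptor"); add("GLU", "OE2", "acceptor")
  add("TRP", "NE1", "donor")
  do.call(rbind, rows)
}

#' Load the bundled heptapeptide ligand donor/acceptor template
#'
#' Hetero-group template for the cyclized heptapeptide ligand (residue name
#' `DAR`): seven backbone amide nitrogens as donors and seven carbonyl
#' oxygens as acceptors, all flagged backbone.
#'
#' @return template data frame compatible with [assign_donors_acceptors()].
#' @export
darobactin_template <- function() {
  path <- system.file("extdata", "darobactin_template.csv", package = "gatescope")
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$backbone <- TRUE
  df
}

#' Annotate donor and acceptor atoms of a structure
#'
#' @param s structure.
#' @param extra_templates optional data frame(s) with columns `res_name`,
#'   `atom`, `role` and optionally `backbone`, for hetero groups.
#' @param model_index model to annotate.
#' @return the model's atom table with added logical columns `is_donor`,
#'   `is_acceptor`, `is_backbone_polar`. Atoms of residues not covered by any
#'   template are left unannotated with one warning naming the residues.
#' @export
assign_donors_acceptors <- function(s, extra_templates = NULL, model_index = 1L) {
  tmpl <- donor_acceptor_template()
  if (!is.null(extra_templates)) {
    if (is.data.frame(extra_templates)) extra_templates <- list(extra_templates)
    for (et in extra_templates) {
      et <- as.data.frame(et)
      if (is.null(et$backbone)) et$backbone <- FALSE
      tmpl <- rbind(tmpl, et[, c("res_name", "atom", "role", "backbone")])
    }
  }
  a <- s$atoms[s$atoms$model_index == model_index, , drop = FALSE]
  key <- paste(a$res_name, a$name)
  dk <- paste(tmpl$res_name[tmpl$role == "donor"], tmpl$atom[tmpl$role == "donor"])
  ak <- paste(tmpl$res_name[tmpl$role == "acceptor"], tmpl$atom[tmpl$role == "acceptor"])
  bk <- paste(tmpl$res_name[tmpl$backbone], tmpl$atom[tmpl$backbone])
  a$is_donor <- key %in% dk
  a$is_acceptor <- key %in% ak
  a$is_backbone_polar <- key %in% bk
  is_h <- substr(a$name, 1, 1) == "H" | toupper(a$element) == "H"
  unknown <- setdiff(unique(a$res_name[!is_h]), unique(tmpl$res_name))
  if (length(unknown) > 0)
    warning("no donor/acceptor template for residue(s): ",
            paste(unknown, collapse = ", "), "; their atoms are skipped")
  a
}

.sel_mask <- function(a, sel) {
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chains)) keep <- keep & a$chain_id %in% sel$chains
  if (!is.null(sel$atom_names)) keep <- keep & a$name %in% sel$atom_names
  if (!sel$include_hetero) keep <- keep & !a$is_hetero
  if (!is.null(sel$residue_ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in sel$residue_ranges)
      in_range <- in_range | (a$res_seq >= r[1] & a$res_seq <= r[2])
    keep <- keep & in_range
  }
  keep
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Directed candidate scan: donors in table `don` against acceptors in `acc`.
# `a` is the full annotated model table (for hydrogens and antecedents).
.scan_hbonds <- function(a, don, acc, criteria) {
  if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
  is_h <- substr(a$name, 1, 1) == "H" | toupper(a$element) == "H"
  res_of <- .residue_key(a)
  out <- list()
  dxyz <- as.matrix(don[, c("x", "y", "z")])
  axyz <- as.matrix(acc[, c("x", "y", "z")])
  for (i in seq_len(nrow(don))) {
    dv <- dxyz[i, ]
    dists <- sqrt(colSums((t(axyz) - dv)^2))
    cand <- which(dists <= criteria$max_da_distance & dists >= 1.8)
    for (j in cand) {
      if (.residue_key(don[i, ]) == .residue_key(acc[j, ])) next
      av <- axyz[j, ]
      dha <- NA_real_
      if (criteria$require_hydrogen) {
        hyd <- a[is_h & res_of == .residue_key(don[i, ]), , drop = FALSE]
        if (nrow(hyd) == 0) next
        hd <- sqrt((hyd$x - dv[1])^2 + (hyd$y - dv[2])^2 + (hyd$z - dv[3])^2)
        hyd <- hyd[hd <= 1.3, , drop = FALSE]
        if (nrow(hyd) == 0) next
        best <- NA_real_; best_h <- NA_character_
        for (k in seq_len(nrow(hyd))) {
          hv <- as.numeric(hyd[k, c("x", "y", "z")])
          ang <- .angle_deg(dv - hv, av - hv)
          if (is.na(best) || ang > best) { best <- ang; best_h <- hyd$name[k] }
        }
        if (180 - best > criteria$max_angle_deviation) next
        dha <- best
        hname <- best_h
      } else {
        # heavy-atom plausibility: angle donor-acceptor-antecedent >= 90
        same_res <- a[res_of == .residue_key(acc[j, ]) & !is_h, , drop = FALSE]
        dd <- sqrt((same_res$x - av[1])^2 + (same_res$y - av[2])^2 +
                     (same_res$z - av[3])^2)
        ante <- same_res[dd > 1e-6 & dd < 1.8, , drop = FALSE]
        if (nrow(ante) > 0) {
          aav <- as.numeric(ante[which.min(dd[dd > 1e-6 & dd < 1.8]), c("x", "y", "z")])
          if (.angle_deg(dv - av, aav - av) < 90) next
        }
        hname <- NA_character_
      }
      out[[length(out) + 1]] <- data.frame(
        donor = paste(don$chain_id[i], don$res_seq[i], don$name[i], sep = ":"),
        hydrogen = hname,
        acceptor = paste(acc$chain_id[j], acc$res_seq[j], acc$name[j], sep = ":"),
        donor_serial = don$serial[i], acceptor_serial = acc$serial[j],
        da_distance = dists[j], dha_angle = dha,
        backbone_backbone = don$is_backbone_polar[i] && acc$is_backbone_polar[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' Detect hydrogen bonds between two selections
#'
#' Scans donor(A) vs acceptor(B) and donor(B) vs acceptor(A), applies the
#' criteria (strict donor-H-acceptor geometry, or heavy-atom mode when
#' `require_hydrogen` is FALSE), excludes intra-residue and covalent
#' (< 1.8 Angstrom) contacts, deduplicates, and sorts by distance.
#'
#' @param s structure.
#' @param sel_a,sel_b [selection()] objects for the two atom groups.
#' @param criteria [hbond_criteria()].
#' @param model_index model (frame) to analyse.
#' @param extra_templates optional hetero-group templates (see
#'   [assign_donors_acceptors()]).
#' @return data frame of bonds (possibly 0 rows) with donor/acceptor labels,
#'   `da_distance`, `dha_angle` (NA in heavy-atom mode), and
#'   `backbone_backbone`.
#' @export
detect_hbonds <- function(s, sel_a, sel_b, criteria = hbond_criteria(),
                          model_index = 1L, extra_templates = NULL) {
  a <- suppressWarnings(
    assign_donors_acceptors(s, extra_templates, model_index))
  if (nrow(a) == 0) stop("no atoms in model ", model_index)
  .detect_hbonds_frame(a, sel_a, sel_b, criteria)
}

# Detection on one pre-annotated single-frame atom table.
.detect_hbonds_frame <- function(a, sel_a, sel_b, criteria) {
  if (criteria$require_hydrogen) {
    any_h <- any(substr(a$name, 1, 1) == "H" | toupper(a$element) == "H")
    if (!any_h)
      stop("structure has no hydrogens; use require_hydrogen = FALSE ",
           "(heavy-atom mode) for deposited models")
  }
  ma <- .sel_mask(a, sel_a); mb <- .sel_mask(a, sel_b)
  if (!any(ma) || !any(mb)) stop("empty selection in hydrogen-bond scan")
  res <- rbind(
    .scan_hbonds(a, a[ma & a$is_donor, , drop = FALSE],
                 a[mb & a$is_acceptor, , drop = FALSE], criteria),
    .scan_hbonds(a, a[mb & a$is_donor, , drop = FALSE],
                 a[ma & a$is_acceptor, , drop = FALSE], criteria))
  if (is.null(res))
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), donor_serial = integer(),
                      acceptor_serial = integer(), da_distance = numeric(),
                      dha_angle = numeric(), backbone_backbone = logical()))
  res <- res[!duplicated(paste(res$donor_serial, res$acceptor_serial)), ]
  res <- res[order(res$da_distance), ]
  rownames(res) <- NULL
  res
}

#' Per-frame seam hydrogen-bond series over a multi-model trajectory
#'
#' Counts bonds between the two strand selections in each frame and reports
#' the arithmetic mean, optionally over only the last fraction of frames
#' (mirroring equilibrated-tail analysis of production trajectories).
#'
#' @param traj multi-model structure.
#' @param strand1_sel,strand16_sel selections for the two seam strands.
#' @param criteria [hbond_criteria()].
#' @param frames NULL for all frames, a fraction in (0, 1) for the last part
#'   of the trajectory, or an integer vector of frame indices.
#' @return object of class `gatescope_seam_series`: list with
#'   `per_frame_counts`, `mean_count`, `frames_used`, `frame_index`.
#' @export
seam_series <- function(traj, strand1_sel, strand16_sel,
                        criteria = hbond_criteria(), frames = NULL) {
  nf <- traj$n_models
  if (nf < 1) stop("trajectory has no frames")
  idx <- if (is.null(frames)) {
    seq_len(nf)
  } else if (length(frames) == 1 && frames > 0 && frames < 1) {
    seq.int(max(1L, nf - ceiling(frames * nf) + 1L), nf)
  } else {
    fr <- as.integer(frames)
    if (any(fr < 1 | fr > nf)) stop("frame index out of range")
    fr
  }
  # split frames once; annotate the first frame and reuse flags where the
  # topology is identical across frames (the generator guarantees this).
  # Frames are restricted to the residues touched by either strand
  # selection (hydrogens and acceptor antecedents live in those residues).
  frames_tab <- split(traj$atoms, traj$atoms$model_index)
  a1 <- suppressWarnings(
    assign_donors_acceptors(traj, model_index = idx[1]))
  sel_rows <- .sel_mask(a1, strand1_sel) | .sel_mask(a1, strand16_sel)
  keep1 <- .residue_key(a1) %in% unique(.residue_key(a1[sel_rows, ]))
  a1 <- a1[keep1, , drop = FALSE]
  topo1 <- paste(a1$chain_id, a1$res_seq, a1$name)
  counts <- vapply(idx, function(m) {
    am_full <- frames_tab[[as.character(m)]]
    am <- if (nrow(am_full) == length(keep1))
      am_full[keep1, , drop = FALSE] else am_full
    if (nrow(am) == nrow(a1) &&
        all(paste(am$chain_id, am$res_seq, am$name) == topo1)) {
      am$is_donor <- a1$is_donor
      am$is_acceptor <- a1$is_acceptor
      am$is_backbone_polar <- a1$is_backbone_polar
    } else {
      am2 <- am_full; am2$model_index <- 1L
      am <- suppressWarnings(
        assign_donors_acceptors(new_structure(am2), model_index = 1L))
    }
    nrow(.detect_hbonds_frame(am, strand1_sel, strand16_sel, criteria))
  }, integer(1))
  structure(list(per_frame_counts = counts, mean_count = mean(counts),
                 frames_used = length(counts), frame_index = idx),
            class = "gatescope_seam_series")
}

#' @export
print.gatescope_seam_series <- function(x, ...) {
  cat(sprintf("<seam series> %d frames, mean %.3f bonds (range %d-%d)\n",
              x$frames_used, x$mean_count, min(x$per_frame_counts),
              max(x$per_frame_counts)))
  invisible(x)
}
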