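# ---------------------------------------------------------------------------
# Synthetic-data generators: idealized openable beta-barrels, bilayer
# headgroup clouds with imposed thinning, seam H-bond trajectories, and
# ligand pose sets.
# ---------------------------------------------------------------------------

#' Specification of an idealized beta-barrel
#'
#' The derived radius and strand tilt follow the standard sheared-barrel
#' closed forms `R = sqrt((S*a)^2 + (n*b)^2) / (2*pi)` and
#' `alpha = atan(S*a / (n*b))`. The generated lattice itself is untilted
#' (strands parallel to the barrel axis, exact inter-strand chord `b`) so
#' that the seam hydrogen-bond register is exact and analytically checkable;
#' see the methods vignette.
#'
#' @param n_strands number of strands (default 16).
#' @param shear shear number S (default 20).
#' @param residues_per_strand residues per strand (default 10).
#' @param rise_per_residue axial C-alpha spacing `a` in Angstrom (default 3.3).
#' @param interstrand_distance inter-strand spacing `b` in Angstrom
#'   (default 4.4).
#' @param seed integer seed recorded in the spec.
#' @return object of class `gatescope_barrel_spec` with derived fields
#'   `radius` (Angstrom) and `tilt` (radians).
#' @export
barrel_spec <- function(n_strands = 16L, shear = 20L,
                        residues_per_strand = 10L, rise_per_residue = 3.3,
                        interstrand_distance = 4.4, seed = 1L) {
  if (n_strands < 8) stop("need at least 8 strands")
  if (residues_per_strand < 4) stop("need at least 4 residues per strand")
  a <- rise_per_residue; b <- interstrand_distance; n <- n_strands; S <- shear
  structure(list(n_strands = as.integer(n), shear = as.integer(S),
                 residues_per_strand = as.integer(residues_per_strand),
                 rise_per_residue = a, interstrand_distance = b,
                 seed = as.integer(seed),
                 radius = sqrt((S * a)^2 + (n * b)^2) / (2 * pi),
                 tilt = atan2(S * a, n * b)),
            class = "gatescope_barrel_spec")
}

# Lattice levels that carry the inter-strand hydrogen-bond register:
# even levels away from the strand termini (4 levels for the 10-residue
# default, matching the fully zipped seam's bond count).
.bond_levels <- function(m) {
  lv <- seq(2L, m - 2L, by = 2L)
  lv[seq_len(min(length(lv), 4L))]
}

#' Generate an idealized beta-barrel structure
#'
#' Backbone atoms (N, H, CA, C, O) are placed on a cylindrical lattice:
#' strand `s` is a straight vertical line at angle `2*pi*(s-1)/n` on a
#' circle chosen so adjacent strand lines are exactly `b` apart, residues
#' numbered antiparallel (odd strands run up, even strands run down).
#' At the bond-carrying lattice levels the amide N (with H) points at the
#' next strand and the carbonyl O at the previous one, so every adjacent
#' strand pair -- including the beta1-beta16 seam -- forms the same
#' detectable hydrogen-bond register under default criteria.
#'
#' Residue numbering encodes the strand: strand `s` occupies residues
#' `(s-1)*m + 1 .. s*m`; the mapping is also carried in the structure
#' metadata.
#'
#' @param spec a [barrel_spec()].
#' @return structure with metadata fields `spec`, `strand_ranges`,
#'   `geometry_radius`.
#' @export
make_ideal_barrel <- function(spec = barrel_spec()) {
  n <- spec$n_strands; m <- spec$residues_per_strand
  a <- spec$rise_per_residue; b <- spec$interstrand_distance
  rg <- b / (2 * sin(pi / n))   # exact inter-strand chord b
  lv_bond <- .bond_levels(m)
  rows <- vector("list", n * m * 5)
  ri <- 0L
  for (s in seq_len(n)) {
    phi <- 2 * pi * (s - 1) / n
    rhat <- c(cos(phi), sin(phi), 0)
    ghat <- c(-sin(phi), cos(phi), 0)    # toward strand s+1
    up <- if (s %% 2 == 1) 1 else -1     # antiparallel numbering
    dhat <- c(0, 0, up)
    for (i in seq_len(m)) {
      level <- if (up == 1) i else m + 1L - i
      P <- rg * rhat + c(0, 0, (level - (m + 1) / 2) * a)
      bonded <- level %in% lv_bond
      u <- if (bonded) ghat else rhat
      res_seq <- (s - 1L) * m + i
      atoms <- list(
        c("N", 0.5), c("H", 1.5), c("CA", 0), c("C", NA), c("O", -1.0))
      for (at in atoms) {
        ri <- ri + 1L
        pos <- if (at[[1]] == "C") {
          P - 0.3 * u + 0.6 * dhat
        } else if (at[[1]] == "O" && !bonded) {
          P + 1.5 * u + 0.6 * dhat   # inert O kept away from the seam lattice
        } else {
          P + as.numeric(at[[2]]) * u
        }
        rows[[ri]] <- data.frame(
          serial = ri, name = at[[1]],
          element = substr(at[[1]], 1, 1),
          alt_loc = "", res_name = "GLY", chain_id = "A",
          res_seq = res_seq, i_code = "",
          x = pos[1], y = pos[2], z = pos[3],
          occupancy = 1, b_factor = 0, model_index = 1L,
          is_hetero = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  strand_ranges <- data.frame(
    strand = seq_len(n),
    first_res = (seq_len(n) - 1L) * m + 1L,
    last_res = seq_len(n) * m)
  new_structure(do.call(rbind, rows), source = "synthetic",
                metadata = list(spec = spec, strand_ranges = strand_ranges,
                                geometry_radius = rg, bond_levels = lv_bond))
}

#' Selection covering one strand of a synthetic barrel
#' @param s barrel structure from [make_ideal_barrel()].
#' @param strand strand number.
#' @param atom_names optional atom-name restriction.
#' @return a [selection()].
#' @export
strand_selection <- function(s, strand, atom_names = NULL) {
  sr <- s$metadata$strand_ranges
  if (is.null(sr)) stop("structure carries no strand tags")
  row <- sr[sr$strand == strand, ]
  if (nrow(row) == 0) stop("no such strand: ", strand)
  selection(residue_ranges = list(c(row$first_res, row$last_res)),
            atom_names = atom_names)
}

#' Gate-opening perturbation
#'
#' @param k_strands number of gate strands rotated (default 4).
#' @param angle rotation in degrees (default 45).
#' @return object of class `gatescope_gate_perturbation`.
#' @export
gate_perturbation <- function(k_strands = 4L, angle = 45) {
  if (angle < 0 || angle > 90) stop("angle must be in [0, 90] degrees")
  structure(list(k_strands = as.integer(k_strands), angle = angle),
            class = "gatescope_gate_perturbation")
}

# Rotate points about a vertical axis through (hx, hy) by ang (radians).
.rotate_about_axis <- function(xyz, hx, hy, ang) {
  dx <- xyz[, 1] - hx; dy <- xyz[, 2] - hy
  cbind(hx + cos(ang) * dx - sin(ang) * dy,
        hy + sin(ang) * dx + cos(ang) * dy,
        xyz[, 3])
}

#' Rigidly open the lateral gate of a synthetic barrel
#'
#' Rotates strands `1..k` about a hinge axis parallel to the barrel axis
#' through the C-alpha line of the first retained strand (`k+1`), in the
#' sense that moves strand 1 away from the seam partner (strand `n`).
#' `angle = 0` is the identity; all other atoms are untouched.
#'
#' @param s barrel from [make_ideal_barrel()].
#' @param p a [gate_perturbation()].
#' @return perturbed structure (strand tags preserved); the hinge is stored
#'   in metadata `hinge`.
#' @export
open_gate <- function(s, p = gate_perturbation()) {
  sr <- s$metadata$strand_ranges
  if (is.null(sr)) stop("structure carries no strand tags")
  n <- nrow(sr)
  if (p$k_strands < 1 || p$k_strands >= n)
    stop("k_strands must be in 1..", n - 1)
  hinge_rows <- s$atoms$res_seq >= sr$first_res[p$k_strands + 1] &
    s$atoms$res_seq <= sr$last_res[p$k_strands + 1] & s$atoms$name == "CA"
  hx <- mean(s$atoms$x[hinge_rows]); hy <- mean(s$atoms$y[hinge_rows])
  gate <- s$atoms$res_seq <= sr$last_res[p$k_strands]
  seam_partner <- s$atoms$res_seq >= sr$first_res[n] & s$atoms$name == "CA"
  s1 <- s$atoms$res_seq <= sr$last_res[1] & s$atoms$name == "CA"
  ang <- p$angle * pi / 180
  xyz <- as.matrix(s$atoms[gate, c("x", "y", "z")])
  sep <- function(ang_signed) {
    r <- .rotate_about_axis(as.matrix(s$atoms[s1, c("x", "y", "z")]), hx, hy,
                            ang_signed)
    min(sqrt(rowSums((r[1, 1:2] - t(as.matrix(
      s$atoms[seam_partner, c("x", "y")])))^2)))
  }
  sign <- if (ang > 0 && sep(-ang) > sep(ang)) -1 else 1
  rot <- .rotate_about_axis(xyz, hx, hy, sign * ang)
  s$atoms$x[gate] <- rot[, 1]; s$atoms$y[gate] <- rot[, 2]
  s$atoms$z[gate] <- rot[, 3]
  s$metadata$hinge <- c(hx, hy)
  s$metadata$gate_angle <- p$angle
  s
}

#' Gate-loop definitions for a synthetic barrel pair/set
#'
#' Marker residues on the two outermost gate strands: two mid-strand
#' residues each from strand 1 and strand 2, shared across all structure
#' keys (synthetic conformers keep their numbering).
#'
#' @param spec the [barrel_spec()] used to build the structures.
#' @param keys structure keys the loops should cover.
#' @return list of two [gate_loop()] definitions.
#' @export
synthetic_gate_loops <- function(spec, keys) {
  m <- spec$residues_per_strand
  mk <- function(resseq) {
    df <- data.frame(chain_id = "A", res_seq = resseq)
    setNames(rep(list(df), length(keys)), keys)
  }
  l1 <- c(3L, 5L, m + 3L, m + 5L)            # strands 1 and 2
  l2 <- c(4L, 6L, m + 4L, m + 6L)
  list(gate_loop("L1", mk(l1)), gate_loop("L2", mk(l2)))
}

# --- Bilayer ---------------------------------------------------------------

#' Specification of a synthetic bilayer headgroup cloud
#'
#' @param box `c(Lx, Ly)` lateral box in Angstrom (default 90 x 90, centered
#'   on the origin).
#' @param baseline_thickness leaflet-to-leaflet distance in Angstrom
#'   (default 30, the unperturbed membrane).
#' @param particles_per_leaflet headgroup particles per leaflet (default
#'   4000, emulating a time-accumulated headgroup cloud).
#' @param thinning optional list with `center` `c(x, y)`, `width` (Gaussian
#'   sigma, Angstrom) and `depth` (Angstrom) of a local thinned patch.
#' @param z_noise_sd vertical positional noise sd (Angstrom, default 1).
#' @param seed RNG seed.
#' @return object of class `gatescope_bilayer_spec`.
#' @export
bilayer_spec <- function(box = c(90, 90), baseline_thickness = 30,
                         particles_per_leaflet = 4000L, thinning = NULL,
                         z_noise_sd = 1, seed = 1L) {
  if (!is.null(thinning)) {
    stopifnot(all(c("center", "width", "depth") %in% names(thinning)))
    thinning$center <- as.numeric(unlist(thinning$center))
    thinning$width <- as.numeric(thinning$width)
    thinning$depth <- as.numeric(thinning$depth)
    if (thinning$depth < 0 || thinning$depth >= baseline_thickness)
      stop("thinning depth must be in [0, baseline)")
  }
  structure(list(box = box, baseline_thickness = baseline_thickness,
                 particles_per_leaflet = as.integer(particles_per_leaflet),
                 thinning = thinning, z_noise_sd = z_noise_sd,
                 seed = as.integer(seed)),
            class = "gatescope_bilayer_spec")
}

#' Imposed thickness field of a bilayer spec
#'
#' `t(x, y) = baseline - depth * exp(-((x-cx)^2 + (y-cy)^2) / (2 width^2))`.
#'
#' @param spec a [bilayer_spec()].
#' @param x,y coordinates (vectorized).
#' @return thickness in Angstrom.
#' @export
bilayer_truth <- function(spec, x, y) {
  t0 <- rep(spec$baseline_thickness, length(x))
  if (!is.null(spec$thinning)) {
    th <- spec$thinning
    t0 <- t0 - th$depth *
      exp(-((x - th$center[1])^2 + (y - th$center[2])^2) / (2 * th$width^2))
  }
  t0
}

#' Generate a bilayer headgroup point cloud
#'
#' Two leaflets of pseudo-headgroup particles at `z = +/- t(x, y)/2` plus
#' Gaussian vertical noise, with uniform lateral sampling over the box.
#' Upper-leaflet particles are chain `U`, lower chain `L`, atom name `P`.
#' Reproducible for a fixed spec (seeded).
#'
#' @param spec a [bilayer_spec()].
#' @return structure of headgroup particles.
#' @export
make_bilayer <- function(spec = bilayer_spec()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  np <- spec$particles_per_leaflet
  mk_leaflet <- function(side, chain, off) {
    x <- runif(np, -spec$box[1] / 2, spec$box[1] / 2)
    y <- runif(np, -spec$box[2] / 2, spec$box[2] / 2)
    z <- side * bilayer_truth(spec, x, y) / 2 + rnorm(np, 0, spec$z_noise_sd)
    data.frame(serial = seq_len(np) + off, name = "P", element = "P",
               alt_loc = "", res_name = "HGP", chain_id = chain,
               res_seq = seq_len(np), i_code = "", x = x, y = y, z = z,
               occupancy = 1, b_factor = 0, model_index = 1L,
               is_hetero = TRUE, stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk_leaflet(1, "U", 0L), mk_leaflet(-1, "L", np))
  new_structure(atoms, source = "synthetic", metadata = list(spec = spec))
}

# Save/restore global RNG state so generators are seeded without side
# effects on the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- Seam H-bond trajectory ------------------------------------------------

#' Specification of a seam hydrogen-bond Markov chain
#'
#' States are seam bond counts `0..4`; a frame in state `k` realizes exactly
#' `k` detectable seam bonds.
#'
#' @param transition 5x5 row-stochastic matrix (rows/cols = states 0..4).
#' @param n_frames number of frames.
#' @param initial initial state (0..4, default 4: fully zipped).
#' @param seed RNG seed.
#' @return object of class `gatescope_seam_chain_spec`.
#' @export
seam_chain_spec <- function(transition, n_frames = 500L, initial = 4L,
                            seed = 1L) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(5, 5)))
    stop("transition matrix must be 5 x 5 (states 0..4)")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix must be row-stochastic")
  structure(list(transition = transition, n_frames = as.integer(n_frames),
                 initial = as.integer(initial), seed = as.integer(seed)),
            class = "gatescope_seam_chain_spec")
}

#' Stationary distribution of a finite Markov chain
#' @param P row-stochastic transition matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

#' Generate a multi-model seam hydrogen-bond trajectory
#'
#' Samples the chain state per frame and emits a conformer of the template
#' barrel whose seam realizes exactly that many detectable bonds: broken
#' bonds are realized geometrically by displacing the seam donor amide
#' (N and H of strand `n` at that lattice level) radially outward beyond the
#' distance cutoff.
#'
#' @param spec a [seam_chain_spec()].
#' @param template barrel from [make_ideal_barrel()].
#' @return multi-model structure; the sampled state sequence is in metadata
#'   `states`.
#' @export
make_seam_trajectory <- function(spec, template = make_ideal_barrel()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  states <- integer(spec$n_frames)
  cur <- spec$initial
  for (f in seq_len(spec$n_frames)) {
    cur <- sample.int(5L, 1L, prob = spec$transition[cur + 1L, ]) - 1L
    states[f] <- cur
  }
  sr <- template$metadata$strand_ranges
  n <- nrow(sr)
  lv <- template$metadata$bond_levels
  m <- template$metadata$spec$residues_per_strand
  # donor residues on the seam strand (strand n, even: residue index m+1-level)
  donor_res <- sr$first_res[n] - 1L + (m + 1L - lv)
  a0 <- template$atoms[template$atoms$model_index == 1L, , drop = FALSE]
  move <- lapply(seq_along(lv), function(k)
    which(a0$res_seq == donor_res[k] & a0$name %in% c("N", "H")))
  rad <- local({
    i <- vapply(move, `[`, integer(1), 1L)
    v <- cbind(a0$x[i], a0$y[i])
    v / sqrt(rowSums(v^2))
  })
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    af <- a0
    nb <- states[f]
    if (nb < length(lv)) {
      for (k in seq.int(nb + 1L, length(lv))) {
        af$x[move[[k]]] <- af$x[move[[k]]] + 5 * rad[k, 1]
        af$y[move[[k]]] <- af$y[move[[k]]] + 5 * rad[k, 2]
      }
    }
    af$model_index <- f
    frames[[f]] <- af
  }
  out <- new_structure(do.call(rbind, frames), source = "synthetic",
                       metadata = c(template$metadata,
                                    list(chain_spec = spec, states = states)))
  out$n_models <- spec$n_frames
  out
}

# --- Ligand pose set -------------------------------------------------------

#' Generate the eight-orientation ligand pose set
#'
#' Places a 7-residue beta-strand peptide mimic (sequence W-N-W-S-K-S-F)
#' along the exposed edge of the receptor's strand 1, in
#' `n_inplane x conformers` poses: in-plane orientations rotate the ligand
#' about its own strand axis in 90-degree steps (orientation 4 faces its
#' amide donors at the receptor), and the two end-group conformers place the
#' terminal aromatic-ring mimic extended away from the receptor (`E`) or
#' condensed against it (`C`). By construction exactly one pose (`E4`) forms
#' the maximal backbone hydrogen-bond register, while the condensed ring of
#' `C4` packs at van der Waals contact, making it the most favorable in
#' interaction energy; the condensed ring occludes the terminal amide, so
#' `C4` carries one bond fewer than `E4`.
#'
#' @param receptor barrel (typically after [open_gate()]) with strand tags.
#' @param n_inplane in-plane orientations (default 4).
#' @param conformers end-group conformers (default 2: extended, condensed).
#' @param seed recorded seed (the construction is deterministic).
#' @return named list of ligand structures (chain `L`), names `E1..C4` for
#'   the defaults, with attributes `ground_truth` (maximal H-bond register)
#'   and `best_energy` (planted lowest-energy pose).
#' @export
make_pose_set <- function(receptor, n_inplane = 4L, conformers = 2L,
                          seed = 1L) {
  sr <- receptor$metadata$strand_ranges
  if (is.null(sr)) stop("receptor carries no strand tags (need strand 1)")
  spec <- receptor$metadata$spec
  m <- spec$residues_per_strand; a <- spec$rise_per_residue
  b <- spec$interstrand_distance
  lv <- receptor$metadata$bond_levels
  s1 <- receptor$atoms$res_seq <= sr$last_res[1] &
    receptor$atoms$model_index == 1L
  ca1 <- receptor$atoms[s1 & receptor$atoms$name == "CA", , drop = FALSE]
  o1 <- receptor$atoms[s1 & receptor$atoms$name == "O", , drop = FALSE]
  cx <- mean(ca1$x); cy <- mean(ca1$y)
  # direction the strand-1 carbonyls point (the exposed edge after opening)
  lev1 <- lv[1]
  ca_at <- ca1[order(ca1$z), ][lev1, ]
  o_at <- o1[which.min(abs(o1$z - ca_at$z)), ]
  g <- c(o_at$x - ca_at$x, o_at$y - ca_at$y)
  g <- g / sqrt(sum(g^2))          # unit vector from strand 1 toward ligand
  lig_gap <- b + 0.6               # ligand strand axis sits slightly wider
  lx <- cx + lig_gap * g[1]; ly <- cy + lig_gap * g[2]
  seqs <- c("TRP", "ASN", "TRP", "SER", "LYS", "SER", "PHE")
  lig_levels <- 2:8                 # spans the receptor's bond levels
  base_ang <- atan2(-g[2], -g[1])   # donor direction at orientation 4
  poses <- list()
  for (co in seq_len(conformers)) {
    ctag <- if (co == 1) "E" else "C"
    for (o in seq_len(n_inplane)) {
      ang <- base_ang + (o - n_inplane) * pi / 2
      u <- c(cos(ang), sin(ang), 0)      # amide direction of this pose
      rows <- list(); ri <- 0L
      for (j in seq_along(lig_levels)) {
        level <- lig_levels[j]
        P <- c(lx, ly, (level - (m + 1) / 2) * a)
        bonded <- level %in% lv
        terminal <- j == length(lig_levels)
        occluded <- terminal && ctag == "C"
        # inert and occluded amides always point away from the receptor
        away <- c(g[1], g[2], 0)
        uu <- if (bonded && !occluded) u else away
        add <- function(nm, pos) {
          ri <<- ri + 1L
          rows[[ri]] <<- data.frame(
            serial = ri, name = nm, element = substr(nm, 1, 1),
            alt_loc = "", res_name = seqs[j], chain_id = "L",
            res_seq = j, i_code = "", x = pos[1], y = pos[2], z = pos[3],
            occupancy = 1, b_factor = 0, model_index = 1L,
            is_hetero = FALSE, stringsAsFactors = FALSE)
        }
        # amide extensions widened by the extra axis gap so the facing
        # pose recovers the lattice N...O = 2.9 hydrogen-bond distance
        add("N", P + 1.1 * uu)
        add("H", P + 2.1 * uu)
        add("CA", P)
        add("C", P - 0.3 * uu + c(0, 0, 0.6))
        add("O", P - 1.0 * uu)
        if (terminal) {
          # aromatic-ring mimic on the last residue: condensed packs the
          # ring at van der Waals contact with the receptor strand,
          # extended points it away into solvent
          ring_dir <- if (ctag == "E") -u else u
          off <- if (ctag == "C") lig_gap - 3.64 else 1.2
          that <- c(-ring_dir[2], ring_dir[1], 0)
          zmid <- (c(m - 1.5, m - 0.5) - (m + 1) / 2) * a
          k <- 0L
          for (zr in zmid[c(1, 1, 2, 2)]) {
            k <- k + 1L
            side <- if (k %% 2 == 0) 0.5 else -0.5
            add(paste0("CR", k),
                c(lx, ly, zr) + off * c(ring_dir[1], ring_dir[2], 0) +
                  side * that)
          }
        }
      }
      poses[[paste0(ctag, o)]] <- new_structure(
        do.call(rbind, rows), source = "synthetic",
        metadata = list(pose = paste0(ctag, o), seed = seed))
    }
  }
  attr(poses, "ground_truth") <- "E4"
  attr(poses, "best_energy") <- "C4"
  poses
}
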