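# ---------------------------------------------------------------------------
# Pose scoring: Gaussian-atom simulated density, masked real-space map-model
# correlation, nonbonded interaction energy, and the combined ranking.
# ---------------------------------------------------------------------------

.atomic_number <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

.element_of <- function(atoms) {
  el <- toupper(atoms$element)
  blank <- el == "" | is.na(el)
  el[blank] <- substr(gsub("[0-9]", "", atoms$name[blank]), 1, 1)
  el
}

#' Construct a density map object
#'
#' @param values 3D numeric array (x fastest-varying).
#' @param voxel_size voxel edge in Angstrom.
#' @param origin Cartesian position of the first voxel center.
#' @return object of class `gatescope_density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, voxel_size > 0, all(is.finite(values)))
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "gatescope_density_map")
}

#' @export
print.gatescope_density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density map> %dx%dx%d voxels @ %.2f A, origin (%.1f, %.1f, %.1f)\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# Add Gaussian-atom density for structure s onto an existing grid definition.
.gaussian_density <- function(s, sigma, dims, voxel, origin, model_index = 1L) {
  a <- s$atoms[s$atoms$model_index == model_index, , drop = FALSE]
  el <- .element_of(a)
  keep <- el != "H"
  a <- a[keep, , drop = FALSE]; el <- el[keep]
  z <- .atomic_number[el]; z[is.na(z)] <- 6
  vals <- array(0, dims)
  xg <- origin[1] + (seq_len(dims[1]) - 1) * voxel
  yg <- origin[2] + (seq_len(dims[2]) - 1) * voxel
  zg <- origin[3] + (seq_len(dims[3]) - 1) * voxel
  reach <- 4 * sigma
  for (i in seq_len(nrow(a))) {
    ix <- which(abs(xg - a$x[i]) <= reach)
    iy <- which(abs(yg - a$y[i]) <= reach)
    iz <- which(abs(zg - a$z[i]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(xg[ix] - a$x[i])^2 / (2 * sigma^2))
    gy <- exp(-(yg[iy] - a$y[i])^2 / (2 * sigma^2))
    gz <- exp(-(zg[iz] - a$z[i])^2 / (2 * sigma^2))
    block <- z[i] * outer(gx, gy)
    for (k in seq_along(iz))
      vals[ix, iy, iz[k]] <- vals[ix, iy, iz[k]] + block * gz[k]
  }
  vals
}

#' Simulate a density map from an atomic model
#'
#' Each non-hydrogen atom contributes an isotropic 3D Gaussian of standard
#' deviation `sigma = 0.225 * resolution` with amplitude proportional to its
#' atomic number (a common low-pass kernel convention; coarser resolution
#' emulates low-pass filtering).
#'
#' @param s structure.
#' @param resolution nominal resolution in Angstrom.
#' @param voxel_size voxel edge (default 1 Angstrom).
#' @param padding margin around the model (default 5 Angstrom).
#' @return a [density_map()].
#' @export
simulate_map <- function(s, resolution, voxel_size = 1, padding = 5) {
  stopifnot(resolution > 0, voxel_size > 0)
  if (n_atoms(s) == 0) stop("cannot simulate a map from an empty structure")
  x <- coords(s)
  origin <- apply(x, 2, min) - padding
  upper <- apply(x, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((upper - origin) / voxel_size)) + 1L)
  sigma <- 0.225 * resolution
  vals <- .gaussian_density(s, sigma, dims, voxel_size, origin)
  density_map(vals, voxel_size, origin)
}

#' Real-space map-model correlation coefficient
#'
#' Pearson correlation between the map and a Gaussian-atom map simulated
#' from the model at the same grid, restricted to the mask formed by the
#' union of spheres of `mask_radius` around the model's non-hydrogen atoms.
#' Invariant under affine intensity transforms of the map.
#'
#' @param map a [density_map()].
#' @param s structure to score.
#' @param mask_radius mask sphere radius (Angstrom, default 3).
#' @param resolution resolution of the simulated comparison map (Angstrom).
#' @return correlation in `[-1, 1]`.
#' @export
map_model_cc <- function(map, s, mask_radius = 3, resolution = 5) {
  dims <- dim(map$values)
  sim <- .gaussian_density(s, 0.225 * resolution, dims, map$voxel_size,
                           map$origin)
  a <- s$atoms[s$atoms$model_index == 1L, , drop = FALSE]
  a <- a[.element_of(a) != "H", , drop = FALSE]
  mask <- array(FALSE, dims)
  xg <- map$origin[1] + (seq_len(dims[1]) - 1) * map$voxel_size
  yg <- map$origin[2] + (seq_len(dims[2]) - 1) * map$voxel_size
  zg <- map$origin[3] + (seq_len(dims[3]) - 1) * map$voxel_size
  for (i in seq_len(nrow(a))) {
    ix <- which(abs(xg - a$x[i]) <= mask_radius)
    iy <- which(abs(yg - a$y[i]) <= mask_radius)
    iz <- which(abs(zg - a$z[i]) <= mask_radius)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xg[ix] - a$x[i])^2; dy2 <- (yg[iy] - a$y[i])^2
    dz2 <- (zg[iz] - a$z[i])^2
    sph <- outer(outer(dx2, dy2, "+"), dz2, "+") <= mask_radius^2
    mask[ix, iy, iz] <- mask[ix, iy, iz] | sph
  }
  nmask <- sum(mask)
  if (nmask < 50) stop("mask covers only ", nmask, " voxels (need >= 50)")
  stats::cor(map$values[mask], sim[mask])
}

# --- MRC/CCP4 I/O (mode 2, little-endian) ----------------------------------

#' Write a density map in MRC/CCP4 format (mode 2)
#' @param map a [density_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                     # nx ny nz
  wi(2)                     # mode 2 = float32
  wi(c(0, 0, 0))            # nxstart nystart nzstart
  wi(d)                     # mx my mz
  wf(d * map$voxel_size)    # cella
  wf(c(90, 90, 90))         # cellb
  wi(c(1, 2, 3))            # mapc mapr maps
  v <- map$values
  wf(c(min(v), max(v), mean(v)))
  wi(1)                     # ispg
  wi(0)                     # nsymbt
  wi(rep(0, 25))            # extra
  wf(map$origin)            # origin x y z
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(sd(v))                 # rms
  wi(0)                     # nlabl
  writeBin(raw(800), con)   # labels
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a density map from MRC/CCP4 format
#' @param path MRC file (mode 2).
#' @return a [density_map()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only MRC mode 2 (float32) supported, got mode ", mode)
  ri(3)                     # nxstart..
  mx <- ri(3)
  cella <- rf(3)
  rf(3); ri(3)              # cellb, axis order
  rf(3); ri(1); ri(1)       # dmin/dmax/dmean, ispg, nsymbt
  ri(25)
  origin <- rf(3)
  seek(con, 1024)
  v <- rf(prod(d))
  density_map(array(v, d), voxel_size = cella[1] / mx[1], origin = origin)
}

# --- Nonbonded interaction energy ------------------------------------------

#' Nonbonded energy parameters
#'
#' Element-typed Lennard-Jones well depths and radii with simple
#' backbone-style partial charges by atom name; an approximate bundled table
#' for relative pose ranking, not a force field. Epsilon is stored as a
#' magnitude (kcal/mol).
#'
#' @param cutoff pair cutoff in Angstrom (default 12, plain truncation).
#' @param dielectric relative dielectric (default 80, solvent-mimicking).
#' @return object of class `gatescope_energy_params` with a `table` of
#'   per-element `epsilon` (kcal/mol) and `rmin_half` (Angstrom) and a
#'   `charges` map by atom name.
#' @export
energy_params <- function(cutoff = 12, dielectric = 80) {
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(
    table = data.frame(
      element = c("C", "N", "O", "S", "P", "H"),
      epsilon = c(0.07, 0.20, 0.12, 0.45, 0.585, 0.03),
      rmin_half = c(2.0, 1.45, 1.45, 2.0, 2.15, 0.45)),
    charges = c(N = -0.47, H = 0.31, O = -0.51, C = 0.51, CA = 0.07),
    cutoff = cutoff, dielectric = dielectric),
    class = "gatescope_energy_params")
}

.atom_params <- function(atoms, params) {
  el <- .element_of(atoms)
  idx <- match(el, params$table$element)
  if (anyNA(idx)) {
    warning("no energy parameters for element(s) ",
            paste(unique(el[is.na(idx)]), collapse = ", "),
            "; using carbon-like defaults")
    idx[is.na(idx)] <- match("C", params$table$element)
  }
  q <- params$charges[atoms$name]
  q[is.na(q)] <- 0
  list(epsilon = params$table$epsilon[idx],
       rmin_half = params$table$rmin_half[idx],
       charge = unname(q))
}

#' Receptor-ligand nonbonded interaction energy
#'
#' Sum over receptor-ligand atom pairs within the cutoff of a 12-6
#' Lennard-Jones term (Lorentz-Berthelot combination) plus a Coulomb term
#' `332.06 q_i q_j / (dielectric * r)` (kcal/mol). Plain truncation at the
#' cutoff; symmetric under exchange of the two structures; deterministic.
#'
#' @param receptor,ligand structures.
#' @param params an [energy_params()].
#' @param model_index model of each structure to use.
#' @return energy in kcal/mol (negative = favorable).
#' @export
interaction_energy <- function(receptor, ligand, params = energy_params(),
                               model_index = 1L) {
  ra <- receptor$atoms[receptor$atoms$model_index == model_index, , drop = FALSE]
  la <- ligand$atoms[ligand$atoms$model_index == model_index, , drop = FALSE]
  if (nrow(ra) == 0 || nrow(la) == 0) stop("empty structure in energy evaluation")
  pr <- .atom_params(ra, params); pl <- .atom_params(la, params)
  xr <- as.matrix(ra[, c("x", "y", "z")]); xl <- as.matrix(la[, c("x", "y", "z")])
  e <- 0
  for (i in seq_len(nrow(xr))) {
    dv <- sweep(xl, 2, xr[i, ])
    r <- sqrt(rowSums(dv^2))
    sel <- which(r <= params$cutoff & r > 0)
    if (!length(sel)) next
    eps <- sqrt(pr$epsilon[i] * pl$epsilon[sel])
    rmin <- pr$rmin_half[i] + pl$rmin_half[sel]
    sr6 <- (rmin / r[sel])^6
    lj <- eps * (sr6^2 - 2 * sr6)
    coul <- 332.06 * pr$charge[i] * pl$charge[sel] / (params$dielectric * r[sel])
    e <- e + sum(lj + coul)
  }
  e
}

#' Merge two structures into one
#'
#' Atom order: all of `a`, then all of `b`; serials renumbered. Model 1 only.
#'
#' @param a,b structures.
#' @return combined structure.
#' @export
merge_structures <- function(a, b) {
  ta <- a$atoms[a$atoms$model_index == 1L, , drop = FALSE]
  tb <- b$atoms[b$atoms$model_index == 1L, , drop = FALSE]
  out <- rbind(ta, tb)
  out$serial <- seq_len(nrow(out))
  new_structure(out, source = "merged",
                metadata = c(a$metadata, b$metadata))
}

#' Score and rank a set of ligand poses
#'
#' Computes, per pose: the masked map-model correlation (when a map is
#' given), the receptor-ligand nonbonded interaction energy, and the mean
#' interface hydrogen-bond count over the pose's models. Primary ranking is
#' by CC (descending) when a map is present, else by energy (ascending, more
#' negative = better); ties break by energy, then mean H-bonds (descending),
#' then pose id. The full score table is returned so both decision metrics
#' (best energy vs most hydrogen bonds) can be inspected.
#'
#' @param receptor structure shared by all poses.
#' @param poses named list of ligand structures (names are pose ids, e.g.
#'   `E1..E4`, `C1..C4`).
#' @param map optional [density_map()] for CC scoring.
#' @param params [energy_params()].
#' @param criteria [hbond_criteria()] for interface bonds.
#' @param mask_radius,resolution CC parameters (see [map_model_cc()]).
#' @param extra_templates hetero-group donor/acceptor templates.
#' @return data frame of class `gatescope_pose_scores` with columns
#'   `pose_id`, `map_cc`, `energy`, `mean_hbonds`, `rank` (a permutation of
#'   `1..n`).
#' @export
rank_poses <- function(receptor, poses, map = NULL, params = energy_params(),
                       criteria = hbond_criteria(), mask_radius = 3,
                       resolution = 5, extra_templates = NULL) {
  if (length(poses) == 0) stop("no poses to rank")
  ids <- names(poses)
  if (is.null(ids)) ids <- sprintf("pose%d", seq_along(poses))
  rows <- lapply(seq_along(poses), function(k) {
    lig <- poses[[k]]
    cc <- if (!is.null(map)) {
      map_model_cc(map, merge_structures(receptor, lig),
                   mask_radius = mask_radius, resolution = resolution)
    } else NA_real_
    en <- interaction_energy(receptor, lig, params)
    rec_chains <- unique(receptor$atoms$chain_id)
    lig_chains <- unique(lig$atoms$chain_id)
    nb <- vapply(seq_len(lig$n_models), function(m) {
      comb <- merge_structures(receptor, lig)  # model 1 of each
      if (m > 1) {
        lm <- lig$atoms[lig$atoms$model_index == m, , drop = FALSE]
        lm$model_index <- 1L
        comb <- merge_structures(receptor, new_structure(lm))
      }
      nrow(detect_hbonds(comb, selection(chains = rec_chains),
                         selection(chains = lig_chains), criteria,
                         extra_templates = extra_templates))
    }, numeric(1))
    data.frame(pose_id = ids[k], map_cc = cc, energy = en,
               mean_hbonds = mean(nb), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- if (!is.null(map)) {
    order(-tab$map_cc, tab$energy, -tab$mean_hbonds, tab$pose_id)
  } else {
    order(tab$energy, -tab$mean_hbonds, tab$pose_id)
  }
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  class(tab) <- c("gatescope_pose_scores", "data.frame")
  tab
}
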