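#' Build the wild-type C-alpha structure-based (Go) model
#'
#' Encodes the native structure into a potential whose minimum is the native
#' geometry: harmonic bonds between consecutive beads, harmonic angles,
#' periodic dihedrals, a 10-12 Lennard-Jones-type well of depth epsilon at
#' each native contact distance, and a truncated r^-12 repulsion between all
#' other pairs. All reference values (r0, theta0, phi0, sigma) are taken
#' from the input structure, so every bonded term vanishes at the native
#' coordinates and the native potential energy is exactly -sum(epsilon).
#'
#' Reduced units throughout: epsilon_0 = 1 sets the energy scale, k_B = 1
#' (temperature in epsilon_0), lengths in Angstrom, uniform unit masses.
#'
#' @param structure a [calpha_structure].
#' @param cmap a [contact_map] consistent with the structure length.
#' @param k_bond harmonic bond constant, epsilon_0/A^2 (V = k (r - r0)^2).
#' @param k_angle harmonic angle constant, epsilon_0/rad^2.
#' @param k_dihedral dihedral constant, epsilon_0
#'   (V = k\[(1 - cos(dphi)) + 1/2 (1 - cos 3 dphi)\]).
#' @param sigma_nn non-native excluded-volume diameter in Angstrom; the
#'   repulsion eps_nn\[(sigma_nn/r)^12 - 1\] applies for r < sigma_nn to pairs
#'   with sequence separation >= 3 that are neither native contacts nor
#'   bonded.
#' @param eps_nn non-native repulsion strength, epsilon_0.
#' @param extra_exclusions optional two-column matrix/data.frame of residue
#'   pairs additionally excluded from the non-native repulsion (e.g. pairs
#'   that are sequence-local in an alternative threading of the same
#'   assembly, so that differently threaded constructs share an identical
#'   non-bonded potential).
#' @return an object of class `sbm_topology`.
#' @export
build_wt_model <- function(structure, cmap, k_bond = 100, k_angle = 20,
                           k_dihedral = 1, sigma_nn = 4.0, eps_nn = 1.0,
                           extra_exclusions = NULL) {
  stopifnot(inherits(structure, "calpha_structure"), inherits(cmap, "contact_map"))
  n <- nrow(structure$xyz)
  if (attr(cmap, "n_residues") != n)
    stop("contact map references a chain length different from the structure")
  if (nrow(cmap) > 0 && max(cmap$j) > n)
    stop("contact references residue beyond chain length")
  xyz <- structure$xyz

  bi <- seq_len(n - 1); bj <- bi + 1
  bonds <- data.frame(i = bi, j = bj,
                      r0 = sqrt(rowSums((xyz[bj, , drop = FALSE] - xyz[bi, , drop = FALSE])^2)),
                      k = k_bond)
  angles <- if (n >= 3) {
    ai <- seq_len(n - 2)
    data.frame(i = ai, j = ai + 1, k = ai + 2,
               theta0 = vapply(ai, function(a) bead_angle(xyz, a, a + 1, a + 2), 0),
               k_angle = k_angle)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    theta0 = numeric(0), k_angle = numeric(0))
  dihedrals <- if (n >= 4) {
    di <- seq_len(n - 3)
    data.frame(i = di, j = di + 1, k = di + 2, l = di + 3,
               phi0 = vapply(di, function(a) bead_dihedral(xyz, a, a + 1, a + 2, a + 3), 0),
               k_dihedral = k_dihedral)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0), l = integer(0),
                    phi0 = numeric(0), k_dihedral = numeric(0))

  structure(list(n_beads = n, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, contacts = cmap,
                 excluded_volume = list(sigma_nn = sigma_nn, epsilon_nn = eps_nn,
                                        min_sep = 3L,
                                        extra_exclusions = extra_exclusions),
                 masses = rep(1, n), native_coords = xyz,
                 provenance = sprintf("built from %s (%d beads, %d contacts)",
                                      structure$source, n, nrow(cmap))),
            class = "sbm_topology")
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat(sprintf("sbm_topology: %d beads, %d bonds, %d angles, %d dihedrals, %d contacts\n",
              x$n_beads, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$contacts)))
  for (p in x$provenance) cat(" ", p, "\n")
  invisible(x)
}

bead_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

bead_dihedral <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]; b3 <- xyz[l, ] - xyz[k, ]
  n1 <- c(b1[2]*b2[3] - b1[3]*b2[2], b1[3]*b2[1] - b1[1]*b2[3], b1[1]*b2[2] - b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3] - b2[3]*b3[2], b2[3]*b3[1] - b2[1]*b3[3], b2[1]*b3[2] - b2[2]*b3[1])
  m1 <- c(n1[2]*n2[3] - n1[3]*n2[2], n1[3]*n2[1] - n1[1]*n2[3], n1[1]*n2[2] - n1[2]*n2[1])
  atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

# Convert to the flat 0-based representation consumed by the compiled core.
as_engine_topology <- function(topo) {
  stopifnot(inherits(topo, "sbm_topology"))
  rest <- topo$restraint
  list(n_beads = topo$n_beads,
       bonds_idx = cbind(as.integer(topo$bonds$i) - 1L, as.integer(topo$bonds$j) - 1L),
       bonds_par = cbind(topo$bonds$r0, topo$bonds$k),
       angles_idx = cbind(as.integer(topo$angles$i) - 1L, as.integer(topo$angles$j) - 1L,
                          as.integer(topo$angles$k) - 1L),
       angles_par = cbind(topo$angles$theta0, topo$angles$k_angle),
       dihedrals_idx = cbind(as.integer(topo$dihedrals$i) - 1L, as.integer(topo$dihedrals$j) - 1L,
                             as.integer(topo$dihedrals$k) - 1L, as.integer(topo$dihedrals$l) - 1L),
       dihedrals_par = cbind(topo$dihedrals$phi0, topo$dihedrals$k_dihedral),
       contacts_idx = cbind(as.integer(topo$contacts$i) - 1L, as.integer(topo$contacts$j) - 1L),
       contacts_par = cbind(topo$contacts$sigma, topo$contacts$epsilon),
       sigma_nn = topo$excluded_volume$sigma_nn,
       eps_nn = topo$excluded_volume$epsilon_nn,
       nn_min_sep = topo$excluded_volume$min_sep,
       exclusions_idx = {
         ex <- topo$excluded_volume$extra_exclusions
         if (is.null(ex) || length(ex) == 0) {
           matrix(integer(0), 0, 2)
         } else {
           ex <- as.matrix(as.data.frame(ex))
           if (nrow(ex) == 0) matrix(integer(0), 0, 2)
           else cbind(as.integer(ex[, 1]) - 1L, as.integer(ex[, 2]) - 1L)
         }
       },
       restraint_k = if (is.null(rest)) 0 else rest$k,
       restraint_R = if (is.null(rest)) 0 else rest$R,
       restraint_center = if (is.null(rest)) c(0, 0, 0) else rest$center)
}

#' Delete an inter-domain interface while preserving per-residue stability
#'
#' Removes every contact carrying `interface_label` and rescales the
#' remaining contacts of each affected residue so that its total contact
#' strength (sum of epsilon over its contacts) is unchanged. The rescaling
#' solves for per-contact multipliers by iterative proportional fitting:
#' each remaining contact (i, j) is repeatedly scaled by
#' sqrt(f_i * f_j), where f_i is the ratio of residue i's wild-type epsilon
#' sum to its current sum (f = 1 for unaffected residues), until all
#' affected-residue sums match within `tol`. A residue whose only contacts
#' were interface contacts cannot be compensated; a warning is recorded in
#' the topology provenance (and raised).
#'
#' @param topo an `sbm_topology` whose contacts are labelled
#'   (see [classify_contacts()]).
#' @param interface_label label of the contacts to delete, e.g.
#'   `"interface:CORE-NMP"`.
#' @param tol convergence tolerance on per-residue epsilon sums.
#' @param max_iter iteration cap for the proportional fitting.
#' @return the modified `sbm_topology`.
#' @export
delete_interface <- function(topo, interface_label, tol = 1e-9, max_iter = 500L) {
  cm <- topo$contacts
  drop <- which(!is.na(cm$label) & cm$label == interface_label)
  if (length(drop) == 0)
    stop(sprintf("no contacts carry label '%s'", interface_label))
  affected <- sort(unique(c(cm$i[drop], cm$j[drop])))
  wt_sum <- residue_eps_sums(cm, topo$n_beads)
  kept <- cm[-drop, , drop = FALSE]

  orphans <- affected[residue_eps_sums(kept, topo$n_beads)[affected] == 0]
  solvable <- setdiff(affected, orphans)

  eps <- kept$epsilon
  touches <- kept$i %in% solvable | kept$j %in% solvable
  residual <- 0
  for (iter in seq_len(max_iter)) {
    cur <- residue_eps_sums_vec(kept$i, kept$j, eps, topo$n_beads)
    residual <- if (length(solvable) == 0) 0 else
      max(abs(cur[solvable] - wt_sum[solvable]))
    if (residual < tol) break
    f <- rep(1, topo$n_beads)
    f[solvable] <- wt_sum[solvable] / cur[solvable]
    eps[touches] <- eps[touches] * sqrt(f[kept$i[touches]] * f[kept$j[touches]])
  }
  kept$epsilon <- eps
  topo$contacts <- contact_map(kept, attr(cm, "n_residues"))
  note <- sprintf("deleted %d contacts labelled %s; rescaled %d residues",
                  length(drop), interface_label, length(solvable))
  topo$provenance <- c(topo$provenance, note)
  if (length(orphans) > 0) {
    msg <- sprintf("residue(s) %s lost all contacts; their stabilization cannot be preserved",
                   paste(orphans, collapse = ", "))
    topo$provenance <- c(topo$provenance, paste("warning:", msg))
    warning(msg)
  }
  if (residual >= 1e-6) {
    msg <- sprintf("per-residue strength conservation not reached (max residual %.3g); the remaining contact graph cannot balance every affected residue",
                   residual)
    topo$provenance <- c(topo$provenance, paste("warning:", msg))
    warning(msg)
  }
  topo
}

residue_eps_sums <- function(cm, n) residue_eps_sums_vec(cm$i, cm$j, cm$epsilon, n)

residue_eps_sums_vec <- function(i, j, eps, n) {
  out <- numeric(n)
  s1 <- tapply(eps, i, sum); s2 <- tapply(eps, j, sum)
  out[as.integer(names(s1))] <- out[as.integer(names(s1))] + s1
  out[as.integer(names(s2))] <- out[as.integer(names(s2))] + s2
  out
}

#' Circular permutation of a chain
#'
#' Joins the original termini through a poly-glycine-like bead linker and
#' cuts the chain after `cut_after`, so the new chain order is: old residues
#' cut_after+1..N, then `linker_length` linker beads bridging the old
#' C-terminus to the old N-terminus, then old residues 1..cut_after. Every
#' native contact is renumbered (identical sigma and epsilon); linker beads
#' carry bonded terms only.
#'
#' Linker geometry: beads are equally spaced along the straight segment
#' joining the two old termini when the implied spacing is between 3.0 and
#' 4.5 Angstrom; when the termini are closer than that, beads are placed on
#' a circular arc with chord equal to the termini gap and arc length
#' (linker_length + 1) x 3.8 Angstrom; a gap too wide to bridge is an error.
#' Bonded reference values at the junctions are taken from the built
#' geometry, so the permutant's native energy is still -sum(epsilon).
#'
#' @param structure a [calpha_structure].
#' @param cmap a [contact_map] of the same chain.
#' @param cut_after residue index after which the new termini are created
#'   (`cut_after = N` with `linker_length = 0` is the identity).
#' @param linker_length number of linker beads (>= 0).
#' @return list with elements `structure`, `cmap`, `index_map` (old -> new
#'   position for the N original residues), `linker_residues` (new indices).
#' @export
circular_permute <- function(structure, cmap, cut_after, linker_length = 4L) {
  n <- nrow(structure$xyz)
  stopifnot(cut_after >= 1, cut_after <= n, linker_length >= 0)
  if (cut_after %in% structure$linker_residues ||
      (cut_after < n && (cut_after + 1) %in% structure$linker_residues))
    stop("cannot cut inside an engineered linker")
  if (cut_after == n && linker_length == 0) {
    return(list(structure = structure, cmap = cmap, index_map = seq_len(n),
                linker_residues = integer(0)))
  }
  xyz <- structure$xyz
  # linker from old C-terminus (residue n) to old N-terminus (residue 1)
  linker_xyz <- place_linker(xyz[n, ], xyz[1, ], linker_length)
  new_xyz <- rbind(xyz[seq(cut_after + 1, length.out = n - cut_after), , drop = FALSE],
                   linker_xyz,
                   xyz[seq_len(cut_after), , drop = FALSE])
  index_map <- integer(n)
  index_map[(cut_after + 1):n] <- seq_len(n - cut_after)
  if (cut_after >= 1)
    index_map[seq_len(cut_after)] <- (n - cut_after) + linker_length + seq_len(cut_after)
  linker_res <- if (linker_length > 0) (n - cut_after) + seq_len(linker_length) else integer(0)

  new_struct <- calpha_structure(new_xyz, chain_id = structure$chain_id,
                                 source = sprintf("%s|CP cut_after=%d linker=%d",
                                                  structure$source, cut_after, linker_length),
                                 linker_residues = linker_res)
  ni <- index_map[cmap$i]; nj <- index_map[cmap$j]
  new_cm <- contact_map(data.frame(i = pmin(ni, nj), j = pmax(ni, nj),
                                   sigma = cmap$sigma, epsilon = cmap$epsilon,
                                   label = cmap$label),
                        n + linker_length)
  list(structure = new_struct, cmap = new_cm, index_map = index_map,
       linker_residues = linker_res)
}

place_linker <- function(from, to, n_beads, bond = 3.8) {
  if (n_beads == 0) return(matrix(numeric(0), ncol = 3))
  gap <- sqrt(sum((to - from)^2))
  spacing <- gap / (n_beads + 1)
  if (spacing > 4.5)
    stop(sprintf("termini gap %.1f A too wide to bridge with %d linker beads", gap, n_beads))
  frac <- seq_len(n_beads) / (n_beads + 1)
  if (spacing >= 3.0) {
    return(t(vapply(frac, function(f) from + f * (to - from), numeric(3))))
  }
  # termini closer than the linker's natural length: bow the beads out on a
  # circular arc (chord = gap, arc length = (n_beads + 1) * bond)
  arc_len <- (n_beads + 1) * bond
  # solve chord = 2 R sin(arc/(2R)) for R
  fn <- function(R) 2 * R * sin(arc_len / (2 * R)) - gap
  lo <- arc_len / (2 * pi) + 1e-9; hi <- arc_len * 100
  R <- stats::uniroot(fn, c(lo, hi))$root
  half <- arc_len / (2 * R)
  u <- (to - from) / gap
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- ref - sum(ref * u) * u; w <- w / sqrt(sum(w^2))   # bowing direction
  mid <- (from + to) / 2
  centre <- mid - w * R * cos(half)
  ang0 <- -half
  t(vapply(frac, function(f) {
    a <- ang0 + f * 2 * half
    centre + R * (cos(a) * w) + R * sin(a) * u
  }, numeric(3)))
}

#' Dual-basin (open/closed) model construction
#'
#' Augments an open-state topology with the contacts specific to a second,
#' closed conformation: pairs present in the closed-structure contact map
#' and absent from the open map are added with sigma taken from the closed
#' structure, strength `epsilon_closed`, and label `"closed-specific"`.
#' Open-state contacts are untouched, so the dual potential decomposes as
#' E_dual(x) = E_open(x) + E_closed_contacts(x) for all x.
#'
#' @param open_topo `sbm_topology` of the open state.
#' @param closed_structure [calpha_structure] of the closed state; must have
#'   the same residue count and numbering as the open structure.
#' @param epsilon_closed strength of each closed-specific contact.
#' @param closed_cmap optional pre-computed [contact_map] of the closed
#'   state; by default computed with [compute_contact_map()] defaults.
#' @param ... passed to [compute_contact_map()] (cutoff, min_sep).
#' @return the augmented `sbm_topology`.
#' @export
build_dual_model <- function(open_topo, closed_structure, epsilon_closed = 1,
                             closed_cmap = NULL, ...) {
  if (nrow(closed_structure$xyz) != open_topo$n_beads)
    stop("open and closed structures must have identical residue counts")
  if (is.null(closed_cmap)) closed_cmap <- compute_contact_map(closed_structure, ...)
  open_keys <- paste(open_topo$contacts$i, open_topo$contacts$j)
  new <- closed_cmap[!(paste(closed_cmap$i, closed_cmap$j) %in% open_keys), , drop = FALSE]
  if (nrow(new) > 0) {
    new$epsilon <- epsilon_closed
    new$label <- "closed-specific"
  }
  merged <- rbind(as.data.frame(open_topo$contacts), as.data.frame(new))
  topo <- open_topo
  topo$contacts <- contact_map(merged, open_topo$n_beads)
  topo$provenance <- c(topo$provenance,
                       sprintf("dualized: %d closed-specific contacts added (eps = %g)",
                               nrow(new), epsilon_closed))
  topo
}

#' Tune the closed-state contact strength of a dual-basin model
#'
#' Scans a grid of strength scales (multiples of the mean open-state contact
#' epsilon) and returns the smallest scale for which a short Langevin
#' simulation visits both conformational basins, each with at least
#' `min_occupancy` of the frames. Basins are defined on the closed-specific
#' reaction coordinate Q_closed (fraction of closed-specific contacts
#' formed): open when Q_closed < 0.3, closed when Q_closed > 0.7.
#'
#' @param dual_topo an `sbm_topology` from [build_dual_model()].
#' @param T simulation temperature (below the folding temperature).
#' @param seed integer simulation seed.
#' @param grid multiples of the mean open-contact epsilon to scan.
#' @param n_steps,dt,save_every simulation settings for each probe run.
#' @param min_occupancy minimum fraction of frames per basin.
#' @return the selected scale (absolute epsilon value), with the scan record
#'   in attribute `"scan"`.
#' @export
tune_closed_strength <- function(dual_topo, T, seed = 1L,
                                 grid = seq(0.4, 2.0, by = 0.2),
                                 n_steps = 200000L, dt = 0.005,
                                 save_every = 200L, min_occupancy = 0.1) {
  closed <- !is.na(dual_topo$contacts$label) &
    dual_topo$contacts$label == "closed-specific"
  if (!any(closed)) stop("topology has no closed-specific contacts")
  mean_open_eps <- mean(dual_topo$contacts$epsilon[!closed])
  scan <- data.frame(scale = grid, occ_open = NA_real_, occ_closed = NA_real_)
  for (g in seq_along(grid)) {
    topo_g <- dual_topo
    topo_g$contacts$epsilon[closed] <- grid[g] * mean_open_eps
    traj <- run_langevin(topo_g, T = T, n_steps = n_steps, dt = dt,
                         friction = 1, seed = seed + g, save_every = save_every)
    qc <- compute_q(traj, topo_g$contacts[closed, , drop = FALSE])$values
    scan$occ_open[g] <- mean(qc < 0.3)
    scan$occ_closed[g] <- mean(qc > 0.7)
    if (scan$occ_open[g] >= min_occupancy && scan$occ_closed[g] >= min_occupancy) {
      out <- grid[g] * mean_open_eps
      attr(out, "scan") <- scan[seq_len(g), ]
      attr(out, "scale_multiple") <- grid[g]
      return(out)
    }
  }
  stop(paste0("no scale in the grid populates both basins; occupancies:\n",
              paste(utils::capture.output(print(scan)), collapse = "\n")))
}

#' Serialize / restore an SBM topology as JSON
#'
#' Writes all potential terms (beads, bonds, angles, dihedrals, contacts,
#' excluded volume, provenance) to a documented JSON file.
#'
#' @param topo an `sbm_topology`.
#' @param path file path.
#' @export
write_topology <- function(topo, path) {
  obj <- list(n_beads = topo$n_beads, bonds = topo$bonds, angles = topo$angles,
              dihedrals = topo$dihedrals,
              contacts = as.data.frame(topo$contacts),
              n_residues = attr(topo$contacts, "n_residues"),
              excluded_volume = topo$excluded_volume, masses = topo$masses,
              native_coords = topo$native_coords, provenance = topo$provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- obj$excluded_volume
  if (!is.null(ev$extra_exclusions) && length(ev$extra_exclusions) > 0) {
    ev$extra_exclusions <- matrix(unlist(ev$extra_exclusions), ncol = 2)
  } else {
    ev$extra_exclusions <- NULL
  }
  structure(list(n_beads = obj$n_beads, bonds = as.data.frame(obj$bonds),
                 angles = as.data.frame(obj$angles),
                 dihedrals = as.data.frame(obj$dihedrals),
                 contacts = contact_map(as.data.frame(obj$contacts), obj$n_residues),
                 excluded_volume = ev, masses = obj$masses,
                 native_coords = matrix(unlist(obj$native_coords), ncol = 3),
                 provenance = obj$provenance),
            class = "sbm_topology")
}
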