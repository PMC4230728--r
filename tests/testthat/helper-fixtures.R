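# Shared fixtures: tiny PDB texts, hand-built chains and minimal topologies.

pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          atom = "CA", altloc = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, atom, altloc, resname, chain, resno, x, y, z)
}

# n-residue single-chain CA-only PDB text along a line (3.8 A spacing)
make_pdb_text <- function(n, chain = "A", spacing = 3.8, drop_ca_for = integer(0)) {
  lines <- character(0)
  s <- 1
  for (r in seq_len(n)) {
    if (!(r %in% drop_ca_for)) {
      lines <- c(lines, pdb_atom_line(s, "GLY", chain, r, spacing * (r - 1), 0, 0))
      s <- s + 1
    }
    # a second (non-CA) atom so residues missing CA are still present
    lines <- c(lines, pdb_atom_line(s, "GLY", chain, r, spacing * (r - 1), 1.5, 0,
                                    atom = "CB"))
    s <- s + 1
  }
  paste(c(lines, "END"), collapse = "\n")
}

# straight chain structure (no contacts under the default criterion)
straight_chain <- function(n, spacing = 3.8) {
  calpha_structure(cbind(spacing * (seq_len(n) - 1), 0, 0), source = "straight")
}

# random compact bead cloud re-used across tests (deterministic)
toy_fixture <- local({
  cache <- new.env()
  function(n = 16, seed = 42) {
    key <- paste0("t", n, "_", seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_toy_domain(n, seed = seed)
    cache[[key]]
  }
})

# minimal hand-built topology (bonds/contacts only) for integrator tests
bare_topology <- function(xyz, bonds, contacts = NULL, sigma_nn = 4.0,
                          eps_nn = 1.0, min_sep = 3L) {
  n <- nrow(xyz)
  cm <- if (is.null(contacts)) {
    contact_map(data.frame(i = integer(0), j = integer(0), sigma = numeric(0)), n)
  } else contact_map(contacts, n)
  structure(list(
    n_beads = n, bonds = bonds,
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), k_angle = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0), k_dihedral = numeric(0)),
    contacts = cm,
    excluded_volume = list(sigma_nn = sigma_nn, epsilon_nn = eps_nn, min_sep = min_sep),
    masses = rep(1, n), native_coords = xyz,
    provenance = "test fixture"), class = "sbm_topology")
}

# make a fake trajectory object from a list of coordinate matrices
traj_from_frames <- function(frame_list, T = 1) {
  n <- nrow(frame_list[[1]])
  fr <- array(unlist(frame_list), dim = c(n, 3, length(frame_list)))
  structure(list(frames = fr, potential_energy = rep(0, length(frame_list)),
                 kinetic_energy = rep(0, length(frame_list)),
                 step_indices = seq_along(frame_list), T = T, dt = 0.005,
                 friction = 1, seed = 0L, topology_provenance = "fixture"),
            class = "sbm_trajectory")
}

# hinge toy: two 8-bead blobs joined by a 2-bead zigzag hinge; the closed
# conformation rotates the second blob about the hinge to dock against the
# first, giving a dual-basin fixture with a dozen closed-specific contacts
make_hinge_pair <- function(th_deg = 130) {
  a <- make_toy_domain(8, seed = 101)$structure$xyz
  b <- make_toy_domain(8, seed = 102)$structure$xyz
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  xa <- max(a[, 1])
  h1 <- c(xa + 3.4, 1.6, 0); h2 <- c(xa + 6.8, -1.6, 0)
  bshift <- sweep(b, 2, c(h2[1] + 3.4 - min(b[, 1]), 0, 0), "+")
  th <- th_deg * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- function(x) sweep(sweep(x, 2, h1) %*% t(Rz), 2, h1, "+")
  list(open = calpha_structure(rbind(a, h1, h2, bshift), source = "hinge open"),
       closed = calpha_structure(rbind(a, h1, rot(rbind(h2, bshift))),
                                 source = "hinge closed"))
}
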