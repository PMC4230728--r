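# Synthetic toy proteins: compact self-avoiding bead domains, two-domain
# constructs in inserted / singly-linked chain topologies, and telegraph
# reaction-coordinate fixtures with known ground truth.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a compact toy protein domain
#'
#' Grows a self-avoiding random walk with bond length 3.8 Angstrom, then
#' collapses it by seeded Langevin dynamics under a soft spherical
#' restraint and a cold quench. The result is a compact bead structure
#' with, at default compactness, at least 1.5 native contacts per residue
#' (8 Angstrom / min_sep 3 criterion) and no non-bonded bead pair closer
#' than 3.5 Angstrom. Deterministic given `seed`.
#'
#' @param n number of beads (>= 8).
#' @param compactness sphere-radius scale; 1 gives protein-like density,
#'   smaller values give looser structures.
#' @param seed integer seed.
#' @param max_retries collapse attempts (with perturbed sub-seeds) before
#'   giving up.
#' @return list with `structure` (a [calpha_structure]) and `cmap`
#'   (its [contact_map], epsilon = 1).
#' @export
make_toy_domain <- function(n, compactness = 1, seed = 1L, max_retries = 8L) {
  stopifnot(n >= 8, compactness > 0)
  for (attempt in seq_len(max_retries)) {
    out <- with_local_seed(seed + 7907L * (attempt - 1L),
                           try_toy_domain(n, compactness,
                                          seed + 7907L * (attempt - 1L)))
    if (!is.null(out)) {
      out$structure$source <- sprintf("synthetic toy domain (n=%d, seed=%d)", n, seed)
      return(out)
    }
  }
  stop(sprintf("failed to generate a compact self-avoiding %d-bead domain after %d retries",
               n, max_retries))
}

try_toy_domain <- function(n, compactness, engine_seed) {
  bond <- 3.8
  xyz <- saw_grow(n, bond, pull = 0.5 * min(compactness, 1))
  if (is.null(xyz)) return(NULL)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  R <- 2.7 * n^(1/3) / compactness^(1/3)
  collapse_topo <- structure(list(
    n_beads = n,
    bonds = data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1, r0 = bond, k = 20),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), k_angle = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0), k_dihedral = numeric(0)),
    contacts = contact_map(data.frame(i = integer(0), j = integer(0),
                                      sigma = numeric(0)), n),
    excluded_volume = list(sigma_nn = 4.0, epsilon_nn = 1.0, min_sep = 2L),
    masses = rep(1, n), native_coords = xyz,
    restraint = list(k = 5, R = R, center = c(0, 0, 0)),
    provenance = "toy-domain collapse"), class = "sbm_topology")
  # collapse hot, then anneal, then quench
  tr <- run_langevin(collapse_topo, T = 1.0, n_steps = 20000, dt = 0.005,
                     friction = 1, seed = engine_seed, save_every = 20000)
  tr <- run_langevin(collapse_topo, T = 0.2, n_steps = 20000, dt = 0.005,
                     friction = 1, seed = engine_seed + 1L, save_every = 20000,
                     coords0 = tr$final_coords)
  tr <- run_langevin(collapse_topo, T = 0.02, n_steps = 10000, dt = 0.005,
                     friction = 1, seed = engine_seed + 2L, save_every = 10000,
                     coords0 = tr$final_coords)
  xyz <- sweep(tr$final_coords, 2, colMeans(tr$final_coords))
  st <- calpha_structure(xyz, source = "synthetic")
  d <- as.matrix(stats::dist(xyz))
  nb <- which(upper.tri(d) & (col(d) - row(d)) >= 2, arr.ind = FALSE)
  if (min(d[nb]) < 3.5) return(NULL)
  cmap <- compute_contact_map(st)
  if (compactness >= 1 && nrow(cmap) / n < 1.5) return(NULL)
  list(structure = st, cmap = cmap)
}

saw_grow <- function(n, bond, pull = 0.5, max_restarts = 30L, tries_per_step = 100L) {
  for (res in seq_len(max_restarts)) {
    xyz <- matrix(0, n, 3)
    xyz[2, ] <- c(bond, 0, 0)
    ok <- TRUE
    for (k in 3:n) {
      placed <- FALSE
      for (t in seq_len(tries_per_step)) {
        centroid <- colMeans(xyz[seq_len(k - 1), , drop = FALSE])
        inward <- centroid - xyz[k - 1, ]
        pn <- sqrt(sum(inward^2))
        dir <- stats::rnorm(3) + if (pn > 1e-9) pull * inward / pn else 0
        dir <- dir / sqrt(sum(dir^2))
        cand <- xyz[k - 1, ] + bond * dir
        prev <- xyz[seq_len(k - 2), , drop = FALSE]
        if (min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > 3.8) {
          xyz[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  NULL
}

#' Generate a two-domain toy protein
#'
#' Builds a large and a small compact domain, docks the small domain
#' against a surface patch of the large one (centroid `interface_distance`
#' Angstrom out from the patch residue, rigid-body rotation chosen to
#' shorten the chain junctions without steric clash), and threads the chain
#' through the assembly in one of two topologies:
#'
#' * `"inserted"`: the small domain's sequence is embedded after residue
#'   `insertion_point` of the large domain, so the large domain is
#'   discontinuous (two intervals) and the small domain inserted;
#' * `"singly_linked"`: the small domain is appended after the large one.
#'
#' The 3-D geometry and hence the contact content are identical between the
#' modes (a candidate pair only counts as a contact when its sequence
#' separation is >= 3 under *both* topologies); the only systematic
#' difference is chain connectivity. Contact strengths encode the
#' stability contrast: intra-large epsilon = 1, intra-small epsilon =
#' `stability_ratio`, interface epsilon = sqrt(`stability_ratio`).
#'
#' @param n_large,n_small domain sizes in beads (>= 8 each).
#' @param topology_mode `"inserted"` or `"singly_linked"`.
#' @param stability_ratio epsilon_small / epsilon_large (< 1 makes the
#'   small domain less stable, the situation domain insertion compensates).
#' @param insertion_point large-domain residue after which the small domain
#'   is inserted (interior; default: the large domain's most
#'   surface-exposed interior residue).
#' @param interface_distance docking distance in Angstrom between the patch
#'   residue and the small domain's centroid; the default 7 A produces a
#'   small emergent interface (a handful of contacts) at the 8 A contact
#'   criterion, mirroring the sparse functional interfaces of inserted
#'   domains.
#' @param seed integer seed (both domains and the docking search derive
#'   from it).
#' @return list with `structure`, `cmap`, `partition` (domains `large`,
#'   `small`), `exclusions` (close pairs that are sequence-local in at
#'   least one threading; pass to [build_wt_model()] as
#'   `extra_exclusions`), `insertion_point`, `mode`.
#' @export
make_two_domain_protein <- function(n_large = 28L, n_small = 12L,
                                    topology_mode = c("inserted", "singly_linked"),
                                    stability_ratio = 0.5,
                                    insertion_point = NULL,
                                    interface_distance = 7,
                                    seed = 1L) {
  topology_mode <- match.arg(topology_mode)
  stopifnot(n_large >= 8, n_small >= 8, stability_ratio > 0)
  large <- make_toy_domain(n_large, seed = seed)
  small <- make_toy_domain(n_small, seed = seed + 7919L)
  xyzL <- sweep(large$structure$xyz, 2, colMeans(large$structure$xyz))
  xyzS0 <- sweep(small$structure$xyz, 2, colMeans(small$structure$xyz))

  interior <- 2:(n_large - 1)
  if (is.null(insertion_point)) {
    p <- interior[which.max(sqrt(rowSums(xyzL[interior, , drop = FALSE]^2)))]
  } else {
    p <- as.integer(insertion_point)
    if (p < 2 || p > n_large - 1)
      stop("insertion_point must be interior to the large domain")
  }
  u <- xyzL[p, ] / sqrt(sum(xyzL[p, ]^2))

  dock <- with_local_seed(seed + 13L, {
    rots <- c(list(diag(3)), lapply(1:60, function(i) {
      qr_r <- qr(matrix(stats::rnorm(9), 3))
      Qm <- qr.Q(qr_r)
      if (det(Qm) < 0) Qm[, 1] <- -Qm[, 1]
      Qm
    }))
    best <- NULL
    for (extra in 0:5) {
      target <- xyzL[p, ] + (interface_distance + extra) * u
      for (Rm in rots) {
        xyzS <- sweep(xyzS0 %*% t(Rm), 2, target, "+")
        cross <- sqrt(outer(rowSums(xyzL^2), rowSums(xyzS^2), "+") -
                        2 * xyzL %*% t(xyzS))
        if (min(cross) < 4.0) next
        score <- sqrt(sum((xyzS[1, ] - xyzL[p, ])^2)) +
          sqrt(sum((xyzS[n_small, ] - xyzL[min(p + 1, n_large), ])^2))
        if (is.null(best) || score < best$score)
          best <- list(xyzS = xyzS, score = score)
      }
      if (!is.null(best)) break
    }
    best
  })
  if (is.null(dock)) stop("could not dock the small domain without steric clash")
  xyzS <- dock$xyzS

  # contact content on the assembly, independent of threading order
  all_xyz <- rbind(xyzL, xyzS)
  is_small <- c(rep(FALSE, n_large), rep(TRUE, n_small))
  linked_idx <- seq_len(n_large + n_small)
  inserted_idx <- c(ifelse(seq_len(n_large) <= p, seq_len(n_large),
                           seq_len(n_large) + n_small),
                    p + seq_len(n_small))
  d <- as.matrix(stats::dist(all_xyz))
  pr <- which(upper.tri(d) & d <= 8.0, arr.ind = TRUE)
  sep_ok <- abs(linked_idx[pr[, 2]] - linked_idx[pr[, 1]]) >= 3 &
    abs(inserted_idx[pr[, 2]] - inserted_idx[pr[, 1]]) >= 3
  # pairs that are spatially close but sequence-local in at least one
  # threading: excluded from the non-native repulsion in BOTH modes so the
  # two potentials differ only by chain connectivity (and the native state
  # stays an exact minimum)
  excl_pr <- pr[!sep_ok, , drop = FALSE]
  pr <- pr[sep_ok, , drop = FALSE]
  eps <- ifelse(!is_small[pr[, 1]] & !is_small[pr[, 2]], 1,
                ifelse(is_small[pr[, 1]] & is_small[pr[, 2]], stability_ratio,
                       sqrt(stability_ratio)))

  if (topology_mode == "inserted") {
    new_idx <- inserted_idx
    partition <- domain_partition(list(
      large = rbind(c(1L, p), c(p + n_small + 1L, n_large + n_small)),
      small = c(p + 1L, p + n_small)))
  } else {
    new_idx <- linked_idx
    partition <- domain_partition(list(large = c(1L, n_large),
                                       small = c(n_large + 1L, n_large + n_small)))
  }
  ei <- new_idx[excl_pr[, 1]]; ej <- new_idx[excl_pr[, 2]]
  exclusions <- cbind(i = pmin(ei, ej), j = pmax(ei, ej))
  exclusions <- exclusions[exclusions[, 2] - exclusions[, 1] >= 3, , drop = FALSE]
  ord <- order(new_idx)
  structure_out <- calpha_structure(
    all_xyz[ord, , drop = FALSE],
    source = sprintf("synthetic two-domain (%s, nL=%d, nS=%d, ratio=%g, seed=%d)",
                     topology_mode, n_large, n_small, stability_ratio, seed))
  ci <- new_idx[pr[, 1]]; cj <- new_idx[pr[, 2]]
  cmap <- contact_map(data.frame(i = pmin(ci, cj), j = pmax(ci, cj),
                                 sigma = d[pr], epsilon = eps),
                      n_large + n_small)
  cmap <- classify_contacts(cmap, partition)
  list(structure = structure_out, cmap = cmap, partition = partition,
       exclusions = exclusions,
       insertion_point = p, mode = topology_mode,
       spec = list(n_large = n_large, n_small = n_small,
                   stability_ratio = stability_ratio, seed = seed))
}

#' Telegraph Q series and contact-formation fixture with known truth
#'
#' Generates a two-state telegraph folding coordinate with planted
#' transitions and a binary contact-formation matrix whose columns are
#' organized into independent correlation blocks, for testing transition
#' detection and foldon clustering against ground truth. Deterministic
#' given `seed`.
#'
#' @param n_frames number of frames.
#' @param switch_rate per-frame flip probability of each telegraph state.
#' @param noise Gaussian noise s.d. added to the Q values (clamped to
#'   \[0, 1\]).
#' @param planted_blocks number of independent contact blocks.
#' @param contacts_per_block columns per block.
#' @param coupling probability that a contact column copies its block's
#'   master state in a given frame (1 = perfectly correlated block).
#' @param seed integer seed.
#' @return list: `q` (a `q_series` switching between 0.1 and 0.9),
#'   `switch_frames` (frames at which the Q state flips), `formation`
#'   (frames x contacts binary matrix), `block_assignment`.
#' @export
make_telegraph_qseries <- function(n_frames = 2000L, switch_rate = 0.01,
                                   noise = 0, planted_blocks = 3L,
                                   contacts_per_block = 12L, coupling = 0.95,
                                   seed = 1L) {
  with_local_seed(seed, {
    telegraph <- function() {
      flips <- stats::runif(n_frames) < switch_rate
      (cumsum(flips) + 0) %% 2
    }
    g <- telegraph()
    qv <- 0.1 + 0.8 * g + if (noise > 0) stats::rnorm(n_frames, 0, noise) else 0
    qv <- pmin(1, pmax(0, qv))
    switch_frames <- which(diff(g) != 0) + 1L
    nc <- planted_blocks * contacts_per_block
    formation <- matrix(0L, n_frames, nc)
    block_assignment <- rep(seq_len(planted_blocks), each = contacts_per_block)
    for (b in seq_len(planted_blocks)) {
      m <- telegraph()
      for (c0 in which(block_assignment == b)) {
        copy <- stats::runif(n_frames) < coupling
        formation[, c0] <- ifelse(copy, m, stats::runif(n_frames) < 0.5)
      }
    }
    list(q = q_series(qv, subset = "telegraph"),
         switch_frames = switch_frames, formation = formation,
         block_assignment = block_assignment)
  })
}
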