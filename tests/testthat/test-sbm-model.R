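test_that("native coordinates minimize the potential at -sum(epsilon)", {
  fx <- toy_fixture()
  topo <- build_wt_model(fx$structure, fx$cmap)
  e <- potential_energy(topo)
  expect_equal(e$total, -sum(topo$contacts$epsilon), tolerance = 1e-6)
  expect_equal(e$bonds + e$angles + e$dihedrals, 0, tolerance = 1e-9)
  expect_lt(max(abs(forces(topo))), 1e-6)
})

test_that("a single 10-12 contact well behaves as the closed form", {
  xyz <- cbind(3.8 * (0:4), 0, 0)
  xyz[5, ] <- c(2, 5, 0)   # bead 5 near bead 1
  sig <- sqrt(sum((xyz[5, ] - xyz[1, ])^2))
  topo <- bare_topology(xyz,
                        bonds = data.frame(i = 1:4, j = 2:5,
                                           r0 = sqrt(rowSums((xyz[2:5, ] - xyz[1:4, ])^2)),
                                           k = 100),
                        contacts = data.frame(i = 1, j = 5, sigma = sig))
  expect_equal(potential_energy(topo)$total, -1, tolerance = 1e-9)
  # stretch the contact to 3 sigma: well rises toward zero
  far <- xyz
  far[5, ] <- xyz[1, ] + (xyz[5, ] - xyz[1, ]) * 3
  e_far <- potential_energy(topo, far)$contacts
  expect_gt(e_far, -0.01)
  expect_lt(e_far, 0)
})

test_that("analytic forces match central finite differences", {
  fx <- toy_fixture(20, seed = 11)
  topo <- build_wt_model(fx$structure, fx$cmap)
  set.seed(1)
  x <- topo$native_coords + matrix(rnorm(60, 0, 0.4), 20, 3)
  fa <- forces(topo, x)
  h <- 1e-5
  fd <- fa * 0
  for (i in 1:20) for (d in 1:3) {
    xp <- x; xm <- x
    xp[i, d] <- xp[i, d] + h
    xm[i, d] <- xm[i, d] - h
    fd[i, d] <- -(potential_energy(topo, xp)$total -
                    potential_energy(topo, xm)$total) / (2 * h)
  }
  expect_lt(max(abs(fa - fd)) / max(abs(fa)), 1e-4)
})

test_that("interface deletion conserves per-residue contact strength", {
  # toy from first principles: residue 5 has an interface contact (5,9) and
  # an intra contact (2,5); 9 loses everything, 5 must be compensated via
  # (2,5). The per-residue sum equation for residue 5 forces eps(2,5) = 2.
  xyz <- toy_fixture(12, seed = 5)$structure$xyz
  cm <- contact_map(data.frame(i = c(2, 5), j = c(5, 9),
                               sigma = c(6, 6), epsilon = c(1, 1),
                               label = c("intra:A", "interface:A-B")), 12)
  topo <- bare_topology(xyz, bonds = data.frame(i = 1:11, j = 2:12,
                                                r0 = 3.8, k = 100),
                        contacts = cm)
  expect_warning(del <- delete_interface(topo, "interface:A-B"),
                 "residue\\(s\\) 9")
  expect_equal(nrow(del$contacts), 1L)
  expect_equal(del$contacts$epsilon, 2, tolerance = 1e-6)

  expect_error(delete_interface(topo, "interface:X-Y"), "no contacts carry")
})

test_that("interface deletion on realistic two-domain maps preserves all
          solvable sums and leaves non-incident contacts untouched", {
  for (seed in 1:3) {
    p <- make_two_domain_protein(20, 10, "singly_linked", seed = seed,
                                 interface_distance = 6)
    n <- attr(p$cmap, "n_residues")
    topo <- build_wt_model(p$structure, p$cmap)
    lab <- "interface:large-small"
    expect_gte(sum(p$cmap$label == lab), 3)
    wt_sums <- foldcoop:::residue_eps_sums(topo$contacts, n)
    iface <- p$cmap[p$cmap$label == lab, ]
    affected <- sort(unique(c(iface$i, iface$j)))
    del <- suppressWarnings(delete_interface(topo, lab))
    new_sums <- foldcoop:::residue_eps_sums(del$contacts, n)
    solvable <- affected[new_sums[affected] > 0]
    expect_true(all(abs(new_sums[solvable] - wt_sums[solvable]) < 1e-6))
    # contacts not incident to an affected residue keep their strength
    untouched <- as.data.frame(topo$contacts)
    untouched <- untouched[!(untouched$i %in% affected) &
                             !(untouched$j %in% affected), ]
    m <- match(paste(untouched$i, untouched$j),
               paste(del$contacts$i, del$contacts$j))
    expect_true(all(abs(untouched$epsilon - del$contacts$epsilon[m]) < 1e-12))
  }
})

test_that("circular permutation renumbers without losing contacts", {
  fx <- toy_fixture(12, seed = 9)
  # identity position
  id <- circular_permute(fx$structure, fx$cmap, cut_after = 12, linker_length = 0)
  expect_equal(id$index_map, 1:12)
  expect_equal(as.data.frame(id$cmap), as.data.frame(fx$cmap))

  cp <- circular_permute(fx$structure, fx$cmap, cut_after = 5, linker_length = 2)
  # brute-force rebuild of the permuted numbering
  expect_equal(cp$index_map[6:12], (6:12) - 5)
  expect_equal(cp$index_map[1:5], (1:5) + 9)
  expect_equal(length(cp$structure), 14L)
  expect_equal(cp$linker_residues, c(8L, 9L))
  expect_equal(nrow(cp$cmap), nrow(fx$cmap))
  # every WT contact maps to exactly one CP contact with same sigma/epsilon
  old_key <- paste(round(sort(fx$cmap$sigma), 9), collapse = ",")
  new_key <- paste(round(sort(cp$cmap$sigma), 9), collapse = ",")
  expect_equal(new_key, old_key)
  # linker beads carry no contacts
  expect_false(any(cp$cmap$i %in% cp$linker_residues |
                     cp$cmap$j %in% cp$linker_residues))
  # cutting inside the engineered linker is refused
  expect_error(circular_permute(cp$structure, cp$cmap, cut_after = 8,
                                linker_length = 0), "linker")
})

test_that("complementary circular permutations restore the contact multiset", {
  fx <- toy_fixture(12, seed = 9)
  cp1 <- circular_permute(fx$structure, fx$cmap, cut_after = 5, linker_length = 0)
  cp2 <- circular_permute(cp1$structure, cp1$cmap, cut_after = 12 - 5,
                          linker_length = 0)
  ms <- function(cm) sort(paste(round(cm$sigma, 9), cm$epsilon))
  expect_equal(ms(cp2$cmap), ms(fx$cmap))
  expect_equal(cp2$index_map[cp1$index_map], 1:12)
})

test_that("dual-basin construction adds exactly the closed-specific contacts", {
  fx <- toy_fixture(12, seed = 2)
  topo <- build_wt_model(fx$structure, fx$cmap)
  # closed structure identical to open: nothing to add
  dual0 <- build_dual_model(topo, fx$structure)
  expect_equal(nrow(dual0$contacts), nrow(topo$contacts))

  # bend the chain so one extra pair comes within the cutoff
  xyz2 <- fx$structure$xyz
  far_pairs <- which(as.matrix(dist(xyz2)) > 8 &
                       abs(row(diag(12)) - col(diag(12))) >= 3, arr.ind = TRUE)
  pick <- far_pairs[1, ]
  dirv <- xyz2[pick[2], ] - xyz2[pick[1], ]
  xyz2[pick[2], ] <- xyz2[pick[1], ] + dirv / sqrt(sum(dirv^2)) * 6.0
  closed <- calpha_structure(xyz2, source = "closed")
  closed_cm <- compute_contact_map(closed)
  dual <- build_dual_model(topo, closed, epsilon_closed = 0.7)
  added <- dual$contacts[!is.na(dual$contacts$label) &
                           dual$contacts$label == "closed-specific", ]
  brute <- setdiff(paste(closed_cm$i, closed_cm$j),
                   paste(topo$contacts$i, topo$contacts$j))
  expect_equal(sort(paste(added$i, added$j)), sort(brute))
  expect_true(all(added$epsilon == 0.7))

  # exact decomposition E_dual = E_open + E_closed_contacts at arbitrary coords
  set.seed(3)
  x <- fx$structure$xyz + matrix(rnorm(36, 0, 1), 12, 3)
  e_dual <- potential_energy(dual, x)$total
  e_open <- potential_energy(topo, x)$total
  closed_only <- topo
  closed_only$contacts <- contact_map(as.data.frame(added), 12)
  e_closed <- potential_energy(closed_only, x)$contacts
  # the open topology's non-native term differs where added pairs are now
  # excluded from repulsion; account for it explicitly
  e_nn_diff <- potential_energy(topo, x)$nonnative -
    potential_energy(dual, x)$nonnative
  expect_equal(e_dual, e_open + e_closed - e_nn_diff, tolerance = 1e-9)

  expect_error(build_dual_model(topo, toy_fixture(16, seed = 2)$structure),
               "identical residue counts")
})

test_that("topology JSON serialization round-trips", {
  fx <- toy_fixture(12, seed = 2)
  topo <- build_wt_model(fx$structure, fx$cmap)
  path <- withr::local_tempfile(fileext = ".json")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_equal(back$n_beads, topo$n_beads)
  expect_equal(back$bonds$r0, topo$bonds$r0, tolerance = 1e-12)
  expect_equal(back$dihedrals$phi0, topo$dihedrals$phi0, tolerance = 1e-12)
  expect_equal(as.data.frame(back$contacts), as.data.frame(topo$contacts),
               tolerance = 1e-12)
  expect_equal(potential_energy(back)$total, potential_energy(topo)$total,
               tolerance = 1e-9)
})
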