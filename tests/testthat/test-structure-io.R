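test_that("PDB parsing extracts CA beads, renumbers, and reports bad input", {
  txt <- make_pdb_text(5)
  st <- read_calpha_structure(txt, "A")
  expect_s3_class(st, "calpha_structure")
  expect_equal(length(st), 5L)
  expect_equal(st$residue_ids, 1:5)
  expect_equal(st$xyz[, 1], 3.8 * (0:4))
  expect_equal(st$xyz[, 2], rep(0, 5))

  expect_error(read_calpha_structure(txt, "B"), "chain 'B' not found")
  expect_error(read_calpha_structure(make_pdb_text(10, drop_ca_for = 7), "A"),
               "missing CA.*7")
})

test_that("alternate locations resolve to the first occurrence", {
  lines <- c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "ALA", "A", 2, 3.8, 0, 0, altloc = "A"),
             pdb_atom_line(3, "ALA", "A", 2, 4.2, 0, 0, altloc = "B"),
             pdb_atom_line(4, "ALA", "A", 3, 7.6, 0, 0),
             pdb_atom_line(5, "ALA", "A", 4, 11.4, 0, 0), "END")
  st <- read_calpha_structure(paste(lines, collapse = "\n"), "A")
  expect_equal(length(st), 4L)
  expect_equal(st$xyz[2, 1], 3.8)
})

test_that("contact map computation matches a brute-force all-pairs scan", {
  # far-apart beads: no contacts
  far <- calpha_structure(cbind(c(0, 20, 40, 60), 0, 0), source = "far")
  expect_equal(nrow(compute_contact_map(far, cutoff = 8)), 0L)

  # straight chain: nearest eligible pair is 3 x 3.8 = 11.4 A > 8 A
  expect_equal(nrow(compute_contact_map(straight_chain(10))), 0L)

  # random beads vs exhaustive scan
  set.seed(7)
  xyz <- matrix(runif(30, 0, 12), 10, 3)
  st <- calpha_structure(xyz, source = "random")
  cm <- compute_contact_map(st, cutoff = 8, min_sep = 3)
  brute <- do.call(rbind, lapply(1:9, function(i) {
    do.call(rbind, lapply((i + 1):10, function(j) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (j - i >= 3 && d <= 8) data.frame(i = i, j = j, sigma = d) else NULL
    }))
  }))
  expect_equal(nrow(cm), nrow(brute))
  expect_equal(cm$i, brute$i)
  expect_equal(cm$j, brute$j)
  expect_equal(cm$sigma, brute$sigma)
})

test_that("contact maps are invariant under rigid-body motion", {
  fx <- toy_fixture()
  cm0 <- fx$cmap
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- calpha_structure(fx$structure$xyz %*% Rz + matrix(c(5, -3, 11),
                            nrow(fx$structure$xyz), 3, byrow = TRUE),
                            source = "moved")
  cm1 <- compute_contact_map(moved)
  expect_equal(cm1$i, cm0$i)
  expect_equal(cm1$j, cm0$j)
  expect_equal(cm1$sigma, cm0$sigma, tolerance = 1e-9)
})

test_that("contact lists load, validate, and round-trip", {
  cm <- load_contact_list(c("# i j sigma epsilon", "1 5 6.0", "2 8 7.1"), 10)
  expect_equal(nrow(cm), 2L)
  expect_equal(cm$epsilon, c(1, 1))
  expect_equal(cm$sigma, c(6.0, 7.1))

  expect_error(load_contact_list("5 1 6.0", 10), "row 1.*i < j")
  expect_error(load_contact_list(c("1 5 6.0", "1 5 6.0"), 10), "duplicate")
  expect_error(load_contact_list("1 12 6.0", 10), "out of range")
  expect_error(load_contact_list("1 5 -2.0", 10), "non-positive sigma")

  # round-trip identity
  fx <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_list(fx$cmap, path)
  back <- load_contact_list(path, attr(fx$cmap, "n_residues"))
  expect_equal(back$i, fx$cmap$i)
  expect_equal(back$j, fx$cmap$j)
  expect_equal(back$sigma, fx$cmap$sigma, tolerance = 1e-6)
  expect_equal(back$epsilon, fx$cmap$epsilon, tolerance = 1e-6)
})

test_that("domain partitions enforce their invariants and flags", {
  part <- domain_partition(list(host = rbind(c(1, 10), c(21, 30)),
                                insert = c(11, 20)))
  expect_true(domain_is_discontinuous(part, "host"))
  expect_false(domain_is_discontinuous(part, "insert"))
  expect_true(domain_is_inserted(part, "insert"))
  expect_false(domain_is_inserted(part, "host"))

  expect_error(domain_partition(list(a = c(1, 10), b = c(10, 20))), "overlap")
  expect_error(domain_partition(list(a = rbind(c(1, 10), c(5, 20)))), "overlap")

  rd <- residue_domains(part, 32)
  expect_equal(rd[5], "host")
  expect_equal(rd[15], "insert")
  expect_true(is.na(rd[31]))

  path <- withr::local_tempfile(fileext = ".json")
  write_domain_partition(part, path)
  back <- read_domain_partition(path)
  expect_equal(unclass(back), unclass(part))
})

test_that("contact classification partitions the contact set", {
  cm <- contact_map(data.frame(i = c(1, 2, 5, 12, 3),
                               j = c(5, 9, 14, 16, 20),
                               sigma = rep(6, 5)), 20)
  part <- domain_partition(list(A = c(1, 8), B = c(9, 16)))
  lab <- classify_contacts(cm, part)
  expect_equal(sort(lab$label[lab$i == 1]), "intra:A")
  expect_equal(lab$label[lab$i == 12], "intra:B")
  expect_equal(sum(lab$label == "interface:A-B", na.rm = TRUE), 2L)
  expect_true(is.na(lab$label[lab$j == 20]))   # residue 20 outside all domains
  n_intra <- sum(startsWith(lab$label, "intra:"), na.rm = TRUE)
  n_iface <- sum(startsWith(lab$label, "interface:"), na.rm = TRUE)
  expect_equal(n_intra + n_iface + sum(is.na(lab$label)), nrow(lab))

  # single-domain partition: everything intra
  one <- classify_contacts(cm, domain_partition(list(all = c(1, 20))))
  expect_true(all(one$label == "intra:all"))
})
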