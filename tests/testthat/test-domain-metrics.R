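test_that("contact order and packing fraction match brute force", {
  expect_equal(absolute_contact_order(data.frame(i = 10, j = 25)), 15)
  expect_error(absolute_contact_order(data.frame(i = integer(0), j = integer(0))),
               "empty")

  set.seed(41)
  i <- sample(1:40, 50, replace = TRUE)
  j <- i + sample(3:20, 50, replace = TRUE)
  cm <- data.frame(i = i, j = j)
  expect_equal(absolute_contact_order(cm), mean(j - i))

  expect_equal(packing_fraction(data.frame(i = 1:20, j = 21:40), 10), 2.0)
  expect_equal(packing_fraction(data.frame(i = integer(0)), 10), 0)
})

test_that("domain metrics use intra-domain contacts and residue counts", {
  cm <- contact_map(data.frame(i = c(1, 2, 11, 12, 5, 21),
                               j = c(6, 9, 16, 19, 13, 27),
                               sigma = 6), 30)
  part <- domain_partition(list(A = c(1, 10), B = c(11, 20),
                                C = rbind(c(21, 24), c(26, 30))))
  m <- domain_metrics(cm, part)
  expect_equal(m$ACO[m$domain == "A"], mean(c(5, 7)))
  expect_equal(m$ACO[m$domain == "B"], mean(c(5, 7)))
  expect_equal(m$L[m$domain == "C"], 9L)        # residue count, not span
  expect_equal(m$rho[m$domain == "A"], 0.2)
  expect_equal(m$ACO[m$domain == "C"], 6)       # contact (21,27) internal to C
})

test_that("insert comparison flags follow the strict y > x rule", {
  part <- domain_partition(list(host = rbind(c(1, 12), c(25, 60)),
                                insert = c(13, 24)))
  cm <- contact_map(data.frame(
    i = c(2, 4, 1, 30, 28, 40, 14, 16, 13),
    j = c(30, 40, 50, 55, 44, 58, 20, 22, 17),
    sigma = 6), 60)
  comp <- compare_insert_pair(cm, part, "insert", "host")
  expect_true(comp$flags$aco_higher)
  expect_true(comp$flags$length_higher)
  expect_false(comp$flags$rho_higher)   # equal rho is not strictly higher
  expect_false(comp$flags$all_three)

  # metrically identical artificial domains: every flag false
  part2 <- domain_partition(list(host = rbind(c(1, 5), c(16, 20)),
                                 ins = c(6, 15)))
  cm2 <- contact_map(data.frame(i = c(2, 8), j = c(5, 11), sigma = 6), 30)
  comp2 <- compare_insert_pair(cm2, part2, "ins", "host")
  expect_false(comp2$flags$aco_higher)
  expect_false(comp2$flags$length_higher)
  expect_false(comp2$flags$rho_higher)
  expect_false(comp2$flags$all_three)

  # "inserted" domain that is not actually inserted is refused
  part3 <- domain_partition(list(a = c(1, 10), b = c(11, 20)))
  expect_error(compare_insert_pair(cm2, part3, "a", "b"), "not inserted")
})

test_that("insert comparison agrees with brute-force metric comparison", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(10:20, 1)
    m <- sample(8:12, 1)
    n <- 40 + m
    part <- domain_partition(list(host = rbind(c(1, p), c(p + m + 1, n)),
                                  ins = c(p + 1, p + m)))
    i <- sample(seq_len(n - 4), 60, replace = TRUE)
    j <- pmin(i + sample(3:25, 60, replace = TRUE), n)
    ok <- j - i >= 3 & !duplicated(paste(i, j))
    cm <- contact_map(data.frame(i = i[ok], j = j[ok], sigma = 6), n)
    comp <- compare_insert_pair(cm, part, "ins", "host")
    dom <- residue_domains(part, n)
    sub <- function(nm) cm[dom[cm$i] == nm & dom[cm$j] == nm &
                             !is.na(dom[cm$i]) & !is.na(dom[cm$j]), ]
    aco <- function(s) if (nrow(s)) mean(s$j - s$i) else NA
    expect_equal(comp$flags$aco_higher,
                 isTRUE(aco(sub("host")) > aco(sub("ins"))))
    expect_equal(comp$flags$length_higher, (n - m) > m)
    expect_equal(comp$flags$rho_higher,
                 isTRUE(nrow(sub("host")) / (n - m) > nrow(sub("ins")) / m))
  }
})

test_that("circular permutation changes contact order through renumbering", {
  fx <- toy_fixture()
  aco_wt <- absolute_contact_order(fx$cmap)
  cp <- circular_permute(fx$structure, fx$cmap, cut_after = 8, linker_length = 4)
  aco_cp <- absolute_contact_order(cp$cmap)
  # same 3-D contacts (sigma multiset identical) but different ACO
  expect_equal(sort(cp$cmap$sigma), sort(fx$cmap$sigma), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(aco_wt, aco_cp)))
})

test_that("ACO of a union decomposes as the weighted mean of its parts", {
  set.seed(43)
  a <- data.frame(i = sample(1:10, 8, TRUE), sep = sample(3:8, 8, TRUE))
  b <- data.frame(i = sample(30:40, 6, TRUE), sep = sample(3:8, 6, TRUE))
  cross <- data.frame(i = sample(1:10, 5, TRUE), sep = sample(25:35, 5, TRUE))
  mk <- function(d) data.frame(i = d$i, j = d$i + d$sep)
  all3 <- rbind(mk(a), mk(b), mk(cross))
  expected <- (8 * absolute_contact_order(mk(a)) +
                 6 * absolute_contact_order(mk(b)) +
                 5 * absolute_contact_order(mk(cross))) / 19
  expect_equal(absolute_contact_order(all3), expected, tolerance = 1e-12)
})

test_that("interface-spanning functional sites are flagged", {
  part <- domain_partition(list(NMP = c(30, 67), LID = c(118, 160),
                                CORE = rbind(c(1, 29), c(68, 117), c(161, 214))))
  res <- interface_function_flag(list(c(30, 120)), part, "NMP", "LID", 214)
  expect_true(res$per_site)
  expect_true(res$any_spans)

  inside <- interface_function_flag(list(c(70, 80, 100)), part, "CORE", "LID", 214)
  expect_false(inside$per_site)
  expect_false(inside$any_spans)

  expect_error(interface_function_flag(list(c(10, 500)), part, "CORE", "LID", 214),
               "outside the chain")

  # random sites vs brute-force membership
  set.seed(47)
  dom <- residue_domains(part, 214)
  sites <- lapply(1:10, function(k) sample(1:214, sample(2:6, 1)))
  res <- interface_function_flag(sites, part, "CORE", "NMP", 214)
  brute <- vapply(sites, function(s)
    any(dom[s] == "CORE", na.rm = TRUE) && any(dom[s] == "NMP", na.rm = TRUE),
    logical(1))
  expect_equal(res$per_site, brute)
})
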