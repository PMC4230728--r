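test_that("Q is 1 at native, 0 for fully broken, 0.5 for half-formed", {
  fx <- toy_fixture()
  topo <- build_wt_model(fx$structure, fx$cmap)
  expect_equal(compute_q(topo$native_coords, topo$contacts)$values, 1)

  # fully extended chain: every contact distance beyond 3 sigma
  n <- length(fx$structure)
  ext <- cbind(30 * (seq_len(n) - 1), 0, 0)
  expect_lt(compute_q(ext, topo$contacts)$values, 0.01)

  # artificial configuration: half the contacts exactly at sigma, half at
  # 10 sigma, by choosing sigma values against fixed geometry
  xyz <- cbind(c(0, 50, 100, 150, 200, 250), 0, 0)
  contacts <- data.frame(i = c(1, 2, 3, 1, 2, 3), j = c(2, 3, 4, 4, 5, 6),
                         sigma = c(50, 50, 50, 15, 15, 15), epsilon = 1)
  q <- compute_q(xyz, contacts)$values
  expect_equal(q, 0.5, tolerance = 0.01)
})

test_that("strength-scaled Q* weights contacts by epsilon", {
  xyz <- cbind(c(0, 5, 10, 60), 0, 0)
  contacts <- data.frame(i = c(1, 2), j = c(2, 4), sigma = c(5, 5),
                         epsilon = c(3, 1))
  # contact 1 formed (r = sigma), contact 2 broken (r = 11 sigma)
  expect_equal(compute_q(xyz, contacts)$values, 0.5, tolerance = 0.01)
  expect_equal(compute_q(xyz, contacts, strength_scaled = TRUE)$values, 0.75,
               tolerance = 0.01)
})

test_that("uniformly inflating distances never increases Q", {
  fx <- toy_fixture()
  topo <- build_wt_model(fx$structure, fx$cmap)
  lambdas <- c(1, 1.05, 1.2, 1.5, 2, 3, 5)
  qs <- vapply(lambdas, function(l)
    compute_q(topo$native_coords * l, topo$contacts)$values, 0)
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("centre-of-mass distances match brute-force averaging", {
  xyz <- rbind(c(0, 0, 0), c(0, 3, 0), c(5, 0, 0), c(5, 4, 0))
  expect_equal(com_distance(xyz, 1, 3), 5)
  set.seed(9)
  xyz <- matrix(rnorm(60), 20, 3)
  a <- c(1, 4, 7); b <- c(2, 9, 15, 20)
  expect_equal(com_distance(xyz, a, b),
               sqrt(sum((colMeans(xyz[a, ]) - colMeans(xyz[b, ]))^2)))
  expect_error(com_distance(xyz, a, a), "disjoint")
  expect_error(com_distance(xyz, integer(0), b), "non-empty")
})

test_that("single-run WHAM at its own temperature is -ln(histogram)", {
  set.seed(11)
  rc <- runif(5000)
  en <- rnorm(5000, 10, 2)
  fep <- wham_reweight(wham_run(1.3, en, rc), target_T = 1.3, n_bins = 20,
                       n_blocks = 0)
  h <- hist(rc, breaks = seq(0, 1, length.out = 21), plot = FALSE)$counts
  ref <- -log(h / sum(h))
  ref <- ref - min(ref)
  expect_equal(fep$dG, ref, tolerance = 1e-9)
})

test_that("WHAM recovers the closed-form harmonic free energy", {
  # V(q) = k q^2 sampled exactly from its Boltzmann distribution
  k <- 3; T <- 0.8
  set.seed(13)
  q <- rnorm(40000, 0, sqrt(T / (2 * k)))
  fep <- wham_reweight(wham_run(T, k * q^2, q), target_T = T, n_bins = 30,
                       rc_range = c(-1, 1), n_blocks = 10)
  pop <- !is.na(fep$dG) & fep$variance > 0
  expected <- k * fep$rc_grid^2 / T
  expected <- expected - min(expected[pop])
  # agreement within twice the jackknife error on well-populated bins
  dev <- abs(fep$dG[pop] - expected[pop])
  expect_true(mean(dev <= pmax(2 * sqrt(fep$variance[pop]), 0.05)) > 0.9)
})

test_that("profiles from two temperatures agree after reweighting to one", {
  k <- 3
  set.seed(17)
  mk <- function(T, n) {
    q <- rnorm(n, 0, sqrt(T / (2 * k)))
    wham_run(T, k * q^2, q)
  }
  r1 <- mk(0.7, 30000); r2 <- mk(1.0, 30000)
  f1 <- wham_reweight(list(r1), 0.85, n_bins = 25, rc_range = c(-1, 1))
  f2 <- wham_reweight(list(r2), 0.85, n_bins = 25, rc_range = c(-1, 1))
  both <- !is.na(f1$dG) & !is.na(f2$dG) & f1$variance > 0 & f2$variance > 0
  tol <- 2 * sqrt(f1$variance[both] + f2$variance[both])
  expect_true(mean(abs(f1$dG[both] - f2$dG[both]) <= pmax(tol, 0.1)) > 0.85)
})

test_that("non-overlapping energy distributions raise a warning", {
  expect_warning(
    wham_reweight(list(wham_run(0.5, rnorm(500, 0, 0.1), runif(500)),
                       wham_run(5, rnorm(500, 100, 0.1), runif(500))),
                  target_T = 1, n_blocks = 0),
    "do not overlap")
})

two_level_runs <- function(delta, ln_g, n = 20000) {
  # exact 50/50 sample at T0 = delta / ln(g), where both states are equally
  # populated; reweighting from the exact empirical distribution reproduces
  # the analytic thermodynamics
  T0 <- delta / ln_g
  wham_run(T0, c(rep(0, n / 2), rep(delta, n / 2)))
}

test_that("the heat-capacity peak of a two-level system sits at delta/ln(g)", {
  delta <- 5; ln_g <- 25
  T0 <- delta / ln_g
  run <- two_level_runs(delta, ln_g)
  Tg <- seq(0.9 * T0, 1.1 * T0, length.out = 401)
  cv <- suppressWarnings(heat_capacity(list(run), Tg, n_blocks = 0))
  expect_equal(cv$T_f, T0, tolerance = 0.01)
  expect_false(cv$no_transition)
})

test_that("harmonic (peakless) systems are flagged as no transition", {
  set.seed(19)
  T <- 1
  en <- T / 2 * rchisq(20000, df = 1)   # one harmonic degree of freedom
  cv <- suppressWarnings(heat_capacity(list(wham_run(T, en)),
                                       seq(0.9, 1.1, length.out = 21),
                                       n_blocks = 0))
  expect_true(cv$no_transition)
  expect_error(cooperativity_ratio(cv), "no detected peak")
})

test_that("cooperativity ratio is 1 for a two-state system and below 1 for
          two uncoupled units with split transition temperatures", {
  delta <- 5; ln_g <- 25
  Tg <- seq(0.12, 0.45, by = 0.0005)
  cv1 <- (delta^2 / Tg^2) * {
    p <- 1 / (1 + exp(ln_g - delta / Tg)); p * (1 - p)
  }
  r1 <- cooperativity_ratio(heat_capacity_curve(Tg, cv1))
  expect_equal(r1$ratio, 1, tolerance = 0.02)

  # second unit with a well-separated transition temperature
  d2 <- 5; g2 <- 17   # T_f2 = 5/17 ~ 0.29 vs unit 1 at 0.2
  cv2 <- (d2^2 / Tg^2) * {
    p <- 1 / (1 + exp(g2 - d2 / Tg)); p * (1 - p)
  }
  r12 <- cooperativity_ratio(heat_capacity_curve(Tg, cv1 + cv2))
  expect_lt(r12$ratio, 1)
  expect_lt(r12$ratio, r1$ratio)   # single unit >= split two-unit system

  # scaling the system's energies (E -> cE, T -> cT) leaves the ratio fixed
  r_scaled <- cooperativity_ratio(heat_capacity_curve(3 * Tg, cv1))
  expect_equal(r_scaled$ratio, r1$ratio, tolerance = 1e-9)
})

test_that("foldedness reproduces the worked exponential-ratio examples", {
  grid <- seq(0.01, 0.99, by = 0.02)
  mk_fep <- function(dg_at_ref, basin = 0.75, ref = 0.81) {
    dG <- 8 * (grid - basin)^2          # folded-basin parabola, min 0 at basin
    dG[abs(grid - ref) < 1e-9] <- dg_at_ref
    dG[grid < 0.5] <- 2 + 8 * (grid[grid < 0.5] - 0.2)^2
    structure(list(rc_grid = grid, dG = dG, variance = rep(0, length(grid)),
                   rc_name = "Q", T_ref = 1), class = "free_energy_profile")
  }
  wt <- mk_fep(0, basin = 0.81)
  expect_equal(foldedness(mk_fep(1.6), wt)$value, 0.202, tolerance = 2e-3)
  expect_equal(foldedness(mk_fep(0.94), wt)$value, 0.390, tolerance = 2e-3)
  expect_equal(foldedness(wt, wt)$value, 1)

  # monotone: higher dG at q_ref means lower foldedness
  vals <- vapply(seq(0.2, 3, by = 0.4),
                 function(g) foldedness(mk_fep(g), wt)$value, 0)
  expect_true(all(diff(vals) < 0))

  # q_ref outside the mutant's populated range is an error
  short <- mk_fep(1.6)
  short$dG[short$rc_grid > 0.7] <- NA
  expect_error(foldedness(short, wt), "outside the populated range")
})

test_that("transition detection matches constructed ground truth", {
  # four full folding/unfolding cycles -> 8 transitions
  sq <- c(rep(c(rep(0.1, 5), rep(0.9, 5)), 4), rep(0.1, 5))
  tt <- detect_transitions(sq)
  expect_equal(nrow(tt), 8L)
  expect_equal(sum(tt$direction == "folding"), 4L)
  expect_equal(sum(tt$direction == "unfolding"), 4L)

  # monotone ramp: exactly one folding transition
  ramp <- detect_transitions(seq(0, 1, length.out = 100))
  expect_equal(nrow(ramp), 1L)
  expect_equal(ramp$direction, "folding")
  # segment spans the barrier crossing: last exit from U to first entry to F
  expect_equal(ramp$start, max(which(seq(0, 1, length.out = 100) < 0.3)))
  expect_equal(ramp$end, min(which(seq(0, 1, length.out = 100) > 0.7)))

  expect_error(detect_transitions(sq, folded_threshold = 1.2), "\\[0, 1\\]")
  expect_error(detect_transitions(sq, folded_threshold = 0.2,
                                  unfolded_threshold = 0.3), "below")

  # noiseless telegraph: planted switch count recovered exactly
  for (seed in 1:3) {
    tg <- make_telegraph_qseries(3000, switch_rate = 0.01, noise = 0, seed = seed)
    expect_equal(nrow(detect_transitions(tg$q)), length(tg$switch_frames))
  }
})

test_that("jackknife variance matches hand enumeration and i.i.d. scaling", {
  expect_equal(jackknife_variance(rep(3.3, 100)), 0)

  # two blocks, all zeros then all ones: delete-one estimates are 1 and 0
  x <- c(rep(0, 50), rep(1, 50))
  expect_equal(jackknife_variance(x, mean, n_blocks = 2), 0.25)

  expect_error(jackknife_variance(1:5, mean, n_blocks = 10), "fewer frames")

  # i.i.d. normal stream: jackknife variance of the mean ~ var/n
  set.seed(23)
  ratio <- replicate(100, {
    z <- rnorm(400)
    jackknife_variance(z, mean, 10) / (var(z) / length(z))
  })
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})
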