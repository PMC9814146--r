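test_that("momentum transfer follows elastic-rescattering kinematics", {
  expect_equal(momentum_transfer(100, 0), 0)
  # closed form 2 * sqrt(2 E / Hartree) evaluated independently
  expect_equal(momentum_transfer(100, 180), 2 * sqrt(2 * 100 / 27.211386),
               tolerance = 1e-12)
  expect_equal(momentum_transfer(100, 180), 5.422127, tolerance = 1e-6)
  # sin(30 deg) = 1/2 makes q equal k
  expect_equal(momentum_transfer(50, 60), sqrt(2 * 50 / 27.211386),
               tolerance = 1e-12)
  expect_error(momentum_transfer(-5, 90), "positive")
  expect_error(momentum_transfer(100, 181), "angle")
})

test_that("screened-Born amplitudes have the documented closed form", {
  am <- amplitude_model()
  expect_equal(atomic_amplitude(am, 1, 0), 2 * 0.88534^2, tolerance = 1e-12)
  expect_equal(atomic_amplitude(am, 1, 1), 2 / (1 + (1 / 0.88534)^2),
               tolerance = 1e-12)
  expect_equal(atomic_amplitude(am, 1, 1), 0.8789, tolerance = 1e-4)
  # strictly decreasing in q, strictly positive
  q <- seq(0, 8, length.out = 50)
  for (z in c(1, 6, 8, 16)) {
    f <- atomic_amplitude(am, z, q)
    expect_true(all(f > 0))
    expect_true(all(diff(f) < 0))
  }
  # Rutherford limit f -> 2Z/q^2 at large q
  expect_equal(atomic_amplitude(am, 6, 500) / (2 * 6 / 500^2), 1,
               tolerance = 1e-3)
  # tabulated provider: multi-Yukawa sum, unknown element errors
  tab <- amplitude_model("tabulated",
                         table = list(`6` = list(A = c(8, 4), b = c(1, 2))))
  expect_equal(atomic_amplitude(tab, 6, 1), 8 / 2 + 4 / 5, tolerance = 1e-12)
  expect_error(atomic_amplitude(tab, 8, 1), "no tabulated")
})

test_that("iam_dcs decomposes into atomic and coherent parts", {
  am <- amplitude_model()
  atom <- molecular_structure("C", t(c(0, 0, 0)))
  r1 <- iam_dcs(atom, am, 100, 90)
  f <- atomic_amplitude(am, 6, momentum_transfer(100, 90))
  expect_equal(r1$sigma_coherent, 0)
  expect_equal(r1$sigma_tot, f^2, tolerance = 1e-12)

  # homonuclear diatomic in the qR -> 0 limit: full coherence, (2f)^2
  h2_tight <- molecular_structure(c("H", "H"),
                                  rbind(c(0, 0, 0), c(0, 0, 1e-7)))
  r2 <- iam_dcs(h2_tight, am, 100, 180)
  fh <- atomic_amplitude(am, 1, momentum_transfer(100, 180))
  expect_equal(r2$sigma_tot, 4 * fh^2, tolerance = 1e-6)

  # H2 at R = 1 A, 100 eV, backscattering: exact pairwise-summation value
  h2 <- molecular_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1)))
  r3 <- iam_dcs(h2, am, 100, 180)
  q <- momentum_transfer(100, 180)
  qr <- q * 1.8897261
  expect_equal(qr, 10.24633, tolerance = 1e-5)
  expect_equal(r3$sigma_tot, 2 * fh^2 * (1 + sin(qr) / qr), tolerance = 1e-12)
  expect_equal(r3$sigma_tot, r3$sigma_atom + r3$sigma_coherent)
})

test_that("dcs_map matches the brute-force pairwise oracle", {
  am <- amplitude_model()
  grid <- tiny_grid(6, 5)
  for (seed in 1:4) {
    s <- random_structure(sample(2:6, 1), seed)
    m <- dcs_map(s, am, grid, components = TRUE)
    oracle <- brute_force_map(s, am, grid)
    expect_equal(m$values, oracle, tolerance = 1e-12)
    expect_equal(m$values, m$atom + m$coherent, tolerance = 1e-12)
    expect_true(all(m$atom > 0))
    expect_true(all(m$values >= 0))
  }
})

test_that("maps depend on structure only through pair distances", {
  am <- amplitude_model()
  grid <- tiny_grid()
  for (seed in 1:4) {
    s <- random_structure(5, seed)
    m0 <- dcs_map(s, am, grid)$values
    rot <- random_rotation(seed + 50)
    moved <- s
    moved$xyz <- sweep(s$xyz %*% rot, 2, -c(0.4, 2, -1))
    m1 <- dcs_map(moved, am, grid)$values
    expect_equal(m1, m0, tolerance = 1e-12)
  }
})

test_that("coherent term oscillates through the sinc zeros and stays bounded", {
  am <- amplitude_model()
  # homonuclear diatomic: sigma_coherent crosses zero where q R = m pi
  h2 <- molecular_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1)))
  r_bohr <- 1.8897261
  q <- seq(0.5, 8, length.out = 2000)
  coh <- vapply(q, function(qq) {
    2 * atomic_amplitude(am, 1, qq)^2 * sin(qq * r_bohr) / (qq * r_bohr)
  }, numeric(1))
  sign_flips <- q[which(diff(sign(coh)) != 0)]
  expected_zeros <- (1:4) * pi / r_bohr
  for (z in expected_zeros[expected_zeros < 8]) {
    expect_true(min(abs(sign_flips - z)) < 0.02)
  }
  # |sigma_coherent| / sigma_atom <= N - 1 everywhere (Cauchy-Schwarz);
  # < 1 for the packaged equilibrium molecules on the default window
  grid <- dcs_grid(seq(50, 300, length.out = 16),
                   seq(30, 180, length.out = 16))
  for (s in list(structure_from_params(scheme_c2h2(), c(1.20, 1.06)),
                 structure_from_params(scheme_cs2(), c(1.55, 180)),
                 fenchone_structure())) {
    m <- dcs_map(s, am, grid, components = TRUE)
    ratio <- abs(m$coherent) / m$atom
    expect_true(all(ratio <= length(s$elements) - 1 + 1e-12))
    expect_lt(max(ratio), 1)
  }
  # envelope decay: the coherent/atomic ratio of a diatomic dies off as qR
  # grows (checked on the 1/(qR) envelope at the sinc extrema)
  env <- abs(coh) / (2 * vapply(q, function(qq) atomic_amplitude(am, 1, qq),
                                numeric(1))^2)
  bound <- 1 / (q * r_bohr)
  expect_true(all(env <= bound + 1e-12))
})

test_that("DCS maps survive a CSV round trip", {
  am <- amplitude_model()
  grid <- tiny_grid(5, 4)
  m <- dcs_map(structure_from_params(scheme_cs2(), c(1.7, 140)), am, grid,
               components = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dcs_csv(m, path)
  back <- read_dcs_csv(path)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  expect_equal(back$atom, m$atom, tolerance = 1e-12)
  expect_equal(back$grid$energies, grid$energies)
})
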