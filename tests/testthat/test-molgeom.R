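test_that("label schemes build the documented geometries", {
  # equilibrium acetylene: linear H-C-C-H along z
  s <- structure_from_params(scheme_c2h2(), c(1.20, 1.06))
  expect_equal(sort(internuclear_distances(s)),
               c(1.06, 1.06, 1.20, 2.26, 2.26, 3.32), tolerance = 1e-12)
  expect_equal(s$elements, c("H", "C", "C", "H"))
  expect_true(all(abs(s$xyz[, 1:2]) < 1e-12))  # linear along +z

  # collinear S-C-S: S-S distance forced to 2 * R_CS
  cs2 <- structure_from_params(scheme_cs2(), c(1.55, 180))
  d <- internuclear_distances(cs2)
  expect_equal(sort(d), c(1.55, 1.55, 3.10), tolerance = 1e-9)

  # bent S-C-S: S-S distance from the chord formula 2 R sin(theta/2)
  bent <- structure_from_params(scheme_cs2(), c(1.87, 104.7))
  ss <- max(internuclear_distances(bent))
  expect_equal(ss, 2 * 1.87 * sin(104.7 / 2 * pi / 180), tolerance = 1e-9)
})

test_that("label vectors round-trip through structures exactly", {
  set.seed(42)
  for (i in 1:20) {
    v <- c(runif(1, 0.9, 1.6), runif(1, 0.8, 1.4))
    expect_equal(structure_labels(scheme_c2h2(),
                                  structure_from_params(scheme_c2h2(), v)),
                 v, tolerance = 1e-9)
    w <- c(runif(1, 1.2, 2.2), runif(1, 90, 180))
    expect_equal(structure_labels(scheme_cs2(),
                                  structure_from_params(scheme_cs2(), w)),
                 w, tolerance = 1e-9)
  }
  base <- random_structure(6, seed = 7)
  sch <- scheme_cartesian(base, tracked_atoms = c(2L, 5L))
  expect_equal(label_dim(sch), 6L)
  v <- rnorm(6)
  rebuilt <- structure_from_params(sch, v)
  expect_equal(structure_labels(sch, rebuilt), v, tolerance = 1e-12)
  # untracked atoms stay at base positions
  expect_equal(rebuilt$xyz[c(1, 3, 4, 6), ], base$xyz[c(1, 3, 4, 6), ])
})

test_that("scheme preconditions are enforced", {
  expect_error(structure_from_params(scheme_c2h2(), c(1.2)), "expected 2")
  expect_error(structure_from_params(scheme_c2h2(), c(-1, 1.06)), "positive")
  expect_error(structure_from_params(scheme_cs2(), c(1.55, 181)), "angle")
  expect_error(scheme_cartesian(random_structure(4, 1), c(1L, 5L)),
               "valid atom indices")
})

test_that("internuclear distances are complete and isometry-invariant", {
  two <- molecular_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(internuclear_distances(two), 1.0)
  expect_length(internuclear_distances(molecular_structure("C", t(c(0, 0, 0)))),
                0L)
  for (seed in 1:5) {
    s <- random_structure(sample(3:7, 1), seed)
    n <- length(s$elements)
    d0 <- internuclear_distances(s)
    expect_length(d0, n * (n - 1) / 2)
    rot <- random_rotation(seed + 100)
    moved <- s
    moved$xyz <- sweep(s$xyz %*% rot, 2, -c(1.3, -0.2, 5))
    expect_equal(internuclear_distances(moved), d0, tolerance = 1e-12)
  }
})

test_that("group deformation obeys its contracts", {
  base <- random_structure(8, seed = 3)
  spec <- deformation_spec("group-deformation",
                           scheme_cartesian(base, 1:3),
                           base_structure = base,
                           groups = list(1:3, 4:5), count = 10, seed = 1)
  # identity arguments leave the structure unchanged
  same <- apply_group_deformation(spec, list(c(0, 0, 0), c(0, 0, 0)), 1)
  expect_equal(same$xyz, base$xyz, tolerance = 1e-12)

  # a pure global scale multiplies every pair distance
  scaled <- apply_group_deformation(spec, list(c(0, 0, 0), c(0, 0, 0)), 1.1)
  expect_equal(internuclear_distances(scaled),
               1.1 * internuclear_distances(base), tolerance = 1e-12)

  # shifting one group rigidly: verified against direct coordinate
  # arithmetic, intra-group distances unchanged
  sh <- c(0, 0, 0.1)
  moved <- apply_group_deformation(spec, list(sh, c(0, 0, 0)), 1)
  manual <- base$xyz
  manual[1:3, 3] <- manual[1:3, 3] + 0.1
  expect_equal(moved$xyz, manual, tolerance = 1e-12)
  d_base <- as.matrix(dist(base$xyz)); d_mov <- as.matrix(dist(moved$xyz))
  expect_equal(d_mov[1:3, 1:3], d_base[1:3, 1:3], tolerance = 1e-12)
  expect_gt(max(abs(d_mov[1:3, 4:8] - d_base[1:3, 4:8])), 1e-3)
  # atoms outside all groups move only via the scale
  spec2 <- deformation_spec("group-deformation",
                            scheme_cartesian(base, 1:3),
                            base_structure = base,
                            groups = list(1:3), count = 10, seed = 1)
  out <- apply_group_deformation(spec2, list(c(0.2, 0, 0)), 1)
  expect_equal(out$xyz[4:8, ], base$xyz[4:8, ], tolerance = 1e-12)

  expect_error(apply_group_deformation(spec, list(sh), 1), "one shift")
  expect_error(apply_group_deformation(spec, list(sh, sh), 0), "positive")
  expect_error(deformation_spec("group-deformation",
                                scheme_cartesian(base, 1:3),
                                base_structure = base,
                                groups = list(1:3, 3:5), count = 5),
               "disjoint")
})

test_that("database generation is deterministic with the declared size", {
  grid_spec <- deformation_spec("parameter-grid", scheme_c2h2(),
    parameters = list(R_CC = list(min = 1.0, max = 1.4, n_steps = 21),
                      R_CH = list(min = 0.86, max = 1.26, n_steps = 21)),
    sampling = "grid")
  db <- generate_database(grid_spec)
  expect_equal(nrow(db$labels), 441L)  # 21 x 21 grid
  expect_length(db$structures, 441L)

  uspec <- deformation_spec("parameter-grid", scheme_c2h2(),
    parameters = list(R_CC = list(min = 1.0, max = 1.4),
                      R_CH = list(min = 0.86, max = 1.26)),
    sampling = "uniform", count = 50, seed = 9)
  u1 <- generate_database(uspec); u2 <- generate_database(uspec)
  expect_identical(u1$labels, u2$labels)
  expect_true(all(u1$labels[, 1] >= 1.0 & u1$labels[, 1] <= 1.4))
  expect_true(all(u1$labels[, 2] >= 0.86 & u1$labels[, 2] <= 1.26))

  base <- random_structure(6, seed = 2)
  gspec <- deformation_spec("group-deformation",
                            scheme_cartesian(base, 1:2),
                            base_structure = base, groups = list(1:2, 3:4),
                            count = 30, shift_range = c(-0.2, 0.2),
                            global_scale = c(0.95, 1.05), seed = 4)
  g1 <- generate_database(gspec); g2 <- generate_database(gspec)
  expect_identical(g1$labels, g2$labels)
  expect_length(g1$structures, 30L)

  expect_error(deformation_spec("parameter-grid", scheme_c2h2(),
                                parameters = list()), "non-empty")
  expect_error(deformation_spec("group-deformation",
                                scheme_cartesian(base, 1:2),
                                base_structure = base, groups = list(1:2),
                                count = 0), "positive count")
})

test_that("XYZ files round-trip and reject malformed input", {
  fen <- fenchone_structure()
  expect_length(fen$elements, 27L)
  expect_equal(sum(fen$elements == "C"), 10L)
  expect_equal(sum(fen$elements == "H"), 16L)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(fen, path)
  back <- read_xyz(path)
  expect_identical(back$elements, fen$elements)
  expect_equal(back$xyz, fen$xyz, tolerance = 1e-6)

  hand <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "hand-written", "O 0.0 0.0 0.0",
               "H 0.9572 0.0 0.0", "H -0.2399872 0.9266272 0.0"), hand)
  w <- read_xyz(hand)
  expect_equal(w$xyz[2, 1], 0.9572)
  expect_equal(w$elements, c("O", "H", "H"))

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "count disagrees", "O 0 0 0", "H 1 0 0"), bad)
  expect_error(read_xyz(bad), "count line")
  expect_error(element_to_z("Xx"), "unknown element")
})

test_that("fenchone groups partition all 27 atoms disjointly", {
  idx <- unname(sort(unlist(fenchone_groups())))
  expect_identical(idx, 1:27)
  expect_true(all(fenchone_tracked() %in% 1:27))
  expect_length(fenchone_tracked(), 7L)
})

test_that("group-deformation maps are nearly degenerate across distinct labels", {
  # the practical identifiability limit of the 4-group + scale family:
  # a parameter set found by least squares can fit a noiseless map to
  # numerical precision while its label vector stays visibly away from
  # the truth
  ns <- asNamespace("dcsnet")
  base <- fenchone_structure()
  scheme <- scheme_cartesian(base, fenchone_tracked())
  groups <- fenchone_groups()
  grid <- dcs_grid(seq(50, 300, length.out = 16),
                   seq(30, 180, length.out = 16))
  am <- amplitude_model()
  ref_norm <- normalize_map(dcs_map(base, am, grid)$values)
  mk <- function(p) {
    s <- ns$deform_structure(base, groups,
                             lapply(1:4, function(g) p[(3 * g - 2):(3 * g)]),
                             1 + p[13])
    ns$center_structure(s)
  }
  map_of <- function(p) {
    as.vector(normalize_map(dcs_map(mk(p), am, grid)$values) - ref_norm)
  }
  set.seed(5)
  truth <- c(runif(12, -0.25, 0.25), runif(1, -0.08, 0.08))
  target <- map_of(truth)
  obj <- function(p) sum((map_of(p) - target)^2)
  set.seed(2)
  p0 <- c(runif(12, -0.25, 0.25), runif(1, -0.08, 0.08))
  opt <- optim(p0, obj, method = "L-BFGS-B",
               lower = c(rep(-0.3, 12), -0.1), upper = c(rep(0.3, 12), 0.1),
               control = list(maxit = 400, factr = 1e4))
  lab_err <- mean(abs(structure_labels(scheme, mk(opt$par)) -
                        structure_labels(scheme, mk(truth))))
  # the fitted map agrees with the target to a fraction of the signal far
  # below any realistic measurement precision, yet the labels disagree by
  # an amount comparable to the target accuracy of the retrieval
  expect_lt(opt$value / sum(target^2), 1e-4)
  expect_gt(lab_err, 0.005)
})
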