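# Shared fixture builders. Everything is generated in code at test time;
# expensive trained models are cached per test run in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tiny_grid <- function(n_e = 8, n_a = 8) {
  dcs_grid(seq(60, 250, length.out = n_e), seq(40, 170, length.out = n_a))
}

# A dcs_map with prescribed values, for prep-module tests that do not care
# about the scattering physics behind the matrix.
map_with_values <- function(values, grid = NULL, name = "fixture") {
  if (is.null(grid)) {
    grid <- dcs_grid(seq(50, 300, length.out = nrow(values)),
                     seq(30, 180, length.out = ncol(values)))
  }
  structure(list(grid = grid, values = values, atom = NULL, coherent = NULL,
                 structure_name = name), class = "dcs_map")
}

random_structure <- function(n_atoms, seed,
                             elements = c("H", "C", "O", "S")) {
  set.seed(seed)
  molecular_structure(sample(elements, n_atoms, replace = TRUE),
                      matrix(stats::runif(n_atoms * 3, -2, 2), n_atoms, 3),
                      name = paste0("random", seed))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Independent brute-force IAM oracle: plain loops over pixels and ordered
# atom pairs, no shared code with dcs_map()'s vectorized path.
brute_force_map <- function(structure, model, grid) {
  nE <- length(grid$energies); nA <- length(grid$angles)
  out <- matrix(0, nE, nA)
  n <- length(structure$elements)
  for (e in seq_len(nE)) {
    for (a in seq_len(nA)) {
      k <- sqrt(2 * grid$energies[e] / 27.211386)
      q <- 2 * k * sin(grid$angles[a] / 2 * pi / 180)
      f <- vapply(structure$Z, function(z) atomic_amplitude(model, z, q),
                  numeric(1))
      tot <- 0
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i == j) {
            tot <- tot + f[i]^2
          } else {
            r <- sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2)) *
              1.8897261
            x <- q * r
            tot <- tot + f[i] * f[j] * (if (x == 0) 1 else sin(x) / x)
          }
        }
      }
      out[e, a] <- tot
    }
  }
  out
}

# Small trained C2H2 model on 16x16 maps for tests that need a working
# regressor but not the full acceptance-scale run.
tiny_c2h2_fit <- function() {
  cached("tiny_c2h2_fit", function() {
    spec <- deformation_spec("parameter-grid", scheme_c2h2(),
      parameters = list(R_CC = list(min = 1.00, max = 1.40),
                        R_CH = list(min = 0.86, max = 1.26)),
      sampling = "uniform", count = 400, seed = 11)
    db <- generate_database(spec)
    grid <- dcs_grid(seq(50, 300, length.out = 16),
                     seq(30, 180, length.out = 16))
    am <- amplitude_model()
    ref <- structure_from_params(scheme_c2h2(), c(1.20, 1.06))
    ds <- assemble_dataset(db, ref, grid, am, seed = 5)
    cfg <- cnn_config(conv_layers = list(c(8, 3), c(8, 3)), fc_depth = 2,
                      fc_width = 32, batch_size = 64, learning_rate = 2e-3,
                      epochs = 40, optimizer = "adam", seed = 3)
    mod <- build_model(cfg, c(16, 16), 2)
    fit <- train_cnn(mod, ds, cfg)
    list(fit = fit, dataset = ds, grid = grid, model = am, ref = ref,
         spec = spec)
  })
}
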