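test_that("a fixed seed reproduces the table byte-identically", {
  cfg <- generator_config(seed = 101)
  t1 <- generate_trait_table(cfg)
  t2 <- generate_trait_table(cfg)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_results(t1, f1); write_results(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the generator does not disturb the session RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_trait_table(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("fully tolerant genotypes at zero noise retain control values", {
  cfg <- generator_config(n_genotypes = 3, latent_tolerance = c(1, 1, 1),
                          noise_cv = 0, seed = 5)
  tab <- generate_trait_table(cfg)
  crc <- build_resistance_matrix(tab)
  expect_equal(unname(crc), matrix(100, 3, 4))
})

test_that("higher latent tolerance gives uniformly higher CRC at zero noise", {
  cfg <- generator_config(n_genotypes = 2, latent_tolerance = c(0.9, 0.1),
                          noise_cv = 0, seed = 5)
  tab <- generate_trait_table(cfg)
  crc <- build_resistance_matrix(tab)
  expect_true(all(crc["G01", ] > crc["G02", ]))
})

test_that("zero-growth phenotype is reachable with the linear family", {
  cfg <- generator_config(
    n_genotypes = 2, latent_tolerance = c(0, 1), noise_cv = 0,
    dose_response = "linear",
    traits = data.frame(label = "area", control_mean = 4, control_cv = 0,
                        sensitivity = 1, direction = "higher"),
    seed = 5)
  crc <- build_resistance_matrix(generate_trait_table(cfg))
  expect_equal(unname(crc["G01", ]), rep(0, 4))  # clipped at every dose
  expect_equal(unname(crc["G02", ]), rep(100, 4))
})

test_that("default-condition screen recovers the planted ranking well", {
  tab <- generate_trait_table(generator_config(seed = 1))
  tol <- attr(tab, "latent_tolerance")
  ev <- evaluate(tab, mode = "unweighted")
  rho <- cor(ev$scores$d, tol[ev$scores$genotype], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("ranking recovery degrades monotonically with replicate noise", {
  noise <- c(0, 0.05, 0.2, 0.5)
  mean_rho <- vapply(noise, function(cv) {
    rho <- vapply(1:100, function(s) {
      tab <- generate_trait_table(generator_config(noise_cv = cv, seed = s))
      tol <- attr(tab, "latent_tolerance")
      ev <- evaluate(tab, mode = "unweighted")
      cor(ev$scores$d, tol[ev$scores$genotype], method = "spearman")
    }, numeric(1))
    mean(rho)
  }, numeric(1))
  expect_equal(mean_rho[1], 1)            # exact recovery without noise
  expect_true(all(diff(mean_rho) <= 0))   # non-increasing trend
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_genotypes = 3,
                                latent_tolerance = c(0.5, 1.2, 0)),
               "latent_tolerance")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(stress_levels = c(0, 2)), "stress")
  expect_error(generator_config(n_replicates = 0), "n_replicates")
  expect_error(generate_trait_table(list(seed = 1)), "generator_config")
})

test_that("packaged fixtures carry the printed worked examples", {
  t1 <- load_fixture("table1_strain_D")
  expect_equal(nrow(t1), 10)
  expect_equal(t1$strain[1], "JaCg205")
  expect_equal(t1$D[1], 0.935)
  expect_equal(sum(t1$D == 0), 4)

  t2 <- load_fixture("table2_seedling_eval")
  expect_equal(dim(t2$F), c(4, 3))
  expect_equal(unname(t2$weights), c(0.455, 0.317, 0.228))
  expect_equal(unname(t2$D), c(0.894, 0.539, 0.411, 0.189))

  t3 <- load_fixture("table3_association")
  expect_equal(t3$r, -0.923)
  expect_equal(t3$p, 0.077)
  expect_equal(t3$pairs$genotype, rownames(t2$F))
  expect_error(load_fixture("nope"))
})
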