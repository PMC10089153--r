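test_that("synthetic affine fields realize their specification", {
  f <- gen_affine_field(mixture_spec(c(translation = 1), n_points = 300,
                                    seed = 1))
  expect_equal(polarization(f), 1)

  fr <- gen_affine_field(mixture_spec(c(rotation = 1), n_points = 300,
                                      seed = 2))
  expect_equal(unified_order(fr)$O, 1, tolerance = 1e-3)

  # pure noise: the affine fit is near-identity and eta* is near 1
  fn <- gen_affine_field(mixture_spec(c(translation = 1), noise_power = 1,
                                      n_points = 2000, seed = 3))
  fl <- fluctuations(fn$positions, fn$positions + fn$velocities, dt = 1)
  expect_equal(fl$eta_star, 1, tolerance = 3 / sqrt(2000))
  expect_lt(abs(fl$fit$angle), 0.01)
  expect_equal(fl$fit$scale, 1, tolerance = 0.01)

  # generators are pure functions of spec + seed
  spec <- mixture_spec(c(rotation = 0.5, expansion = 0.5), noise_power = 0.2,
                       n_points = 100, seed = 9)
  expect_identical(gen_affine_field(spec), gen_affine_field(spec))

  expect_error(mixture_spec(c(translation = -1)), "invalid weights")
  expect_error(mixture_spec(c(bogus = 1)), "unknown weight")
  expect_error(mixture_spec(c(translation = 1), noise_power = 1.2),
               "noise_power")
})

test_that("measured noise power converges to the specified fraction", {
  for (p in c(0.2, 0.6)) {
    f <- gen_affine_field(mixture_spec(c(translation = 0.6, rotation = 0.4),
                                       noise_power = p, n_points = 10000,
                                       seed = 50 + 10 * p))
    fl <- fluctuations(f$positions, f$positions + f$velocities * 0.5,
                       dt = 0.5)
    expect_equal(fl$eta_star, p, tolerance = 0.05 * max(p, 0.5))
  }
})

test_that("equivalent diameter and area filtering follow their definitions", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(4 * pi), 4)
  expect_equal(equivalent_diameter(1), 2 / sqrt(pi))
  expect_error(equivalent_diameter(0), "area")

  expect_equal(area_filter(c(100, 85, 79), 0.8), c(1L, 2L))
  expect_equal(area_filter(rep(7, 5)), 1:5)
  expect_equal(area_filter(c(10, 9, 10), 1), c(1L, 3L))
  expect_error(area_filter(numeric(0)), "empty")
})

test_that("edge exclusion removes a boundary band of the footprint", {
  f <- gen_affine_field(mixture_spec(c(translation = 1), n_points = 2000,
                                     radius = 10, seed = 4))
  kept <- edge_exclusion(f, fraction = 0.1)
  r_kept <- sqrt(rowSums(kept$positions^2))
  r_all <- sqrt(rowSums(f$positions^2))
  # disc of radius 10: diameter 20, band width 2 (64-gon approximation)
  expect_lt(max(r_kept), 8.05)
  expect_gt(sum(r_all > 8.05), 0)
  expect_true(nrow(kept$positions) < nrow(f$positions))

  expect_identical(edge_exclusion(f, 0), f)
  expect_warning(empty <- edge_exclusion(f, 0.49), "every entry")
  expect_equal(nrow(empty$positions), 0)

  nofp <- velocity_field(f$positions, f$velocities)
  expect_error(edge_exclusion(nofp), "footprint")
})

test_that("field TSV round-trips losslessly with metadata", {
  fields <- list(
    gen_affine_field(mixture_spec(c(translation = 1), noise_power = 0.3,
                                  n_points = 100, seed = 5)),
    gen_affine_field(mixture_spec(c(rotation = 1), noise_power = 0.1,
                                  n_points = 100, seed = 6)))
  fields[[1]]$time <- 0
  fields[[2]]$time <- 0.5
  path <- file.path(tempdir(), "field.tsv")
  write_field(fields, path, units = "um")
  back <- read_field(path)
  expect_equal(attr(back, "units"), "um")
  expect_length(back, 2)
  for (i in 1:2) {
    expect_identical(back[[i]]$positions, fields[[i]]$positions)
    expect_identical(back[[i]]$velocities, fields[[i]]$velocities)
    expect_equal(back[[i]]$time, fields[[i]]$time)
  }
  expect_equal(back[[1]]$footprint, fields[[1]]$footprint)

  # missing column reported by name
  tab <- read.delim(path)
  tab$vy <- NULL
  path2 <- file.path(tempdir(), "broken.tsv")
  write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(paste0(path, ".json"), paste0(path2, ".json"), overwrite = TRUE)
  expect_error(read_field(path2), "vy")

  # shuffled row order is regrouped identically
  tab <- read.delim(path)
  set.seed(7)
  shuf <- tab[sample(nrow(tab)), ]
  path3 <- file.path(tempdir(), "shuffled.tsv")
  write.table(shuf, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(paste0(path, ".json"), paste0(path3, ".json"), overwrite = TRUE)
  back3 <- read_field(path3)
  expect_equal(back3[[1]]$positions, back[[1]]$positions)
  expect_equal(back3[[2]]$velocities, back[[2]]$velocities)

  # sidecar is mandatory
  file.remove(paste0(path, ".json"))
  expect_error(read_field(path), "sidecar")
})

test_that("the command-line interface drives fixtures, analysis and simulation", {
  td <- tempdir()
  spec_json <- file.path(td, "spec.json")
  jsonlite::write_json(list(weights = list(rotation = 1), noise_power = 0.2,
                            n_points = 150, seed = 3),
                       spec_json, auto_unbox = TRUE)
  field_tsv <- file.path(td, "cli_field.tsv")
  expect_equal(run_cli(c("fixtures", "--spec", spec_json,
                         "--out", field_tsv)), 0L)
  expect_true(file.exists(field_tsv))

  order_tsv <- file.path(td, "cli_order.tsv")
  run_cli(c("analyze", "order", "--in", field_tsv, "--out", order_tsv))
  ord <- read.delim(order_tsv)
  expect_equal(names(ord), c("frame", "time", "P", "R", "Delta", "O"))
  f <- read_field(field_tsv)[[1]]
  expect_equal(ord$O, unified_order(f)$O)

  cfg_json <- file.path(td, "sim.json")
  jsonlite::write_json(list(k = 2, n_particles = 50, n_steps = 200,
                            burn_in = 100, sample_every = 50, seed = 4),
                       cfg_json, auto_unbox = TRUE)
  run_tsv <- file.path(td, "cli_run.tsv")
  expect_equal(run_cli(c("simulate", "--config", cfg_json,
                         "--out", run_tsv)), 0L)
  tab <- read.delim(run_tsv)
  expect_equal(unique(tab$frame), 1:2)
  expect_equal(sum(tab$frame == 1), 50)
  expect_true(file.exists(paste0(run_tsv, ".json")))

  expect_equal(run_cli("no-such-command"), 1L)
})

test_that("the fit subcommand runs finite-size regressions on a sweep table", {
  td <- tempdir()
  set.seed(12)
  sizes <- rep(c(100, 400, 1600, 6400), each = 3)
  sw <- data.frame(k = 3.5, n_particles = sizes, replicate = rep(1:3, 4),
                   mean_O = 0.9 - 0.05 * log(sizes) + rnorm(12, sd = 0.002),
                   chi = 0.2 * sqrt(sheet_diameter(sizes)) +
                     rnorm(12, sd = 0.002),
                   o_prime = -0.2 * log(sizes) + rnorm(12, sd = 0.01),
                   diameter = sheet_diameter(sizes))
  sweep_tsv <- file.path(td, "sweep.tsv")
  write.table(sw, sweep_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out_json <- file.path(td, "fits.json")
  expect_equal(run_cli(c("fit", "order-size", "--in", sweep_tsv,
                         "--out", out_json)), 0L)
  fit <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p, 0.05)

  run_cli(c("fit", "steepness", "--in", sweep_tsv, "--out", out_json))
  st <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(st$b, -0.2, tolerance = 0.05)

  run_cli(c("fit", "chi-scaling", "--in", sweep_tsv, "--out", out_json))
  cs <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(cs$beta, 0.5, tolerance = 0.1)
  expect_true(cs$sublinear)
})
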