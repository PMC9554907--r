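test_that("Fourier filter preserves constants, passes low bands, damps noise", {
  expect_equal(fourier_filter(rep(3.2, 40), 5), rep(3.2, 40))
  n <- 128
  t <- seq_len(n) - 1
  wave <- 2 + cos(2 * pi * 4 * t / n + 0.3)
  expect_equal(fourier_filter(wave, 4), wave, tolerance = 1e-9)
  expect_equal(fourier_filter(wave, 10), wave, tolerance = 1e-9)
  set.seed(1)
  noise <- rnorm(n)
  sm <- fourier_filter(noise, 8)
  expect_lt(stats::var(sm), stats::var(noise))
  expect_equal(mean(sm), mean(noise), tolerance = 1e-12)
  expect_error(fourier_filter(noise, 0), "1 <= m")
  expect_error(fourier_filter(noise, 65), "1 <= m")
})

test_that("s_spher recovers analytic per-lipid areas on the static vesicle", {
  dir <- withr::local_tempdir()
  ves <- gen_vesicle(r_outer = 7, r_inner = 5, n_up = 600, n_down = 400,
                     n_frames = 2, drift = 0, seed = 17)
  pdb <- file.path(dir, "ves.pdb"); ndx <- file.path(dir, "ves.ndx")
  write_structure(ves$frames, pdb)
  write_index(ves$index, ndx)
  out <- file.path(dir, "spher")
  status <- cli(c("s_spher", "-f", pdb, "-n", ndx, "-up", "up", "-down", "down",
                  "-bin", "24", "-o", out))
  expect_equal(status, 0L)
  up <- read_series(paste0(out, "_up.dat"))
  expect_equal(nrow(up), 2)
  expect_equal(up$A_L, rep(4 * pi * 49 / 600, 2), tolerance = 0.02)
  down <- read_series(paste0(out, "_down.dat"))
  expect_equal(down$A_L, rep(4 * pi * 25 / 400, 2), tolerance = 0.02)
  expect_equal(up$psi_g, rep(1, 2), tolerance = 0.01)
})

test_that("s_shell and s_densph run the leaflet-pair pipeline", {
  dir <- withr::local_tempdir()
  ves <- gen_vesicle(r_outer = 7, r_inner = 5, n_up = 600, n_down = 400,
                     n_frames = 2, drift = 0, seed = 18)
  pdb <- file.path(dir, "ves.pdb"); ndx <- file.path(dir, "ves.ndx")
  write_structure(ves$frames, pdb)
  write_index(ves$index, ndx)
  out <- file.path(dir, "shell")
  status <- cli(c("s_shell", "-f", pdb, "-n", ndx, "-up", "up", "-down", "down",
                  "-bin", "24", "-o", out, "-map", file.path(dir, "map.pdb")))
  expect_equal(status, 0L)
  sh <- read_series(paste0(out, ".dat"))
  expect_equal(sh$D_HH, rep(2, 2), tolerance = 0.02)
  expect_equal(sh$V_L, rep(4 / 3 * pi * (343 - 125) / 1000, 2), tolerance = 0.03)
  expect_true(file.exists(file.path(dir, "map.pdb")))
  status <- cli(c("s_densph", "-f", pdb, "-n", ndx, "-up", "up", "-down", "down",
                  "-sel", "up,down", "-bin", "24", "-kinf", "0.5", "-ksup", "1.5",
                  "-nbins", "20", "-o", file.path(dir, "dens")))
  expect_equal(status, 0L)
  dup <- read_series(file.path(dir, "dens_up.dat"))
  # outer leaflet sits near k = 7/6 of the mid-surface
  expect_equal(dup$time[which.max(dup$density)], 7 / 6, tolerance = 0.05)
})

test_that("s_bend, s_inertia and s_filter produce the expected outputs", {
  dir <- withr::local_tempdir()
  ves <- gen_vesicle(r_outer = 7, r_inner = 5, n_up = 800, n_down = 500,
                     n_frames = 1, drift = 0, seed = 19)
  pdb <- file.path(dir, "ves.pdb"); ndx <- file.path(dir, "ves.ndx")
  write_structure(ves$frames, pdb)
  write_index(ves$index, ndx)
  expect_equal(cli(c("s_bend", "-f", pdb, "-n", ndx, "-up", "up", "-bin", "24",
                     "-o", file.path(dir, "bend"),
                     "-map", file.path(dir, "bendmap.pdb"))), 0L)
  bend <- read_series(file.path(dir, "bend.dat"))
  # the center is estimated from the finite cloud here, so the fitted
  # radius is not exactly constant; the exact-center limit is tested in
  # test-acceptance.R
  expect_equal(bend$S_C, 1, tolerance = 1e-2)
  expect_equal(cli(c("s_inertia", "-f", pdb, "-n", ndx, "-up", "up",
                     "-bin", "24", "-o", file.path(dir, "inertia"))), 0L)
  ine <- read_series(file.path(dir, "inertia.dat"))
  expect_equal(ine$round2, 1, tolerance = 0.05)
  # filter a noisy series file end to end
  ts <- file.path(dir, "series.dat")
  set.seed(2)
  write_series(0:99, list(y = sin(2 * pi * (0:99) / 50) + rnorm(100, 0, 0.3)), ts)
  expect_equal(cli(c("s_filter", "-f", ts, "-m", "5",
                     "-o", file.path(dir, "smooth.dat"))), 0L)
  sm <- read_series(file.path(dir, "smooth.dat"))
  expect_equal(nrow(sm), 100)
  expect_lt(stats::var(sm$y - sin(2 * pi * (0:99) / 50)), 0.3^2)
})

test_that("s_pore and fixtures subcommands work end to end", {
  dir <- withr::local_tempdir()
  expect_equal(cli(c("fixtures", "-type", "porous", "-cavity", "0.65",
                     "-o", file.path(dir, "cell"))), 0L)
  expect_true(file.exists(file.path(dir, "cell.pdb")))
  expect_equal(cli(c("s_pore", "-f", file.path(dir, "cell.pdb"),
                     "-N", "20000", "-seed", "4", "-bin", "16",
                     "-o", file.path(dir, "pore.dat"))), 0L)
  lines <- readLines(file.path(dir, "pore.dat"))
  vals <- as.numeric(strsplit(trimws(lines[length(lines)]), "\\s+")[[1]])
  truth <- jsonlite::read_json(file.path(dir, "cell_truth.json"))
  nm <- strsplit(trimws(sub("^#", "", lines[2])), "\\s+")[[1]]
  theta <- vals[match("theta_Gm", nm)]
  expect_lt(abs(theta - truth$theta_half_vdw), 0.02)
})

test_that("usage errors exit with a distinct nonzero status", {
  expect_equal(cli(c("no_such_subcommand")), 2L)
  expect_equal(cli(character(0)), 2L)
  dir <- withr::local_tempdir()
  ves <- gen_vesicle(n_up = 50, n_down = 40, seed = 1)
  pdb <- file.path(dir, "v.pdb"); ndx <- file.path(dir, "v.ndx")
  write_structure(ves$frames, pdb)
  write_index(ves$index, ndx)
  expect_equal(cli(c("s_shell", "-f", pdb, "-n", ndx, "-up", "up")), 2L)
  expect_equal(cli(c("s_spher", "-f", file.path(dir, "missing.pdb"),
                     "-n", ndx, "-up", "up")), 1L)
})

test_that("re-running a subcommand with identical inputs is byte-identical", {
  dir <- withr::local_tempdir()
  ves <- gen_vesicle(n_up = 300, n_down = 200, n_frames = 2, seed = 23)
  pdb <- file.path(dir, "v.pdb"); ndx <- file.path(dir, "v.ndx")
  write_structure(ves$frames, pdb)
  write_index(ves$index, ndx)
  f1 <- file.path(dir, "a"); f2 <- file.path(dir, "b")
  cli(c("s_spher", "-f", pdb, "-n", ndx, "-up", "up", "-bin", "20", "-o", f1))
  cli(c("s_spher", "-f", pdb, "-n", ndx, "-up", "up", "-bin", "20", "-o", f2))
  expect_identical(readLines(paste0(f1, "_up.dat")),
                   readLines(paste0(f2, "_up.dat")))
})
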