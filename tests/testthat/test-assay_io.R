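test_that("trace tables are grouped, sorted and duplicate-collapsed on read", {
  p <- write_trace_csv(c("a,1,30,2.0", "a,1,25,1.0", "a,1,35,3.0", "a,1,28,1.5"))
  tab <- read_trace_table(p, schema = "melt", min_points = 1)
  expect_s3_class(tab, "trace_table")
  expect_equal(tab$x, c(25, 28, 30, 35))
  expect_equal(tab$y, c(1.0, 1.5, 2.0, 3.0))
  expect_identical(attr(tab, "condition_unit"), "C_per_min")

  # duplicate x collapses to the mean y
  p2 <- write_trace_csv(c("a,1,25.0,1", "a,1,25.0,3", "a,1,26,5", "a,1,27,6"))
  tab2 <- read_trace_table(p2, min_points = 1)
  expect_equal(tab2$y[tab2$x == 25.0], 2)
  expect_equal(nrow(tab2), 3)
})

test_that("undersized groups and malformed trace files are rejected by name", {
  five <- sprintf("small,2,%d,%d", 20:24, 1:5)
  err <- expect_error(read_trace_table(write_trace_csv(five)),
                      class = "sk_format_error")
  expect_match(conditionMessage(err), "small")

  p <- tempfile(fileext = ".csv")
  writeLines(c("sample,condition,y", "a,1,2"), p)
  err2 <- expect_error(read_trace_table(p), class = "sk_format_error")
  expect_match(conditionMessage(err2), "x")
})

test_that("trace tables round-trip through write and read exactly", {
  sch <- calibrate_melt_scheme(280, 58.6, 1)
  s <- simulate_melt(sch, 2, t_range_C = c(45, 75), step_C = 0.5,
                     noise = noise_model(mult = 0.01, seed = 42))
  tab <- structure(
    data.frame(sample = "wt", condition = 2,
               x = s$trace$temperature_C, y = s$trace$signal),
    condition_unit = "C_per_min", schema = "melt",
    class = c("trace_table", "data.frame"))
  p <- tempfile(fileext = ".csv")
  write_trace_table(tab, p)
  back <- read_trace_table(p, schema = "melt")
  expect_identical(back$sample, tab$sample)
  expect_identical(back$x, tab$x)
  expect_identical(back$y, tab$y)
  expect_identical(attr(back, "condition_unit"), "C_per_min")
})

test_that("spectra are sorted and negatives clipped with a warning", {
  p <- write_spectrum_csv(c(300, 340, 400), c(1, 2, 1))
  sp <- read_spectrum(p)
  expect_equal(sp$wavelength, c(300, 340, 400))
  expect_equal(sp$intensity, c(1, 2, 1))

  p2 <- write_spectrum_csv(c(400, 300, 340), c(1, 1, 2))
  sp2 <- read_spectrum(p2)
  expect_equal(sp2$wavelength, c(300, 340, 400))

  p3 <- write_spectrum_csv(c(300, 340, 400), c(1, -0.2, 1))
  w <- expect_warning(read_spectrum(p3), class = "sk_clip_warning")
  expect_match(conditionMessage(w), "1 negative")
  suppressWarnings(sp3 <- read_spectrum(p3))
  expect_equal(sp3$intensity[2], 0)

  p4 <- write_spectrum_csv(c(300, 340), c(1, 1))
  expect_error(read_spectrum(p4), class = "sk_format_error")
})

test_that("per-residue B extraction averages heavy atoms and honours altlocs", {
  p <- toy_three_residue_pdb()
  m <- read_structure_b(p, "all_heavy")
  expect_equal(m$value, c(10, 20, 30))
  expect_equal(m$resno, 1:3)
  # one CA per residue with the residue B: identical map
  mca <- read_structure_b(p, "calpha")
  expect_equal(mca$value, m$value)

  # altloc: atom contributes once via its highest-occupancy conformer
  lines <- c(pdb_atom_line(1, "CA", 1, b = 10, occ = 0.7, alt = "A"),
             pdb_atom_line(2, "CA", 1, b = 50, occ = 0.3, alt = "B"),
             pdb_atom_line(3, "CA", 2, b = 20),
             pdb_atom_line(4, "CA", 3, b = 30))
  malt <- read_structure_b(write_pdb(lines), "all_heavy")
  expect_equal(malt$value, c(10, 20, 30))

  # invariant to atom-record order within a residue
  msh <- read_structure_b(write_pdb(lines[c(2, 4, 1, 3)]), "all_heavy")
  expect_equal(msh$value, malt$value)

  # waters / hetero groups excluded entirely
  het <- sub("^ATOM  ", "HETATM", pdb_atom_line(9, "O", 99, b = 99,
                                                resname = "HOH"))
  mhet <- read_structure_b(write_pdb(c(lines, het)), "all_heavy")
  expect_equal(nrow(mhet), 3)
})

test_that("run configuration rejects unknown keys and resolves paths", {
  cfg <- run_config(seed = 1L, out_dir = ".")
  expect_true(grepl("^/", cfg$out_dir))
  expect_error(run_config(seeed = 1), class = "sk_config_error")
})

test_that("fit reports serialize parameters and convergence to JSON", {
  tab <- aat_tm_table()
  m <- subset(tab, variant == "M")
  ea <- ramp_rate_activation_energy(
    build_ramp_series(m$v_C_per_min, m$tm_C, m$tm_se_C, "M"))
  p <- tempfile(fileext = ".json")
  write_fit_report(ea, p)
  rep <- jsonlite::read_json(p)
  expect_equal(rep$parameters$ea_kJ_mol, ea$ea_kJ_mol, tolerance = 1e-12)
  expect_equal(rep$n, 4L)
  expect_true(rep$converged)
})
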