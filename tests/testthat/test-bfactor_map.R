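toy_map <- function(values, lineage = "raw") {
  residue_b_map(data.frame(chain = "A", resno = seq_along(values),
                           icode = "", value = values),
                lineage = lineage, source = "toy")
}

test_that("z-normalization standardizes, is idempotent, and rejects degenerate maps", {
  z <- znorm(toy_map(c(10, 20, 30)))
  expect_equal(z$value, c(-1, 0, 1))           # mean 20, sample SD 10
  expect_equal(mean(z$value), 0, tolerance = 1e-12)
  expect_equal(sd(z$value), 1, tolerance = 1e-12)
  z2 <- znorm(z)
  expect_equal(z2$value, z$value, tolerance = 1e-12)
  expect_error(znorm(toy_map(c(5, 5, 5))), class = "sk_degenerate_input")
  expect_error(znorm(toy_map(c(1, 2))), class = "sk_insufficient_data")
})

test_that("averaging restricts to the common residues and reports the dropped ones", {
  a <- toy_map(c(-1, 1), "znorm")
  b <- toy_map(c(1, -1), "znorm")
  av <- average_maps(list(a, b))
  expect_equal(av$value, c(0, 0))
  expect_identical(average_maps(list(a, a))$value, a$value)

  c3 <- residue_b_map(data.frame(chain = "A", resno = 1:3, icode = "",
                                 value = c(1, 2, 3)), "znorm")
  c4 <- residue_b_map(data.frame(chain = "A", resno = 2:4, icode = "",
                                 value = c(4, 5, 6)), "znorm")
  av2 <- average_maps(list(c3, c4))
  expect_equal(av2$resno, c(2, 3))
  expect_setequal(attr(av2, "dropped"), c("A|1|", "A|4|"))

  far <- residue_b_map(data.frame(chain = "B", resno = 9:11, icode = "",
                                  value = 1:3), "znorm")
  expect_error(average_maps(list(c3, far)), class = "sk_empty_intersection")
})

test_that("difference maps are anti-symmetric and consistent between modes", {
  a <- toy_map(c(0, 0, 0, 0, 2), "znorm")
  b <- toy_map(c(0, 0, 0, 0, 0), "znorm")
  d <- diff_maps(a, b, "signed")
  expect_equal(d$value, c(0, 0, 0, 0, 2))
  expect_equal(diff_maps(b, a, "signed")$value, -d$value)
  expect_equal(diff_maps(a, b, "absolute")$value, abs(d$value))
  expect_equal(diff_maps(a, a, "signed")$value, rep(0, 5))
  expect_error(diff_maps(a, toy_map(1:5, "raw")), class = "sk_lineage_error")
})

test_that("min-max rescaling attains both endpoints and is shift-invariant", {
  m <- minmax01(toy_map(c(0.5, 1.0, 1.5)))
  expect_equal(m$value, c(0, 0.5, 1))
  m2 <- minmax01(toy_map(c(-10.5, -10.0, -9.5)))
  expect_equal(m2$value, c(0, 0.5, 1))
  already <- minmax01(toy_map(c(0, 0.5, 1)))
  expect_equal(already$value, c(0, 0.5, 1))
  expect_error(minmax01(toy_map(c(2, 2, 2))), class = "sk_degenerate_input")
})

test_that("an injected B inflation is recovered as the top of the difference map", {
  d <- tempfile(); dir.create(d)
  a <- file.path(d, "ref.pdb"); b <- file.path(d, "pert.pdb")
  region <- 18:24
  make_toy_structures(a, b, n_res = 40, region = region, delta_z = 2,
                      seed = 101)
  za <- znorm(read_structure_b(a))
  zb <- znorm(read_structure_b(b))
  dm <- minmax01(diff_maps(zb, za, "absolute"))
  top <- dm$resno[order(-dm$value)][seq_along(region)]
  expect_setequal(top, region)
  expect_equal(max(dm$value), 1)
  expect_equal(min(dm$value), 0)

  # identical structure pair gives an all-zero difference map
  same <- diff_maps(za, za, "signed")
  expect_true(all(same$value == 0))
})

test_that("B column write-back round-trips through the reader", {
  d <- tempfile(); dir.create(d)
  a <- file.path(d, "ref.pdb")
  make_toy_structures(a, file.path(d, "unused.pdb"), n_res = 12,
                      region = 3:5, seed = 3)
  map <- residue_b_map(data.frame(chain = "A", resno = 1:12, icode = "",
                                  value = seq(0.05, 123.456, length.out = 12)))
  out <- file.path(d, "colored.pdb")
  res <- write_bfactor_column(a, map, out)
  expect_length(res$unmapped, 0)
  back <- read_structure_b(out)
  expect_equal(back$value, round(map$value, 2), tolerance = 1e-9)
  # formatting rule: %6.2f
  ln <- grep("^ATOM", readLines(out), value = TRUE)[45]   # residue 12
  expect_identical(substr(ln, 61, 66), "123.46")

  # residues absent from the map fall back to 0.00 and are reported
  part <- residue_b_map(data.frame(chain = "A", resno = 1:6, icode = "",
                                   value = 1:6))
  res2 <- write_bfactor_column(a, part, out)
  expect_setequal(res2$unmapped, paste0("A|", 7:12, "|"))
  back2 <- read_structure_b(out)
  expect_equal(back2$value[7:12], rep(0, 6))
})
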