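test_that("the same seed reproduces a paired screen byte-identically", {
  cfg <- synthetic_screen_config(n_ligands = 15, seed = 99)
  d1a <- tempfile(); d1b <- tempfile()
  d2a <- tempfile(); d2b <- tempfile()
  g1 <- generate_paired_screen(cfg, d1a, d1b)
  g2 <- generate_paired_screen(cfg, d2a, d2b)
  expect_equal(g1$truth, g2$truth)
  for (f in list.files(d1a)) {
    expect_identical(readLines(file.path(d1a, f)), readLines(file.path(d2a, f)))
  }
  for (f in list.files(d1b)) {
    expect_identical(readLines(file.path(d1b, f)), readLines(file.path(d2b, f)))
  }
  # and the files re-read to the in-memory screens
  back <- read_screen(d1a)
  expect_equal(names(back), names(g1$screen_a))
  expect_equal(back[[3]]$modes$affinity, g1$screen_a[[3]]$modes$affinity)
})

test_that("ligand substreams are stable when the screen grows", {
  small <- generate_paired_screen(synthetic_screen_config(n_ligands = 10, seed = 3))
  large <- generate_paired_screen(synthetic_screen_config(n_ligands = 25, seed = 3))
  expect_equal(large$truth[1:10, ], small$truth)
  expect_equal(large$screen_a[[7]]$modes, small$screen_a[[7]]$modes)
})

test_that("degenerate class fractions plant a single label throughout", {
  cfg <- synthetic_screen_config(
    n_ligands = 40, seed = 11,
    class_fractions = c(A_selective = 1, B_selective = 0, nonselective = 0)
  )
  g <- generate_paired_screen(cfg)
  rec <- pair_screens(g$screen_a, g$screen_b)
  expect_true(all(rec$label == "A_selective"))
})

test_that("planted labels and signed deltas are recovered exactly", {
  g <- generate_paired_screen(synthetic_screen_config(n_ligands = 500, seed = 23))
  rec <- pair_screens(g$screen_a, g$screen_b)
  truth <- g$truth[match(rec$ligand_id, g$truth$ligand_id), ]
  expect_equal(rec$label, truth$class)
  expect_equal(rec$s_signed, truth$s_signed)
  # planted sign always matches the planted class
  expect_true(all(truth$s_signed[truth$class == "A_selective"] < -0.1))
  expect_true(all(truth$s_signed[truth$class == "B_selective"] > 0.1))
  expect_true(all(abs(truth$s_signed[truth$class == "nonselective"]) <= 0.1))
  # mode lists honor the Vina rank convention
  for (l in g$screen_a[1:20]) {
    expect_true(all(diff(l$modes$affinity) >= 0))
    expect_equal(l$modes$rank, seq_len(nrow(l$modes)))
    expect_true(all(nrow(l$modes) >= 6 & nrow(l$modes) <= 20))
  }
})

test_that("the planted |dEA| body follows the configured gamma distribution", {
  # all-B screen with the extreme tail off, so every planted magnitude is a
  # draw from the configured gamma (above threshold + guard)
  cfg <- synthetic_screen_config(
    n_ligands = 10000, seed = 77,
    class_fractions = c(A_selective = 0, B_selective = 1, nonselective = 0),
    tail_fraction = 0
  )
  g <- generate_paired_screen(cfg)
  excess <- g$truth$s_signed - cfg$threshold - cfg$guard
  ks <- suppressWarnings(stats::ks.test(  # 3-decimal quantization ties
    excess, "pgamma",
    shape = cfg$gamma_shape[["B_selective"]],
    scale = cfg$gamma_scale[["B_selective"]]
  ))
  expect_gt(ks$p.value, 0.01)
})

test_that("mode-statistic fixtures hit requested moments to 1e-9", {
  lig <- generate_mode_stat_fixture(-9.0, 0.97, 10, seed = 2)
  st <- compute_mode_statistics(lig)
  expect_lt(abs(st$mean_ea - (-9.0)), 1e-9)
  expect_lt(abs(st$sd_ea - 0.97), 1e-9)
  expect_equal(st$first_ea, min(lig$modes$affinity))
  expect_true(all(diff(lig$modes$affinity) >= 0))

  flat <- generate_mode_stat_fixture(-8.2, 0, 6)
  expect_true(all(flat$modes$affinity == -8.2))
  expect_error(generate_mode_stat_fixture(-8, 0.5, 1), "at least 2 modes")

  # statistics survive a file round trip to write precision
  path <- tempfile(fileext = ".pdbqt")
  write_vina_output(lig, path, digits = 3)
  st2 <- compute_mode_statistics(read_vina_output(path))
  expect_equal(st2$mean_ea, st$mean_ea, tolerance = 1e-3)
  expect_equal(st2$sd_ea, st$sd_ea, tolerance = 1e-3)
})

test_that("proximity fixtures plant contacts recoverable to the last atom", {
  planted <- data.frame(residue = c(1, 2, 2), element = c("H", "O", "N"),
                        multiplicity = c(2, 1, 3), distance = c(1.49, 1.2, 2.3))
  fx <- generate_proximity_fixture(4, planted, seed = 13)
  prof <- accumulate_profile(find_contacts(fx$ligand, fx$receptor))
  got <- prof[order(prof$residue_number, prof$element), ]
  expect_equal(nrow(got), 3L)
  expect_equal(got$count, c(2L, 3L, 1L))  # res 101 H, res 102 N, res 102 O
  expect_equal(got$residue_number, c(101L, 102L, 102L))

  # 1.49 vs 1.51 A on either side of the 1.5 A hydrogen cutoff
  near <- generate_proximity_fixture(
    1, data.frame(residue = 1, element = "H", multiplicity = 1, distance = 1.49)
  )
  expect_equal(nrow(find_contacts(near$ligand, near$receptor)), 1L)
  far <- generate_proximity_fixture(
    1, data.frame(residue = 1, element = "H", multiplicity = 1, distance = 1.51)
  )
  expect_equal(nrow(find_contacts(far$ligand, far$receptor)), 0L)

  # guard rails: near-cutoff planting needs boundary_ok; huge distances fail
  expect_error(generate_proximity_fixture(
    1, data.frame(residue = 1, element = "H", multiplicity = 1, distance = 1.5)
  ), "boundary_ok")
  expect_silent(generate_proximity_fixture(
    1, data.frame(residue = 1, element = "H", multiplicity = 1, distance = 1.5),
    boundary_ok = TRUE
  ))
  expect_error(generate_proximity_fixture(
    1, data.frame(residue = 1, element = "H", multiplicity = 1, distance = 11)
  ), "cannot be isolated")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_screen_config(
    class_fractions = c(A_selective = 0.5, B_selective = 0.5,
                        nonselective = 0.2)
  ))
  expect_error(synthetic_screen_config(gamma_shape = c(A_selective = -1,
                                                       B_selective = 1)))
  expect_error(synthetic_screen_config(n_ligands = 0))
})
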