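make_point_receptor <- function(points, resnames = "SER") {
  n <- nrow(points)
  atoms <- data.frame(
    serial = seq_len(n), atom_name = "OG",
    residue_name = rep(resnames, length.out = n),
    residue_number = seq_len(n), chain = "A",
    x = points[, 1], y = points[, 2], z = points[, 3],
    charge = 0, type = "OA", element = "O", stringsAsFactors = FALSE
  )
  structure(list(target_name = "pt", atoms = atoms), class = "receptor")
}

point_ligand <- function(xyz, type) {
  structure(
    list(ligand_id = "L", modes = data.frame(rank = 1L, affinity = -8,
                                             rmsd_lb = 0, rmsd_ub = 0),
         mode1_atoms = data.frame(serial = 1L, name = "X1", type = type,
                                  element = autodock_element(type),
                                  x = xyz[1], y = xyz[2], z = xyz[3],
                                  charge = -0.2, stringsAsFactors = FALSE),
         torsdof = 0L, order_violation = FALSE, source_path = NA_character_),
    class = "docked_ligand"
  )
}

test_that("cutoff thresholds behave per element, inclusively", {
  rec <- make_point_receptor(matrix(c(0, 0, 0), 1, 3))
  # coincident ligand O atom: one event at distance 0
  ev <- find_contacts(point_ligand(c(0, 0, 0), "OA"), rec)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$min_distance, 0)
  # O at 1.6 A with 1.5 A cutoff: no event; N at the same spot (2.5 A): event
  expect_equal(nrow(find_contacts(point_ligand(c(1.6, 0, 0), "OA"), rec)), 0L)
  evn <- find_contacts(point_ligand(c(1.6, 0, 0), "N"), rec)
  expect_equal(nrow(evn), 1L)
  expect_equal(evn$min_distance, 1.6)
  # the boundary is inclusive: exactly at the cutoff counts
  expect_equal(nrow(find_contacts(point_ligand(c(1.5, 0, 0), "OA"), rec)), 1L)
})

test_that("contact detection matches the exhaustive all-pairs oracle", {
  set.seed(41)
  cutoffs <- proximity_cutoffs()
  for (i in 1:60) {
    rec <- rand_receptor(n_residues = sample(3:8, 1))
    lig <- rand_ligand(with_atoms = TRUE)
    got <- find_contacts(lig, rec, cutoffs)
    want <- contact_oracle(lig, rec, cutoffs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      got <- got[order(got$residue_number, got$atom_serial), ]
      expect_equal(got$atom_serial, want$atom_serial)
      expect_equal(got$residue_number, want$residue_number)
      expect_equal(got$min_distance, want$min_distance, tolerance = 1e-12)
    }
  }
})

test_that("shrinking any cutoff never increases the number of contacts", {
  set.seed(43)
  for (i in 1:15) {
    rec <- rand_receptor()
    lig <- rand_ligand()
    base <- nrow(find_contacts(lig, rec, proximity_cutoffs(H = 2, O = 2, N = 3)))
    shrunk <- nrow(find_contacts(lig, rec,
                                 proximity_cutoffs(H = 1, O = 1.5, N = 2)))
    expect_lte(shrunk, base)
  }
})

test_that("profiles add counts, ignore ligand order, and reject mixed targets", {
  fx <- generate_proximity_fixture(
    4,
    data.frame(residue = c(1, 1, 3), element = c("H", "O", "N"),
               multiplicity = c(2, 1, 3), distance = c(1.2, 1.0, 2.2))
  )
  c1 <- find_contacts(fx$ligand, fx$receptor)
  lig2 <- fx$ligand
  lig2$ligand_id <- "SYNFIX2"
  c2 <- find_contacts(lig2, fx$receptor)

  prof <- accumulate_profile(list(c1, c2))
  expect_s3_class(prof, "proximity_profile")
  expect_equal(attr(prof, "n_ligands"), 2L)
  # two ligands each contribute the planted multiplicities -> doubled counts
  h_row <- prof[prof$element == "H" & prof$residue_number == 101, ]
  expect_equal(h_row$count, 4L)
  n_row <- prof[prof$element == "N" & prof$residue_number == 103, ]
  expect_equal(n_row$count, 6L)
  expect_equal(accumulate_profile(list(c2, c1)), prof)

  # empty contact set gives an empty profile
  empty <- accumulate_profile(c1[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)

  other <- c2
  attr(other, "target_name") <- "different"
  expect_error(accumulate_profile(list(c1, other)), "different targets")
})

test_that("top_residues ranks by summed density with residue-number tie-break", {
  prof <- structure(
    data.frame(chain = "A", residue_number = c(7L, 3L, 9L),
               residue_name = c("SER", "HIS", "GLU"),
               element = "H", count = c(5L, 3L, 3L), stringsAsFactors = FALSE),
    class = c("proximity_profile", "data.frame"),
    target_name = "t", n_ligands = 1L
  )
  top <- top_residues(prof, k = 2)
  expect_equal(top$residue_number, c(7L, 3L))  # tie 3 vs 9 -> lower number
  expect_equal(nrow(top_residues(prof, k = 10)), 3L)

  set.seed(47)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    p <- structure(
      data.frame(chain = "A", residue_number = seq_len(n),
                 residue_name = "SER",
                 element = sample(c("H", "O", "N"), n, replace = TRUE),
                 count = sample(0:9, n, replace = TRUE),
                 stringsAsFactors = FALSE),
      class = c("proximity_profile", "data.frame"),
      target_name = "t", n_ligands = 1L
    )
    k <- sample(1:5, 1)
    got <- top_residues(p, k = k)
    want <- p[order(-p$count, p$residue_number), , drop = FALSE]
    expect_equal(got$residue_number, utils::head(want$residue_number, k))
    expect_equal(got$count, utils::head(want$count, k))
  }
})

test_that("a uniquely planted residue tops the hydrogen density ranking", {
  # one residue alone holds every ligand H contact, mirroring how catalytic
  # GLU/SER/TYR residues dominate hydrogen clustering in real screens
  fx <- generate_proximity_fixture(
    5,
    data.frame(residue = c(3, 1, 4), element = c("H", "N", "N"),
               multiplicity = c(4, 1, 2), distance = c(1.3, 2.2, 2.0))
  )
  prof <- accumulate_profile(find_contacts(fx$ligand, fx$receptor))
  top <- top_residues(prof, k = 1, elements = "H")
  expect_equal(top$residue_number, 103L)
  expect_equal(top$residue_name, "GLU")
  expect_equal(top$count, 4L)
})

test_that("spatial clouds count atoms, keep charges, and span the right box", {
  mk <- function(id, n_ox) {
    types <- c(rep("OA", n_ox), "C")
    structure(
      list(ligand_id = id,
           modes = data.frame(rank = 1L, affinity = -8, rmsd_lb = 0, rmsd_ub = 0),
           mode1_atoms = data.frame(
             serial = seq_along(types), name = paste0("X", seq_along(types)),
             type = types, element = autodock_element(types),
             x = seq_along(types) + n_ox, y = 0, z = -seq_along(types),
             charge = round(seq_along(types) * 0.1, 3),
             stringsAsFactors = FALSE),
           torsdof = 0L, order_violation = FALSE, source_path = NA_character_),
      class = "docked_ligand"
    )
  }
  ligs <- list(mk("a", 2), mk("b", 0), mk("c", 1))
  cloud <- export_cloud(ligs, elements = "O")
  expect_equal(nrow(cloud), 3L)
  expect_equal(sort(cloud$charge), c(0.1, 0.1, 0.2))  # charges pass through
  # carbon excluded by default
  expect_false("C" %in% export_cloud(ligs)$element)
  # bounding box equals the brute-force min/max per axis
  bb <- bounding_box(cloud)
  expect_equal(sort(c(max(cloud$x) - min(cloud$x),
                      max(cloud$y) - min(cloud$y),
                      max(cloud$z) - min(cloud$z)), decreasing = TRUE),
               bb$dims)
  expect_warning(empty <- export_cloud(list(mk("a", 0)), elements = "halogen"),
                 "no atoms")
  expect_equal(nrow(empty), 0L)
})
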