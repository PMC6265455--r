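# Accessible-volume geometry: helix construction, grid geodesics, reach
# and stacking metrics, PDB output.

blunt_duplex <- function(n_bp = 24, pos = 12) {
  duplex_spec(paste(rep("A", n_bp), collapse = ""),
              attachment = list(strand = 2, position = pos, atom = "C5"))
}

test_that("B-form helix construction has the ideal geometry", {
  m <- build_duplex_model(blunt_duplex(10, 5))
  z <- tapply(m$atoms$z, m$atoms$base, unique)
  expect_equal(unname(z[["10"]] - z[["1"]]), 9 * 3.4)

  # full helical turn: base 11 has the azimuth of base 1
  m2 <- build_duplex_model(blunt_duplex(12, 6))
  a1 <- m2$atoms[m2$atoms$base == 1 & m2$atoms$strand == 1 &
                   m2$atoms$role == "base_out", ]
  a11 <- m2$atoms[m2$atoms$base == 11 & m2$atoms$strand == 1 &
                    m2$atoms$role == "base_out", ]
  expect_equal(atan2(a1$y, a1$x), atan2(a11$y, a11$x), tolerance = 1e-9)

  # a 2-nucleotide gap removes the deleted nucleotides' spheres entirely
  # and strips the orphaned partners down to their single-strand spheres
  sp_gap <- duplex_spec(paste(rep("A", 12), collapse = ""),
                        features = list(list(type = "gap", strand = 1,
                                             positions = c(6, 7))),
                        attachment = list(strand = 2, position = 3,
                                          atom = "C5"))
  m_gap <- build_duplex_model(sp_gap)
  expect_identical(sum(m_gap$atoms$strand == 1 & m_gap$atoms$base %in% 6:7),
                   0L)
  partner <- m_gap$atoms[m_gap$atoms$strand == 2 & m_gap$atoms$base %in% 6:7, ]
  expect_false(any(grepl("wall|edge|base_in", partner$role)))

  expect_error(duplex_spec("ACGT", "ACGT"), "not complementary")
  expect_error(duplex_spec("AAAA",
                           attachment = list(strand = 1, position = 2,
                                             atom = "C5")),
               "pyrimidine")
})

test_that("free-space accessible volume matches the analytic sphere", {
  L <- 10
  p <- linker_dye_params(linker_length = L, grid_spacing = L / 25)
  av <- compute_av(NULL, p, attachment = c(0, 0, 0))
  expect_lt(abs(av$volume / (4 / 3 * pi * L^3) - 1), 0.02)
  expect_equal(unname(av$mean_position), c(0, 0, 0), tolerance = 1e-9)
})

test_that("a plane obstacle through the attachment leaves a half-space AV", {
  L <- 10
  p <- linker_dye_params(linker_length = L, linker_width = 0.8,
                         dye_radii = 0.05, grid_spacing = 0.4)
  g <- expand.grid(x = seq(-15, 15, by = 0.5), y = seq(-15, 15, by = 0.5))
  # plane positioned so the dilated surface ends midway between grid layers
  wall <- structure(list(
    atoms = data.frame(x = g$x, y = g$y, z = -0.65, radius = 0.05,
                       base = 1, strand = 1, role = "wall"),
    attachment = list(point = c(0, 0, 0), base = NULL, strand = 1)),
    class = "helix_model")
  av <- compute_av(wall, p, attachment = c(0, 0, 0))
  expect_lt(abs(av$volume / (4 / 3 * pi * L^3) - 0.5), 0.02)
  expect_true(all(av$points[, "z"] > -0.41))
})

test_that("grid convergence: halving the spacing moves the volume < 5%", {
  p1 <- linker_dye_params(linker_length = 10, grid_spacing = 0.8)
  p2 <- linker_dye_params(linker_length = 10, grid_spacing = 0.4)
  v1 <- compute_av(NULL, p1, attachment = c(0, 0, 0))$volume
  v2 <- compute_av(NULL, p2, attachment = c(0, 0, 0))$volume
  expect_lt(abs(v1 / v2 - 1), 0.05)
})

test_that("dye reach on a duplex is at most four bases", {
  m <- build_duplex_model(blunt_duplex())
  av <- compute_av(m, linker_dye_params())
  expect_lte(axial_reach(av, m), 4L)

  # no allowed point clashes with any pseudo-atom (dye radius clearance)
  a <- m$atoms
  min_clear <- min(sapply(seq_len(nrow(a)), function(i) {
    sqrt((av$points[, 1] - a$x[i])^2 + (av$points[, 2] - a$y[i])^2 +
           (av$points[, 3] - a$z[i])^2) - a$radius[i]
  }))
  expect_gte(min_clear, 3.5 - 1e-9)
})

test_that("reach is monotone in linker length and short linkers stay local", {
  # vanishing linker in free space: the dye stays within one base
  r0 <- axial_reach(compute_av(NULL,
                               linker_dye_params(linker_length = 3,
                                                 linker_width = 1,
                                                 grid_spacing = 0.5),
                               attachment = c(0, 0, 0)))
  expect_lte(r0, 1L)

  m <- build_duplex_model(blunt_duplex())
  r_short <- axial_reach(compute_av(m, linker_dye_params(linker_length = 14,
                                                         grid_spacing = 0.9)),
                         m)
  r_long <- axial_reach(compute_av(m, linker_dye_params()), m)
  expect_lte(r_short, r_long)

  # removing all obstacles never shrinks the allowed set
  p <- linker_dye_params()
  av_dup <- compute_av(m, p)
  av_free <- compute_av(NULL, p, attachment = m$attachment$point)
  expect_lt(av_dup$n_points, av_free$n_points)
  expect_lt(axial_reach(av_dup, m),
            ceiling((p$linker_length + max(p$dye_radii)) / m$rise) + 1)
})

test_that("stacking accessibility falls off with distance from the junction", {
  fr <- sapply(c(0, 2, 4), function(off) {
    tn <- tn_junction_spec(off)
    mm <- build_duplex_model(tn$spec)
    aa <- compute_av(mm, linker_dye_params())
    c(wide = stacking_fraction(aa, mm, tn$junction_base, strand = 1,
                               shell = 10),
      contact = stacking_fraction(aa, mm, tn$junction_base, strand = 1))
  })
  # strictly decreasing accessibility with dye offset (10 A shell: coarse
  # pseudo-atoms inflate contact distances)
  expect_true(all(diff(fr["wide", ]) < 0))
  expect_gt(fr["wide", 1], 0)
  # the dye four bases away cannot overlap the junction region at all
  expect_identical(unname(fr["contact", 3]), 0)

  mm <- build_duplex_model(tn_junction_spec(0)$spec)
  aa <- compute_av(mm, linker_dye_params())
  expect_error(stacking_fraction(aa, mm, 99), "no base pseudo-atom")
  # junction far beyond the tether: empty shell
  expect_identical(stacking_fraction(aa, mm, 1, strand = 1), 0)
})

test_that("AV clouds round-trip through PDB", {
  skip_if_not_installed("bio3d")
  m <- build_duplex_model(blunt_duplex(12, 6))
  av <- compute_av(m, linker_dye_params(linker_length = 14,
                                        grid_spacing = 0.8))
  path <- tempfile(fileext = ".pdb")
  write_av_cloud(av, path, model = m)
  pdb <- bio3d::read.pdb(path)
  expect_lte(nrow(pdb$atom), 9999 + nrow(m$atoms))
  cloud <- pdb$atom[pdb$atom$chain == "B", ]
  expect_lte(nrow(cloud), 9999L)
  helix <- pdb$atom[pdb$atom$chain == "A", ]
  expect_identical(nrow(helix), nrow(m$atoms))
  # coordinates survive to 0.001 A
  expect_equal(cloud$x[1:10], unname(av$points[1:10, "x"]),
               tolerance = 1e-3)
  expect_equal(helix$x, m$atoms$x, tolerance = 1e-3)
})
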