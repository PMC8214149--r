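# Mass arithmetic: formulas, moieties, peptides, fragments, m/z.

test_that("elemental formulas parse to exact counts and reject bad input", {
  expect_equal(unclass(parse_formula("C3H2O"))[c("C", "H", "O")],
               c(C = 3L, H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("S")), c(S = 1L))
  f <- parse_formula("C7H13NO2S")
  expect_equal(unclass(f), c(C = 7L, H = 13L, N = 1L, O = 2L, S = 1L))
  expect_error(parse_formula("C3X2"), "unknown element")
  expect_error(parse_formula("c3h2"), "malformed")
  expect_error(parse_formula(""), "malformed")
})

test_that("monoisotopic masses of the remnant moieties match the summation oracle", {
  # frozen from the atomic-mass summation oracle; nominal +54 / +175 labels
  expect_equal(mono_mass("C3H2O"), 54.010565, tolerance = 1e-6)
  expect_equal(mono_mass("C7H13NO2S"), 175.066699, tolerance = 1e-6)
  # alkene/thiol doublet spacing is one sulfur
  expect_equal(round(mono_mass("C3H2SO") - mono_mass("C3H2O"), 4), 31.9721)
  expect_equal(round(bridge_mass("DSSO"), 4), 158.0038)
})

test_that("peptide masses equal residue-sum + water (+ mods)", {
  expect_equal(peptide_mass(modified_peptide("ADEKK")), 589.3071, tolerance = 1e-4)
  expect_equal(peptide_mass(modified_peptide("DLGEEHFK")), 973.4505, tolerance = 1e-4)
  expect_equal(peptide_mass(modified_peptide("GG")), 132.0535, tolerance = 1e-4)
  expect_error(modified_peptide("ABZ"), "unknown residue")
  p <- modified_peptide("ACK", mods = data.frame(pos = 2, name = "carbamidomethyl",
                                                 mass = NA))
  expect_equal(peptide_mass(p),
               peptide_mass(modified_peptide("ACK")) + 57.021464,
               tolerance = 1e-6)
})

test_that("m/z and neutral mass round-trip exactly across charges", {
  for (z in 1:8) {
    M <- 1734.8134
    expect_equal(neutral_mass(mz(M, z), z), M, tolerance = 1e-9)
  }
  expect_equal(mz(100, 1), 101.00728)
  expect_error(mz(100, 0), "charge")
})

test_that("printed worked-example fragment m/z values are reproduced at 2+", {
  a <- peptide_mass(modified_peptide("ADEKK")) +
    get_linker("SDASO-M")$alkene$mono_mass
  expect_equal(round(mz(a, 2), 2), 322.67)
  b <- peptide_mass(modified_peptide("DLGEEHFK"))
  expect_equal(round(mz(b + get_linker("SDASO-M")$thiol$mono_mass, 2), 2), 537.75)
  expect_equal(round(mz(b + get_linker("SDASO-S")$thiol$mono_mass, 2), 2), 530.74)
})

test_that("every registered linker satisfies the moiety mass identities", {
  for (nm in list_linkers()) {
    lk <- get_linker(nm)
    expect_equal(lk$alkene$mono_mass + lk$sulfenic$mono_mass, bridge_mass(lk),
                 tolerance = 1e-6)
    expect_equal(lk$thiol$mono_mass, lk$sulfenic$mono_mass - WATER_MASS,
                 tolerance = 1e-6)
  }
  expect_equal(get_linker("SDASO-L")$max_ca_ca, 35)
  expect_equal(get_linker("SDASO-M")$max_ca_ca, 30)
  expect_true(get_linker("DSSO")$symmetric)
  expect_length(get_linker("SDASO-S")$end_b_targets, 20)
})

test_that("users can register a linker from a config block", {
  register_linker(list(name = "TESTXL", sulfenic = "C3H4O2S", thiol = "C3H2SO",
                       end_b_targets = "all", symmetric = FALSE,
                       spacer_len = 9.9, max_ca_ca = 28))
  lk <- get_linker("TESTXL")
  expect_equal(lk$max_ca_ca, 28)
  expect_length(lk$end_b_targets, 20)
  expect_error(get_linker("NOPE"), "unknown linker")
})

test_that("b/y fragment ions carry mods by position and are complementary", {
  lk <- get_linker("SDASO-M")
  p <- modified_peptide("ADEKK", data.frame(pos = 4, name = "alkene",
                                            mass = lk$alkene$mono_mass))
  fr <- fragment_ions(p)
  b2 <- fr$mass[fr$ion == "b2"]
  expect_equal(round(mz(b2, 1), 4), 187.0713, tolerance = 1e-4)
  # alkene sits at position 4: b4/b3 differ by K + alkene
  b3 <- fr$mass[fr$ion == "b3"]
  b4 <- fr$mass[fr$ion == "b4"]
  expect_equal(b4 - b3, residue_mass("K")[[1]] + lk$alkene$mono_mass,
               tolerance = 1e-9)

  # property: b_i + y_(n-i) reconstructs the peptide mass, random peptides
  set.seed(11)
  for (rep in 1:200) {
    s <- paste(sample(AAS, sample(5:15, 1), replace = TRUE), collapse = "")
    mp <- sample(nchar(s), 1)
    q <- modified_peptide(s, data.frame(pos = mp, name = "thiol",
                                        mass = lk$thiol$mono_mass))
    fr <- fragment_ions(q)
    n <- nchar(s)
    M <- peptide_mass(q)
    for (i in sample(seq_len(n - 1), min(3, n - 1))) {
      bi <- fr$mass[fr$series == "b" & fr$index == i]
      yni <- fr$mass[fr$series == "y" & fr$index == n - i]
      expect_equal(bi + yni, M, tolerance = 1e-9)
    }
  }
})

test_that("sulfenic-containing fragments emit -H2O neutral-loss companions", {
  lk <- get_linker("SDASO-M")
  p <- modified_peptide("DLGEEHFK", data.frame(pos = 5, name = "sulfenic",
                                               mass = lk$sulfenic$mono_mass))
  fr <- fragment_ions(p, neutral_loss = TRUE)
  plain <- fr[!grepl("-H2O", fr$ion), ]
  nl <- fr[grepl("-H2O", fr$ion), ]
  # exactly the sulfenic-containing ions get companions: b5..b7 and y4..y7
  expect_setequal(sub("-H2O", "", nl$ion),
                  c(paste0("b", 5:7), paste0("y", 4:7)))
  for (i in seq_len(nrow(nl))) {
    base <- plain$mass[plain$ion == sub("-H2O", "", nl$ion[i])]
    expect_equal(nl$mass[i], base - 18.010565, tolerance = 1e-9)
  }
})

test_that("cross-linked pair masses follow mass conservation on cleavage", {
  a <- modified_peptide("ADEKK")
  b <- modified_peptide("DLGEEHFK")
  expect_equal(crosslinked_pair_mass(a, b, "SDASO-M"), 1734.8134, tolerance = 1e-4)
  expect_equal(crosslinked_pair_mass(a, b, "SDASO-S"), 1720.7978, tolerance = 1e-4)
  lk <- get_linker("SDASO-M")
  aA <- modified_peptide("ADEKK", data.frame(pos = 4, name = "alkene",
                                             mass = lk$alkene$mono_mass))
  bS <- modified_peptide("DLGEEHFK", data.frame(pos = 5, name = "sulfenic",
                                                mass = lk$sulfenic$mono_mass))
  expect_equal(peptide_mass(aA) + peptide_mass(bS),
               crosslinked_pair_mass(a, b, lk), tolerance = 1e-9)
  expect_error(crosslinked_pair_mass(aA, b, lk), "remnant")
})

test_that("modified peptides enforce position and remnant invariants", {
  expect_error(modified_peptide("GGK", data.frame(pos = 5, name = "alkene",
                                                  mass = 54.0106)),
               "out of range")
  expect_error(
    modified_peptide("GGKK", data.frame(pos = c(1, 2), name = c("thiol", "thiol"),
                                        mass = c(100, 100))),
    "remnant")
  # alkene + thiol together is the intralink fragment and is allowed
  p <- modified_peptide("GGKE", data.frame(pos = c(3, 4),
                                           name = c("alkene", "thiol"),
                                           mass = c(54.0106, 100.0347)))
  expect_s3_class(p, "modified_peptide")
})
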