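# Ground-truth generator: species simulation, spectrum rendering, MGF I/O,
# toy structure ensembles.

test_that("species counts and degenerate residue preferences are honored", {
  db <- synthetic_db(n = 3, len = 150, seed = 8)
  pref <- stats::setNames(rep(0, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  pref["E"] <- 1
  cfg <- sim_config(n_interlink = 15, n_deadend_nhs = 4,
                    n_deadend_diazirine = 3, n_intralink = 2,
                    residue_preference = pref, seed = 2)
  tr <- simulate_crosslinks(db, cfg)
  expect_equal(as.vector(table(tr$kind)[c("interlink", "deadend_nhs_hydrolyzed",
                                          "deadend_diazirine_hydrolyzed",
                                          "intralink")]),
               c(15L, 4L, 3L, 2L))
  inter <- tr[tr$kind == "interlink", ]
  bres <- substring(inter$beta_seq, inter$beta_site, inter$beta_site)
  expect_true(all(bres == "E"))
  # NHS-side sites are always lysines
  expect_true(all(substring(inter$alpha_seq, inter$alpha_site,
                            inter$alpha_site) == "K"))

  cfg0 <- sim_config(n_interlink = 0, n_deadend_nhs = 2,
                     n_deadend_diazirine = 0, n_intralink = 0, seed = 2)
  tr0 <- simulate_crosslinks(db, cfg0)
  expect_false(any(tr0$kind == "interlink"))
  expect_equal(nrow(tr0), 2L)
})

test_that("simulation is reproducible under a fixed seed", {
  db <- synthetic_db(n = 3, len = 150, seed = 8)
  cfg <- sim_config(n_interlink = 10, seed = 77)
  t1 <- simulate_crosslinks(db, cfg)
  t2 <- simulate_crosslinks(db, cfg)
  expect_identical(t1, t2)
  s1 <- render_spectra(t1, cfg)
  s2 <- render_spectra(t2, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_mgf(s1, f1); write_mgf(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noiseless rendered masses reconcile with the mass arithmetic", {
  db <- synthetic_db(n = 3, len = 150, seed = 8)
  cfg <- sim_config(n_interlink = 6, n_deadend_nhs = 3,
                    n_deadend_diazirine = 3, n_intralink = 3,
                    ppm_sigma = 0, noise_peaks = 0, seed = 5)
  tr <- simulate_crosslinks(db, cfg)
  sp <- render_spectra(tr, cfg)
  truth <- attr(sp, "truth")
  lk <- get_linker(cfg$linker)
  ms2 <- Filter(function(s) s$ms_level == 2L, sp)
  for (s in ms2) {
    t <- truth[truth$ms2_scan == s$scan, ]
    M <- neutral_mass(s$precursor_mz, s$precursor_z)
    expect_equal(M, t$neutral_mass, tolerance = 1e-6)
    if (t$kind == "interlink") {
      # alpha_A + beta_S neutrals reconstruct the precursor exactly
      aA <- peptide_mass(modified_peptide(
        t$alpha_seq, data.frame(pos = t$alpha_site, name = "alkene",
                                mass = lk$alkene$mono_mass)))
      bS <- peptide_mass(modified_peptide(
        t$beta_seq, data.frame(pos = t$beta_site, name = "sulfenic",
                               mass = lk$sulfenic$mono_mass)))
      expect_equal(aA + bS, M, tolerance = 1e-6)
      neutrals <- unlist(lapply(1:(s$precursor_z - 1), function(z)
        neutral_mass(s$mz, z)))
      expect_true(any(abs(neutrals - aA) < 1e-4))
      expect_true(any(abs(neutrals - (bS - WATER_MASS)) < 1e-4))
    }
    if (t$kind == "intralink") {
      # single fragment at peptide + alkene + thiol
      expect_length(s$mz, 1L)
      fm <- peptide_mass(modified_peptide(t$alpha_seq)) +
        lk$alkene$mono_mass + lk$thiol$mono_mass
      zf <- min(2L, s$precursor_z - 1L)
      expect_equal(s$mz, mz(fm, zf), tolerance = 1e-6)
    }
  }
})

test_that("the worked-example interlink renders its printed MS2 fragments", {
  tr <- worked_example_truth("SDASO-M", z = 4L)
  cfg <- sim_config(linker = "SDASO-M", seed = 1)
  sp <- render_spectra(tr, cfg)
  ms2 <- Filter(function(s) s$ms_level == 2L, sp)[[1]]
  expect_true(any(round(ms2$mz, 2) == 322.67))  # alpha with alkene, 2+
  expect_true(any(round(ms2$mz, 2) == 537.75))  # beta with thiol, 2+
  # MS3 children exist for the top MS2 peaks and reference their parent
  ms3 <- Filter(function(s) s$ms_level == 3L, sp)
  expect_gte(length(ms3), 2L)
  expect_true(all(vapply(ms3, function(s) s$parent_scan == ms2$scan, logical(1))))
})

test_that("MGF round trip is lossless and the dialect carries lineage", {
  db <- synthetic_db(n = 2, len = 120, seed = 8)
  cfg <- sim_config(n_interlink = 4, n_deadend_nhs = 1,
                    n_deadend_diazirine = 1, n_intralink = 1,
                    ppm_sigma = 3, noise_peaks = 5, seed = 3)
  sp <- render_spectra(simulate_crosslinks(db, cfg), cfg)
  f <- tempfile(fileext = ".mgf")
  write_mgf(sp, f)
  back <- read_mgf(f)
  expect_length(back, length(sp))
  for (i in seq_along(sp)) {
    expect_equal(back[[i]]$scan, sp[[i]]$scan)
    expect_equal(back[[i]]$ms_level, sp[[i]]$ms_level)
    expect_equal(back[[i]]$parent_scan, sp[[i]]$parent_scan)
    expect_equal(back[[i]]$precursor_z, sp[[i]]$precursor_z)
    expect_equal(back[[i]]$mz, sp[[i]]$mz, tolerance = 1e-4)
    expect_equal(back[[i]]$intensity, sp[[i]]$intensity, tolerance = 1e-3)
  }
  # an MS3 spectrum cannot exist without a parent reference
  expect_error(msn_spectrum(9, 3L, 100, 1, parent_scan = NA), "parent")
  # empty list writes a valid empty file
  f2 <- tempfile(fileext = ".mgf")
  write_mgf(list(), f2)
  expect_length(read_mgf(f2), 0L)
})

test_that("toy structure ensembles realize planted distances per model", {
  plan <- data.frame(res_a = c(5L, 10L), res_b = c(30L, 35L),
                     d1 = c(5, 10), d2 = c(20, 31), d3 = c(29, 36),
                     d4 = c(40, 50))
  toy <- make_toy_structures(4, plan, sequence = paste0(
    strrep("A", 4), "K", strrep("A", 4), "K", strrep("A", 30)))
  expect_length(toy$models, 4L)
  for (m in seq_len(4)) {
    for (i in seq_len(nrow(plan))) {
      d <- ca_distance(toy$models[[m]], "A", plan$res_a[i], "A", plan$res_b[i])
      expect_equal(d, plan[[paste0("d", m)]][i], tolerance = 1e-6)
    }
  }
  one <- make_toy_structures(1, data.frame(res_a = 2L, res_b = 8L, d1 = 5))
  expect_length(one$models, 1L)
  expect_equal(ca_distance(one$models[[1]], "A", 2, "A", 8), 5, tolerance = 1e-6)
  expect_error(
    make_toy_structures(1, data.frame(res_a = c(2L, 3L), res_b = c(8L, 8L),
                                      d1 = c(5, 6))),
    "infeasible")
})
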