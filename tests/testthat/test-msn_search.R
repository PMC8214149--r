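# MS2 signature pairing and MS3 peptide-spectrum matching.

test_that("fragment charge hypotheses follow the precursor charge", {
  s <- msn_spectrum(1, 2L, c(300, 500), c(1, 1), precursor_mz = 500,
                    precursor_z = 4L)
  expect_equal(assign_charges(s), list(1:3, 1:3))
  expect_equal(assign_charges(s, max_z = 2), list(1:2, 1:2))
  s0 <- msn_spectrum(1, 2L, numeric(), numeric(), precursor_mz = 500,
                     precursor_z = 3L)
  expect_length(assign_charges(s0), 0L)
})

test_that("a noiseless interlink spectrum yields exactly one oriented A+T pair", {
  tr <- worked_example_truth("SDASO-M", z = 4L)
  cfg <- sim_config(linker = "SDASO-M", seed = 1)
  sp <- render_spectra(tr, cfg)
  ms2 <- Filter(function(s) s$ms_level == 2L, sp)[[1]]
  pr <- find_signature_pairs(ms2, "SDASO-M")
  at <- pr[pr$pair_type == "A+T", ]
  expect_equal(nrow(at), 1L)
  got <- sort(round(c(ms2$mz[at$peak_i], ms2$mz[at$peak_j]), 2))
  expect_equal(got, c(322.67, 537.75))
  expect_lt(abs(at$error_ppm), 1e-3)
  # the sulfenic (minor) form gives the complementary A+S pair
  expect_equal(sum(pr$pair_type == "A+S"), 1L)
})

test_that("DSSO spectra show corroborating 31.9721 Da alkene/thiol doublets", {
  db <- bsa_like_protein()
  cfg <- sim_config(linker = "DSSO", seed = 4, n_interlink = 3,
                    n_deadend_nhs = 0, n_deadend_diazirine = 0, n_intralink = 0)
  tr <- simulate_crosslinks(db, cfg)
  sp <- render_spectra(tr, cfg)
  ms2 <- Filter(function(s) s$ms_level == 2L, sp)
  for (s in ms2) {
    pr <- find_signature_pairs(s, "DSSO")
    expect_gt(nrow(pr), 0L)
    expect_true(any(pr$corroborated))
  }
})

test_that("pair finding matches the all-pairs oracle on random spectra", {
  set.seed(31)
  for (i in 1:100) {
    npk <- sample(5:25, 1)
    z <- sample(3:5, 1)
    mzv <- runif(npk, 150, 1400)
    M <- runif(1, 1500, 4000)
    s <- msn_spectrum(i, 2L, mzv, runif(npk, 1, 100),
                      precursor_mz = mz(M, z), precursor_z = z)
    got <- find_signature_pairs(s, "SDASO-M")
    want <- oracle_pairs(s, "SDASO-M")
    expect_equal(pair_key(got), pair_key(want))
  }
})

test_that("random noise spectra almost never produce signature pairs", {
  set.seed(17)
  n_with_pairs <- 0L
  for (i in 1:1000) {
    s <- msn_spectrum(i, 2L, runif(10, 200, 1500), runif(10, 1, 10),
                      precursor_mz = runif(1, 600, 1100), precursor_z = 3L)
    if (nrow(find_signature_pairs(s, "SDASO-M"))) {
      n_with_pairs <- n_with_pairs + 1L
    }
  }
  expect_lte(n_with_pairs / 1000, 0.01)
})

test_that("the generating peptide outscores shuffled decoys on its own spectrum", {
  lk <- get_linker("SDASO-M")
  set.seed(41)
  worse <- 0L; total <- 300L
  for (i in seq_len(total)) {
    s <- paste(sample(AAS, 9, replace = TRUE), collapse = "")
    p <- modified_peptide(s, data.frame(pos = sample(9, 1), name = "thiol",
                                        mass = lk$thiol$mono_mass))
    ions <- fragment_ions(p)
    spec <- msn_spectrum(i, 3L, mz(ions$mass, 1), runif(nrow(ions), 50, 100),
                         precursor_mz = mz(peptide_mass(p), 2),
                         precursor_z = 2L, parent_scan = 1L)
    truescore <- score_psm(spec, p)$score
    dec_seq <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    dec <- modified_peptide(dec_seq,
                            data.frame(pos = 1, name = "thiol",
                                       mass = lk$thiol$mono_mass),
                            is_decoy = TRUE)
    if (score_psm(spec, dec)$score >= truescore) worse <- worse + 1L
  }
  expect_lte(worse / total, 0.01)
})

test_that("the PSM score is monotone in matched peaks at fixed candidate", {
  lk <- get_linker("SDASO-M")
  p <- modified_peptide("DLGEEHFK", data.frame(pos = 5, name = "thiol",
                                               mass = lk$thiol$mono_mass))
  ions <- mz(fragment_ions(p)$mass, 1)
  scores <- vapply(seq_along(ions), function(k) {
    # spectrum containing the first k theoretical peaks plus fixed decoys
    mzv <- c(ions[seq_len(k)], seq(1500, 1790, by = 10))
    s <- msn_spectrum(1, 3L, mzv, rep(10, length(mzv)),
                      precursor_mz = mz(peptide_mass(p), 2), precursor_z = 2L,
                      parent_scan = 1L)
    score_psm(s, p)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("site localization reports ties and rejects sub-floor spectra", {
  lk <- get_linker("SDASO-M")
  # spectrum missing the ions that separate positions 1 and 2
  p1 <- modified_peptide("AAEK", data.frame(pos = 1, name = "thiol",
                                            mass = lk$thiol$mono_mass))
  ions <- fragment_ions(p1)
  keep <- !(ions$ion %in% c("b1", "y3"))
  spec <- msn_spectrum(1, 3L, mz(ions$mass[keep], 1), rep(80, sum(keep)),
                       precursor_mz = mz(peptide_mass(p1), 1),
                       precursor_z = 1L, parent_scan = 1L)
  cands <- lapply(1:4, function(pos) modified_peptide(
    "AAEK", data.frame(pos = pos, name = "thiol", mass = lk$thiol$mono_mass)))
  psms <- lapply(cands, function(cd) score_psm(spec, cd))
  best <- localize_site(psms)
  expect_equal(best$ambiguity, c(1L, 2L))
  expect_equal(best$ambiguity_res, c("A", "A"))
  # a site-determining spectrum gives a singleton ambiguity set
  full <- msn_spectrum(1, 3L, mz(ions$mass, 1), rep(80, nrow(ions)),
                       precursor_mz = mz(peptide_mass(p1), 1),
                       precursor_z = 1L, parent_scan = 1L)
  best2 <- localize_site(lapply(cands, function(cd) score_psm(full, cd)))
  expect_equal(best2$ambiguity, 1L)
  # nothing above the floor: unidentified
  junk <- msn_spectrum(1, 3L, c(1500, 1600), c(1, 1),
                       precursor_mz = mz(peptide_mass(p1), 1),
                       precursor_z = 1L, parent_scan = 1L)
  expect_null(localize_site(lapply(cands, function(cd) score_psm(junk, cd))))
})
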