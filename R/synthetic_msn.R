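# Ground-truth generator: simulated cross-linked species, their MSn spectra
# (MS2 signature fragments + MS3 b/y spectra), an MGF writer/reader, and toy
# multi-model CA-only PDB ensembles with planted distances.

#' Default diazirine residue-preference weights
#'
#' Emulates the relative carbene-insertion specificity reported for
#' NHS-diazirine cross-linking: glutamic acid strongly favored (weight
#' 0.30), with alanine, aspartate, leucine and tyrosine moderately favored
#' and the remaining residues sharing the rest equally (~2.7% each).
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
default_residue_preference <- function() {
  w <- c(E = 0.30, A = 0.072, D = 0.068, L = 0.073, Y = 0.064)
  rest <- setdiff(.AA20, names(w))
  w <- c(w, stats::setNames(rep((1 - sum(w)) / length(rest), length(rest)), rest))
  w[.AA20]
}

#' Simulation configuration
#'
#' @param linker Linker name (default \code{"SDASO-M"}).
#' @param n_interlink,n_deadend_nhs,n_deadend_diazirine,n_intralink Species
#'   counts to simulate.
#' @param residue_preference Named weights for the diazirine-side residue
#'   (non-negative, not all zero); default
#'   \code{\link{default_residue_preference}}.
#' @param charges Precursor charge states to draw from (all >= 3, matching
#'   the MSn acquisition that selects 3+ and higher precursors).
#' @param ppm_sigma Gaussian mass-noise sigma in ppm applied to every m/z.
#' @param noise_peaks Uniform random peaks added per spectrum.
#' @param beta_s_ratio Intensity of the sulfenic fragment relative to the
#'   dominant dehydrated thiol fragment (default 0.25).
#' @param seed Integer seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(linker = "SDASO-M", n_interlink = 20L,
                       n_deadend_nhs = 20L, n_deadend_diazirine = 20L,
                       n_intralink = 20L,
                       residue_preference = default_residue_preference(),
                       charges = c(3L, 4L, 5L), ppm_sigma = 0,
                       noise_peaks = 0L, beta_s_ratio = 0.25, seed = 1L) {
  stopifnot(all(charges >= 3L), all(residue_preference >= 0),
            sum(residue_preference) > 0, ppm_sigma >= 0, noise_peaks >= 0)
  structure(list(linker = linker, n_interlink = as.integer(n_interlink),
                 n_deadend_nhs = as.integer(n_deadend_nhs),
                 n_deadend_diazirine = as.integer(n_deadend_diazirine),
                 n_intralink = as.integer(n_intralink),
                 residue_preference = residue_preference,
                 charges = as.integer(charges), ppm_sigma = ppm_sigma,
                 noise_peaks = as.integer(noise_peaks),
                 beta_s_ratio = beta_s_ratio, seed = as.integer(seed)),
            class = "sim_config")
}

# eligible alkene positions of one indexed peptide row
.alkene_positions <- function(seqstr, at_cterm) {
  ch <- strsplit(seqstr, "")[[1]]
  kp <- which(ch == "K")
  kp[kp < length(ch) | at_cterm]
}

#' Simulate cross-linked species from a protein database
#'
#' Draws lysine (NHS-end) sites uniformly from digestible lysines and
#' diazirine-end sites from the configured residue-preference distribution:
#' a residue type is drawn with probability proportional to its weight
#' (restricted to types present in the digest), then a site is drawn
#' uniformly among occurrences of that type, so the marginal residue-type
#' distribution of planted sites equals the preference weights.
#'
#' @param db Target protein data.frame (from \code{\link{read_fasta}}).
#' @param cfg A \code{\link{sim_config}}.
#' @param params Digestion parameters.
#' @return data.frame of truth records (one row per species) with peptide
#'   sequences, protein coordinates of the link sites, precursor m/z and
#'   charge. Scan lineage ids are filled in by
#'   \code{\link{render_spectra}}.
#' @export
simulate_crosslinks <- function(db, cfg, params = digest_params()) {
  linker <- get_linker(cfg$linker)
  idx <- build_digest_index(db, params)
  set.seed(cfg$seed)

  apos <- lapply(seq_len(nrow(idx)),
                 function(i) .alkene_positions(idx$sequence[i], idx$at_protein_cterm[i]))
  a_rows <- which(lengths(apos) > 0L)
  if (!length(a_rows)) stop("database has no lysine-containing peptides")

  # diazirine-side site pool: every allowed residue occurrence
  b_pool <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    ch <- strsplit(idx$sequence[i], "")[[1]]
    pp <- which(ch %in% linker$end_b_targets)
    if (!length(pp)) return(NULL)
    data.frame(row = i, pos = pp, res = ch[pp])
  }))
  pref <- cfg$residue_preference
  pref <- pref[names(pref) %in% unique(b_pool$res)]
  if (!sum(pref) > 0) stop("no diazirine-side sites with positive preference")
  pref <- pref / sum(pref)

  draw_alpha <- function() {
    i <- if (length(a_rows) == 1L) a_rows else sample(a_rows, 1L)
    kp <- apos[[i]]
    kp <- if (length(kp) == 1L) kp else sample(kp, 1L)
    list(row = i, pos = kp)
  }
  draw_beta <- function() {
    res <- sample(names(pref), 1L, prob = pref)
    cand <- which(b_pool$res == res)
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    list(row = b_pool$row[j], pos = b_pool$pos[j])
  }

  rec <- function(kind, a, b = NULL, x_pos = NA_integer_) {
    ar <- idx[a$row, ]
    alpha_mass <- ar$mass
    if (kind == "interlink") {
      br <- idx[b$row, ]
      M <- ar$mass + br$mass + bridge_mass(linker)
    } else if (kind == "deadend_nhs_hydrolyzed" ||
               kind == "deadend_diazirine_hydrolyzed") {
      M <- ar$mass + bridge_mass(linker) + WATER_MASS
    } else { # intralink
      M <- ar$mass + bridge_mass(linker)
    }
    z <- if (length(cfg$charges) == 1L) cfg$charges else sample(cfg$charges, 1L)
    data.frame(
      kind = kind, linker = linker$name,
      alpha_seq = ar$sequence, alpha_protein = ar$accession,
      alpha_start = ar$start, alpha_site = a$pos,
      alpha_res = ar$start + a$pos - 1L,
      beta_seq = if (kind == "interlink") idx$sequence[b$row] else NA_character_,
      beta_protein = if (kind == "interlink") idx$accession[b$row] else NA_character_,
      beta_start = if (kind == "interlink") idx$start[b$row] else NA_integer_,
      beta_site = if (kind == "interlink") b$pos else x_pos,
      beta_res = if (kind == "interlink") idx$start[b$row] + b$pos - 1L
                 else if (!is.na(x_pos)) ar$start + x_pos - 1L else NA_integer_,
      precursor_mz = mz(M, z), z = z, neutral_mass = M,
      ms2_scan = NA_integer_)
  }

  out <- list()
  for (i in seq_len(cfg$n_interlink)) {
    out[[length(out) + 1L]] <- rec("interlink", draw_alpha(), draw_beta())
  }
  # NHS end hydrolyzed: peptide attached via the diazirine end (site from
  # the preference distribution); fragments carry sulfenic/thiol.
  for (i in seq_len(cfg$n_deadend_nhs)) {
    b <- draw_beta()
    out[[length(out) + 1L]] <- rec("deadend_nhs_hydrolyzed",
                                   list(row = b$row, pos = b$pos))
  }
  # diazirine end hydrolyzed: peptide attached via NHS at a lysine;
  # fragment carries the alkene.
  for (i in seq_len(cfg$n_deadend_diazirine)) {
    out[[length(out) + 1L]] <- rec("deadend_diazirine_hydrolyzed", draw_alpha())
  }
  for (i in seq_len(cfg$n_intralink)) {
    repeat {
      a <- draw_alpha()
      ch <- strsplit(idx$sequence[a$row], "")[[1]]
      xs <- setdiff(which(ch %in% linker$end_b_targets), a$pos)
      if (length(xs)) break
    }
    xp <- if (length(xs) == 1L) xs else sample(xs, 1L)
    out[[length(out) + 1L]] <- rec("intralink", a, x_pos = xp)
  }
  truth <- do.call(rbind, out)
  if (is.null(truth)) {
    truth <- rec("interlink", draw_alpha(), draw_beta())[0, ]
  }
  truth$truth_id <- seq_len(nrow(truth))
  truth
}

# ---------------------------------------------------------------------------
# Spectra

#' Construct an MSn spectrum
#'
#' @param scan Integer scan id.
#' @param ms_level 1, 2 or 3.
#' @param mz,intensity Peak vectors (sorted by m/z on construction).
#' @param precursor_mz,precursor_z Precursor (levels 2 and 3).
#' @param parent_scan Parent scan id (required for levels 2 and 3 when part
#'   of a lineage; level 3 must reference its MS2 parent).
#' @param truth_id Optional id of the generating truth record.
#' @return Object of class \code{msn_spectrum}.
#' @export
msn_spectrum <- function(scan, ms_level, mz, intensity,
                         precursor_mz = NA_real_, precursor_z = NA_integer_,
                         parent_scan = NA_integer_, truth_id = NA_integer_) {
  stopifnot(ms_level %in% 1:3, length(mz) == length(intensity))
  if (ms_level == 3L && is.na(parent_scan)) {
    stop("MS3 spectrum requires a parent MS2 scan reference")
  }
  o <- order(mz)
  structure(list(scan = as.integer(scan), ms_level = as.integer(ms_level),
                 parent_scan = as.integer(parent_scan),
                 precursor_mz = precursor_mz,
                 precursor_z = as.integer(precursor_z),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 truth_id = as.integer(truth_id)),
            class = "msn_spectrum")
}

#' @export
print.msn_spectrum <- function(x, ...) {
  cat(sprintf("<MS%d scan %d: %d peaks%s>\n", x$ms_level, x$scan,
              length(x$mz),
              if (!is.na(x$precursor_mz))
                sprintf(", precursor %.4f %d+", x$precursor_mz, x$precursor_z)
              else ""))
  invisible(x)
}

.jitter_ppm <- function(m, sigma_ppm) {
  if (sigma_ppm <= 0) return(m)
  m * (1 + stats::rnorm(length(m), 0, sigma_ppm) * 1e-6)
}

#' Render MSn spectra for simulated truth records
#'
#' For each interlink an MS2 spectrum is produced containing the
#' characteristic signature fragments: the alkene-modified lysine peptide
#' (alpha_A) plus the diazirine peptide as dominant dehydrated thiol
#' (beta_T) and minor sulfenic (beta_S) forms. For the symmetric DSSO both
#' A/S assignments are rendered, giving the 31.9721 Da alkene/thiol
#' doublets on each constituent. Dead-ends and intralinks produce their
#' single-fragment MS2 patterns. The four most intense MS2 peaks are
#' selected for MS3, each yielding a b/y spectrum of the remnant-modified
#' peptide (with -H2O neutral-loss companions for sulfenic forms). Gaussian
#' ppm noise perturbs every m/z and uniform noise peaks are added per
#' spectrum.
#'
#' @param truth Truth data.frame from \code{\link{simulate_crosslinks}}.
#' @param cfg The same \code{\link{sim_config}}.
#' @return List of \code{msn_spectrum}; attribute \code{"truth"} holds the
#'   truth table with \code{ms2_scan} filled in.
#' @export
render_spectra <- function(truth, cfg) {
  linker <- get_linker(cfg$linker)
  set.seed(cfg$seed + 104729L)
  spectra <- list()
  scan <- 0L
  frag_z <- function(z) min(2L, z - 1L)

  add_noise_peaks <- function(mzv, intv, lo, hi) {
    if (cfg$noise_peaks > 0L) {
      nm <- stats::runif(cfg$noise_peaks, lo, hi)
      ni <- stats::runif(cfg$noise_peaks, 1, 10)
      list(mz = c(mzv, nm), intensity = c(intv, ni))
    } else list(mz = mzv, intensity = intv)
  }

  for (r in seq_len(nrow(truth))) {
    tr <- truth[r, ]
    zf <- frag_z(tr$z)
    # signature-pair charge split: fragment charges sum to the precursor charge
    z_alpha <- max(1L, tr$z %/% 2L)
    z_beta <- tr$z - z_alpha
    frags <- list()  # each: list(p = peptide, int = intensity, z = charge)
    pepA <- function(seqstr, site) modified_peptide(
      seqstr, data.frame(pos = site, name = "alkene",
                         mass = linker$alkene$mono_mass))
    pepMo <- function(seqstr, site, mo) modified_peptide(
      seqstr, data.frame(pos = site, name = mo, mass = linker[[mo]]$mono_mass))

    if (tr$kind == "interlink") {
      a_pep <- pepA(tr$alpha_seq, tr$alpha_site)
      b_T <- pepMo(tr$beta_seq, tr$beta_site, "thiol")
      b_S <- pepMo(tr$beta_seq, tr$beta_site, "sulfenic")
      frags <- list(
        list(p = a_pep, int = 100, z = z_alpha),
        list(p = b_T, int = 100, z = z_beta),
        list(p = b_S, int = 100 * cfg$beta_s_ratio, z = z_beta))
      if (linker$symmetric) {
        # both assignments observable for a symmetric linker
        a_T <- pepMo(tr$alpha_seq, tr$alpha_site, "thiol")
        a_S <- pepMo(tr$alpha_seq, tr$alpha_site, "sulfenic")
        b_A <- pepA(tr$beta_seq, tr$beta_site)
        frags <- c(frags, list(
          list(p = b_A, int = 80, z = z_beta),
          list(p = a_T, int = 80, z = z_alpha),
          list(p = a_S, int = 80 * cfg$beta_s_ratio, z = z_alpha)))
      }
    } else if (tr$kind == "deadend_nhs_hydrolyzed") {
      frags <- list(
        list(p = pepMo(tr$alpha_seq, tr$alpha_site, "thiol"), int = 100, z = zf),
        list(p = pepMo(tr$alpha_seq, tr$alpha_site, "sulfenic"),
             int = 100 * cfg$beta_s_ratio, z = zf))
    } else if (tr$kind == "deadend_diazirine_hydrolyzed") {
      frags <- list(list(p = pepA(tr$alpha_seq, tr$alpha_site), int = 100, z = zf))
    } else { # intralink: single fragment carrying alkene + thiol
      p2 <- modified_peptide(
        tr$alpha_seq,
        data.frame(pos = c(tr$alpha_site, tr$beta_site),
                   name = c("alkene", "thiol"),
                   mass = c(linker$alkene$mono_mass, linker$thiol$mono_mass)))
      frags <- list(list(p = p2, int = 100, z = zf))
    }

    ms2_mz <- vapply(frags, function(f) mz(peptide_mass(f$p), f$z), numeric(1))
    ms2_int <- vapply(frags, function(f) f$int, numeric(1))
    pk <- add_noise_peaks(.jitter_ppm(ms2_mz, cfg$ppm_sigma), ms2_int,
                          min(ms2_mz) * 0.5, max(ms2_mz) * 1.5)
    scan <- scan + 1L
    ms2_scan <- scan
    spectra[[length(spectra) + 1L]] <- msn_spectrum(
      ms2_scan, 2L, pk$mz, pk$intensity,
      precursor_mz = .jitter_ppm(tr$precursor_mz, cfg$ppm_sigma),
      precursor_z = tr$z, truth_id = tr$truth_id)
    truth$ms2_scan[r] <- ms2_scan

    # top-four data-dependent MS3 over the rendered (noisy) MS2 peaks
    ord <- order(pk$intensity, decreasing = TRUE)
    sel <- ord[seq_len(min(4L, length(ord)))]
    for (s in sel) {
      # match the selected peak back to a theoretical fragment (noise peaks
      # selected here have no fragment and are skipped)
      fi <- .nearest_index(pk$mz[s], ms2_mz)
      if (abs(pk$mz[s] - ms2_mz[fi]) / ms2_mz[fi] > 50e-6) next
      f <- frags[[fi]]
      ions <- fragment_ions(f$p, neutral_loss = any(f$p$mods$name == "sulfenic"))
      m3 <- mz(ions$mass, 1L)
      i3 <- stats::runif(length(m3), 50, 100)
      pk3 <- add_noise_peaks(.jitter_ppm(m3, cfg$ppm_sigma), i3,
                             min(m3) * 0.5, max(m3) * 1.5)
      scan <- scan + 1L
      spectra[[length(spectra) + 1L]] <- msn_spectrum(
        scan, 3L, pk3$mz, pk3$intensity,
        precursor_mz = pk$mz[s], precursor_z = f$z,
        parent_scan = ms2_scan, truth_id = tr$truth_id)
    }
  }
  attr(spectra, "truth") <- truth
  spectra
}

.nearest_index <- function(x, v) which.min(abs(v - x))

# ---------------------------------------------------------------------------
# MGF I/O (dialect: lineage in TITLE as "scan=<id> parent=<id> level=<n>")

#' Write spectra to an MGF file
#'
#' Dialect: one BEGIN IONS/END IONS block per spectrum; scan lineage is
#' carried in the TITLE line as \code{scan=<id> parent=<id> level=<n>}
#' (\code{truth=<id>} appended for simulated spectra); PEPMASS and CHARGE
#' carry the precursor.
#'
#' @param spectra List of \code{msn_spectrum}.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    if (sp$ms_level == 3L && is.na(sp$parent_scan)) {
      stop("MS3 spectrum ", sp$scan, " lacks a parent scan reference")
    }
    writeLines("BEGIN IONS", con)
    title <- sprintf("scan=%d parent=%s level=%d", sp$scan,
                     ifelse(is.na(sp$parent_scan), "-", sp$parent_scan),
                     sp$ms_level)
    if (!is.na(sp$truth_id)) title <- paste0(title, " truth=", sp$truth_id)
    writeLines(paste0("TITLE=", title), con)
    if (!is.na(sp$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    }
    if (!is.na(sp$precursor_z)) {
      writeLines(sprintf("CHARGE=%d+", sp$precursor_z), con)
    }
    if (length(sp$mz)) {
      writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read an MGF file written in the package dialect
#'
#' @param path MGF path.
#' @return List of \code{msn_spectrum}.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path)
  }
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("^[A-Z]+=", block)
    fields <- block[hdr]
    peaks <- block[!hdr & nzchar(block)]
    getf <- function(key) {
      v <- fields[startsWith(fields, paste0(key, "="))]
      if (length(v)) sub(paste0("^", key, "="), "", v[1]) else NA_character_
    }
    title <- getf("TITLE")
    if (is.na(title)) stop("malformed MGF: block without TITLE")
    gv <- function(k) {
      m <- regmatches(title, regexec(paste0(k, "=([-0-9]+)"), title))[[1]]
      if (length(m) == 2L && m[2] != "-") as.integer(m[2]) else NA_integer_
    }
    pm <- getf("PEPMASS")
    chg <- getf("CHARGE")
    mzi <- if (length(peaks)) {
      do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), as.numeric))
    } else matrix(numeric(), ncol = 2)
    out[[i]] <- msn_spectrum(
      scan = gv("scan"), ms_level = gv("level"),
      mz = mzi[, 1], intensity = mzi[, 2],
      precursor_mz = if (is.na(pm)) NA_real_ else as.numeric(pm),
      precursor_z = if (is.na(chg)) NA_integer_
                    else as.integer(sub("\\+$", "", chg)),
      parent_scan = gv("parent"), truth_id = gv("truth"))
  }
  out
}

#' Write a truth manifest TSV
#' @param truth Truth data.frame (scan lineage filled by
#'   \code{\link{render_spectra}}).
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Toy structures

.AA3 <- c(G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL", T = "THR",
          C = "CYS", L = "LEU", I = "ILE", N = "ASN", D = "ASP", Q = "GLN",
          K = "LYS", E = "GLU", M = "MET", H = "HIS", F = "PHE", R = "ARG",
          Y = "TYR", W = "TRP")

#' Build a toy multi-model CA-only PDB ensemble with planted distances
#'
#' Constructs a synthetic single-chain CA trace (3.8 Angstrom spacing) and,
#' per model, relocates the second residue of each planted linkage so its
#' Calpha-Calpha distance to the first residue equals the requested value.
#' Useful for exercising distance validation and state-specific
#' classification with known answers.
#'
#' @param n_models Number of MODEL blocks (>= 1).
#' @param plan data.frame with columns \code{res_a}, \code{res_b} and the
#'   planted distance for each model in columns \code{d1..d<n_models>}
#'   (Angstrom). Each \code{res_b} may appear only once and must not occur
#'   among \code{res_a} (otherwise the plan is infeasible).
#' @param sequence One-letter residue string defining residue identities
#'   (length = chain length); defaults to all-alanine of length
#'   \code{max(plan residues) + 5}.
#' @param chain Chain identifier.
#' @param path Output PDB path (default a tempfile).
#' @param seed Unused placeholder for API symmetry; construction is
#'   deterministic.
#' @return List with \code{path}, \code{models} (parsed via
#'   \code{\link{read_structure}}) and \code{planted} (the plan).
#' @export
make_toy_structures <- function(n_models, plan, sequence = NULL, chain = "A",
                                path = tempfile(fileext = ".pdb"), seed = 1L) {
  stopifnot(n_models >= 1L, all(c("res_a", "res_b") %in% names(plan)))
  dcols <- paste0("d", seq_len(n_models))
  if (!all(dcols %in% names(plan))) {
    stop("plan must carry distance columns ", paste(dcols, collapse = ", "))
  }
  if (anyDuplicated(plan$res_b) || any(plan$res_b %in% plan$res_a)) {
    stop("infeasible distance plan: each res_b must be a unique movable residue")
  }
  if (any(as.matrix(plan[dcols]) < 0)) stop("infeasible distance plan: negative distance")
  n_res <- if (is.null(sequence)) max(plan$res_a, plan$res_b) + 5L
           else nchar(sequence)
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  if (max(plan$res_a, plan$res_b) > n_res) stop("plan residue beyond chain length")
  ch <- strsplit(sequence, "")[[1]]

  lines <- character()
  for (m in seq_len(n_models)) {
    xyz <- cbind(3.8 * seq_len(n_res), 0, 0)
    # axis-aligned offsets keep coordinates exact at the PDB's 3-decimal
    # precision, so planted distances (given to <= 3 decimals) are realized
    # exactly; the rotating axis choice avoids coordinate collisions
    dirs <- list(c(0, 1, 0), c(0, 0, 1), c(0, -1, 0), c(0, 0, -1))
    for (i in seq_len(nrow(plan))) {
      dir <- dirs[[(i - 1L) %% 4L + 1L]]
      xyz[plan$res_b[i], ] <- xyz[plan$res_a[i], ] + plan[[dcols[m]]][i] * dir
    }
    lines <- c(lines, sprintf("MODEL     %4d", m),
               sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       seq_len(n_res), .AA3[ch], chain, seq_len(n_res),
                       xyz[, 1], xyz[, 2], xyz[, 3]),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  list(path = path, models = read_structure(path), planted = plan)
}
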