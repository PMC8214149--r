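# MS2 signature-ion pair detection and MS3 peptide-spectrum matching with
# remnant modifications, neutral loss and site-localization ambiguity.

#' Search tolerances
#'
#' @param ppm Precursor / signature-pair tolerance in ppm (default 20).
#' @param ms3_window MS3 fragment matching window in Da (default 0.6).
#' @param floor_score Minimum PSM score for a spectrum to count as
#'   identified (-log10 binomial tail; default 2, i.e. P < 0.01).
#' @param tie_tol Score-tie tolerance defining the site ambiguity set.
#' @return List of class \code{tolerances}.
#' @export
tolerances <- function(ppm = 20, ms3_window = 0.6, floor_score = 2,
                       tie_tol = 0.01) {
  stopifnot(ppm > 0, ms3_window > 0)
  structure(list(ppm = ppm, ms3_window = ms3_window,
                 floor_score = floor_score, tie_tol = tie_tol),
            class = "tolerances")
}

#' Candidate fragment charges for an MS2 spectrum's peaks
#'
#' When the spectrum dialect does not carry per-peak charges, every peak
#' receives candidate charges 1..(precursor charge - 1).
#'
#' @param spectrum An \code{msn_spectrum} (MS2, precursor charge known).
#' @param max_z Optional cap on the hypothesized fragment charge.
#' @return List (one element per peak) of integer charge vectors.
#' @export
assign_charges <- function(spectrum, max_z = NULL) {
  if (!length(spectrum$mz)) return(list())
  zmax <- spectrum$precursor_z - 1L
  if (!is.null(max_z)) zmax <- min(zmax, max_z)
  zs <- seq_len(max(zmax, 1L))
  rep(list(zs), length(spectrum$mz))
}

#' Detect cleavable cross-linker signature fragment pairs in an MS2 spectrum
#'
#' Finds all peak pairs (over all fragment-charge hypotheses) whose neutral
#' masses reconstruct the precursor: A+S pairs sum to the precursor neutral
#' mass M, A+T pairs (dehydrated thiol) to M - 18.010565. For the symmetric
#' DSSO, same-peptide alkene/thiol doublets separated by 31.9721 Da are
#' detected and used to corroborate pairs sharing a doublet peak.
#'
#' @param spectrum MS2 \code{msn_spectrum} with precursor m/z and charge.
#' @param linker \code{crosslinker_spec} or name.
#' @param tol A \code{\link{tolerances}} object.
#' @return data.frame with one row per pair: peak indices and charges of the
#'   two members (\code{peak_i} the lower m/z), \code{pair_type}
#'   (\code{"A+S"} / \code{"A+T"}), \code{error_ppm}, \code{corroborated}.
#' @export
find_signature_pairs <- function(spectrum, linker, tol = tolerances()) {
  if (is.character(linker)) linker <- get_linker(linker)
  empty <- data.frame(peak_i = integer(), z_i = integer(),
                      peak_j = integer(), z_j = integer(),
                      pair_type = character(), error_ppm = numeric(),
                      corroborated = logical())
  np <- length(spectrum$mz)
  if (np < 2L || is.na(spectrum$precursor_mz)) return(empty)
  M <- neutral_mass(spectrum$precursor_mz, spectrum$precursor_z)
  zhyp <- assign_charges(spectrum)
  cand <- do.call(rbind, lapply(seq_len(np), function(i) {
    data.frame(peak = i, z = zhyp[[i]],
               neutral = neutral_mass(spectrum$mz[i], zhyp[[i]]))
  }))
  cand <- cand[order(cand$neutral), ]
  nv <- cand$neutral
  abs_tol <- M * tol$ppm * 1e-6
  rows <- list()
  for (target in c("A+S", "A+T")) {
    Msum <- if (target == "A+S") M else M - WATER_MASS
    for (a in seq_len(nrow(cand))) {
      want <- Msum - nv[a]
      lo <- findInterval(want - abs_tol, nv)
      hi <- findInterval(want + abs_tol, nv)
      if (hi <= lo) next
      for (b in (lo + 1L):hi) {
        if (cand$peak[b] == cand$peak[a]) next
        if (cand$peak[a] > cand$peak[b]) next  # emit each pair once, i < j
        # charge conservation: the two fragments of one precursor molecule
        # carry all of its protons, so their charges sum to the precursor's
        if (cand$z[a] + cand$z[b] != spectrum$precursor_z) next
        rows[[length(rows) + 1L]] <- data.frame(
          peak_i = cand$peak[a], z_i = cand$z[a],
          peak_j = cand$peak[b], z_j = cand$z[b],
          pair_type = target,
          error_ppm = (nv[a] + nv[b] - Msum) / Msum * 1e6,
          corroborated = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  pairs <- unique(do.call(rbind, rows))
  if (linker$symmetric) {
    # alkene/thiol doublets on the same constituent: neutral difference of
    # one sulfur at the same charge hypothesis
    smass <- mono_mass("S")
    doublet_peaks <- integer()
    for (a in seq_len(nrow(cand))) {
      want <- nv[a] + smass
      lo <- findInterval(want - abs_tol, nv)
      hi <- findInterval(want + abs_tol, nv)
      if (hi > lo) {
        hits <- (lo + 1L):hi
        hits <- hits[cand$z[hits] == cand$z[a] & cand$peak[hits] != cand$peak[a]]
        if (length(hits)) {
          doublet_peaks <- c(doublet_peaks, cand$peak[a], cand$peak[hits])
        }
      }
    }
    pairs$corroborated <- pairs$peak_i %in% doublet_peaks |
      pairs$peak_j %in% doublet_peaks
  }
  rownames(pairs) <- NULL
  pairs
}

#' Score a candidate peptide against an MS3 spectrum
#'
#' Theoretical singly-protonated b/y ions (with -H2O neutral-loss
#' companions for sulfenic-carrying fragments) are matched to observed
#' peaks within the MS3 window. The score is the -log10 binomial tail
#' probability of matching at least the observed number of ions by chance,
#' with per-ion match probability equal to the covered m/z fraction
#' (2 x window x peak count / spectrum span).
#'
#' @param ms3 MS3 \code{msn_spectrum}.
#' @param candidate A \code{modified_peptide}.
#' @param tol A \code{\link{tolerances}} object.
#' @return List of class \code{psm}: candidate, score, matched ion count,
#'   theoretical ion count, remnant site, decoy flag.
#' @export
score_psm <- function(ms3, candidate, tol = tolerances()) {
  has_sulf <- any(candidate$mods$name == "sulfenic")
  ions <- fragment_ions(candidate, neutral_loss = has_sulf)
  theo <- mz(ions$mass, 1L)
  n <- length(theo)
  obs <- ms3$mz  # sorted on construction
  k <- if (length(obs)) {
    i <- findInterval(theo, obs)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(obs))
    sum(abs(obs[lo] - theo) <= tol$ms3_window |
          abs(obs[hi] - theo) <= tol$ms3_window)
  } else 0L
  span <- if (length(obs) >= 2L) max(obs) - min(obs) else 0
  p <- if (span > 0) min(0.99, length(obs) * 2 * tol$ms3_window / span) else 0.5
  score <- if (k == 0L) 0 else
    -stats::pbinom(k - 1L, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
  remsite <- candidate$mods$pos[candidate$mods$name %in%
                                  c("alkene", "sulfenic", "thiol")]
  structure(list(scan = ms3$scan, parent_scan = ms3$parent_scan,
                 candidate = candidate, score = score, matched = k,
                 n_theoretical = n,
                 site = if (length(remsite)) remsite[1] else NA_integer_,
                 is_decoy = candidate$is_decoy),
            class = "psm")
}

#' Retain the best PSM of a spectrum with its site-ambiguity set
#'
#' Among all scored candidates of one MS3 spectrum, the top-scoring peptide
#' is retained; its ambiguity set collects the remnant positions of
#' same-sequence positional isomers whose score is within the tie
#' tolerance. Spectra whose best score falls below the floor are reported
#' as unidentified (\code{NULL}).
#'
#' @param psms List of \code{psm} objects for one spectrum.
#' @param tol A \code{\link{tolerances}} object.
#' @return The best \code{psm} augmented with \code{ambiguity} (integer
#'   positions) and \code{ambiguity_res} (their residue letters), or
#'   \code{NULL} if nothing clears the floor score.
#' @export
localize_site <- function(psms, tol = tolerances()) {
  if (!length(psms)) return(NULL)
  scores <- vapply(psms, `[[`, numeric(1), "score")
  best <- psms[[which.max(scores)]]
  if (best$score < tol$floor_score) return(NULL)
  same <- vapply(psms, function(p) {
    identical(p$candidate$sequence, best$candidate$sequence) &&
      isTRUE(all.equal(sum(p$candidate$mods$mass), sum(best$candidate$mods$mass)))
  }, logical(1))
  tied <- same & scores >= best$score - tol$tie_tol
  amb <- sort(unique(vapply(psms[tied], `[[`, integer(1), "site")))
  amb <- amb[!is.na(amb)]
  best$ambiguity <- amb
  best$ambiguity_res <- strsplit(best$candidate$sequence, "")[[1]][amb]
  best
}

# ---------------------------------------------------------------------------
# Candidate generation + full search over a run

# Enumerate candidates whose precursor-level mass model matches `target`:
# side A (alkene@K), side B (sulfenic/thiol@X), and intralink fragments
# (alkene@K + thiol@X on one peptide).
.ms3_candidates <- function(idx, linker, target, ppm) {
  out <- candidate_peptides(idx, linker, "A", target, ppm)
  out <- c(out, candidate_peptides(idx, linker, "B", target, ppm))
  # intralink fragment model: peptide + alkene + thiol
  add <- linker$alkene$mono_mass + linker$thiol$mono_mass
  tolm <- target * ppm * 1e-6
  hit <- which(abs(idx$mass + add - target) <= tolm)
  for (i in hit) {
    ch <- strsplit(idx$sequence[i], "")[[1]]
    kp <- .alkene_positions(idx$sequence[i], idx$at_protein_cterm[i])
    xs <- which(ch %in% linker$end_b_targets)
    for (k in kp) for (x in setdiff(xs, k)) {
      out[[length(out) + 1L]] <- modified_peptide(
        idx$sequence[i],
        mods = data.frame(pos = c(k, x), name = c("alkene", "thiol"),
                          mass = c(linker$alkene$mono_mass, linker$thiol$mono_mass)),
        protein = idx$accession[i], start = idx$start[i],
        is_decoy = idx$is_decoy[i])
    }
  }
  out
}

.psm_moiety <- function(p) {
  nm <- p$candidate$mods$name[p$candidate$mods$name %in%
                                c("alkene", "sulfenic", "thiol")]
  paste(sort(nm), collapse = "+")
}

#' Search an MSn run against a protein database
#'
#' Runs MS2 signature-pair detection on every MS2 spectrum and MS3
#' peptide-spectrum matching (with site localization) on every MS3
#' spectrum, against a concatenated target-decoy database.
#'
#' @param spectra List of \code{msn_spectrum} (levels 2 and 3).
#' @param db Protein data.frame (targets + decoys) or a prebuilt
#'   \code{digest_index}.
#' @param linker \code{crosslinker_spec} or name.
#' @param tol A \code{\link{tolerances}} object.
#' @param params Digestion parameters (when \code{db} is raw).
#' @return List with \code{pairs} (per-MS2 signature pairs, keyed data.frame
#'   with \code{ms2_scan}) and \code{psms} (one row per identified MS3).
#' @export
search_msn <- function(spectra, db, linker, tol = tolerances(),
                       params = digest_params()) {
  if (is.character(linker)) linker <- get_linker(linker)
  idx <- if (inherits(db, "digest_index")) db else build_digest_index(db, params)
  pair_rows <- list()
  psm_rows <- list()
  for (sp in spectra) {
    if (sp$ms_level == 2L) {
      pr <- find_signature_pairs(sp, linker, tol)
      if (nrow(pr)) {
        pr$ms2_scan <- sp$scan
        pr$mz_i <- sp$mz[pr$peak_i]
        pr$mz_j <- sp$mz[pr$peak_j]
        pair_rows[[length(pair_rows) + 1L]] <- pr
      }
    } else if (sp$ms_level == 3L) {
      target <- neutral_mass(sp$precursor_mz, sp$precursor_z)
      cands <- .ms3_candidates(idx, linker, target, tol$ppm)
      if (!length(cands)) next
      scored <- lapply(cands, function(cd) score_psm(sp, cd, tol))
      best <- localize_site(scored, tol)
      if (is.null(best)) next
      psm_rows[[length(psm_rows) + 1L]] <- data.frame(
        scan = best$scan, parent_scan = best$parent_scan,
        precursor_mz = sp$precursor_mz, precursor_z = sp$precursor_z,
        sequence = best$candidate$sequence,
        protein = best$candidate$protein, start = best$candidate$start,
        moiety = .psm_moiety(best), site = best$site,
        ambiguity = paste(best$ambiguity, collapse = ","),
        n_ambiguous = length(best$ambiguity),
        score = best$score, matched = best$matched,
        n_theoretical = best$n_theoretical, is_decoy = best$is_decoy)
    }
  }
  list(
    pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(peak_i = integer(), z_i = integer(), peak_j = integer(),
                 z_j = integer(), pair_type = character(),
                 error_ppm = numeric(), corroborated = logical(),
                 ms2_scan = integer(), mz_i = numeric(), mz_j = numeric()),
    psms = if (length(psm_rows)) do.call(rbind, psm_rows) else
      data.frame(scan = integer(), parent_scan = integer(),
                 precursor_mz = numeric(), precursor_z = integer(),
                 sequence = character(), protein = character(),
                 start = integer(), moiety = character(), site = integer(),
                 ambiguity = character(), n_ambiguous = integer(),
                 score = numeric(), matched = integer(),
                 n_theoretical = integer(), is_decoy = logical()))
}
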