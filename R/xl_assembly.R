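# Integration of MS1/MS2/MS3 evidence into cross-link identifications,
# species classification, target-decoy FDR, redundancy collapse to unique
# peptide pairs and residue linkages, and replicate-overlap metrics.

.empty_xlid <- function() {
  data.frame(kind = character(), linker = character(),
             alpha_seq = character(), alpha_protein = character(),
             alpha_start = integer(), alpha_site = integer(),
             alpha_res = integer(),
             beta_seq = character(), beta_protein = character(),
             beta_start = integer(), beta_site = integer(),
             beta_res = integer(), beta_ambiguity = character(),
             beta_amb_res = character(), n_beta_amb = integer(),
             score = numeric(), ppm_error = numeric(),
             is_decoy = logical(), ms2_scan = integer())
}

# ppm between a mass model and the MS2 precursor neutral mass
.ppm <- function(model_mass, M) (model_mass - M) / M * 1e6

#' Assemble cross-link identifications from MSn evidence
#'
#' Joins MS2 signature pairs with the MS3 identifications of their member
#' fragments (matched by MS3 precursor m/z) into interlinks, enforcing
#' precursor-mass consistency (sum of both plain peptide masses + intact
#' bridge vs the MS2 precursor) at the ppm tolerance. MS2 spectra with a
#' single identified fragment are classified as dead-end (peptide + bridge
#' + water precursor model; named for the hydrolyzed end) or intralink
#' (peptide + bridge; fragment carries alkene + thiol). The alkene-carrying
#' side is reported as alpha (the lysine/NHS side); the combined interlink
#' score is the smaller of the two constituent scores.
#'
#' @param spectra The searched spectra (to recover MS2 precursors).
#' @param search Result of \code{\link{search_msn}} (\code{pairs} +
#'   \code{psms}).
#' @param linker \code{crosslinker_spec} or name.
#' @param tol A \code{\link{tolerances}} object.
#' @return data.frame of cross-link identifications, one row per MS2 scan
#'   with resolved evidence (columns as in the package's TSV export).
#' @export
assemble <- function(spectra, search, linker, tol = tolerances()) {
  if (is.character(linker)) linker <- get_linker(linker)
  psms <- search$psms
  pairs <- search$pairs
  ms2 <- Filter(function(s) s$ms_level == 2L, spectra)
  out <- list()
  for (sp in ms2) {
    ch <- psms[!is.na(psms$parent_scan) & psms$parent_scan == sp$scan, ,
               drop = FALSE]
    if (!nrow(ch)) next
    M <- neutral_mass(sp$precursor_mz, sp$precursor_z)
    res <- NULL

    # --- interlink: a signature pair with both member fragments identified
    pp <- pairs[pairs$ms2_scan == sp$scan, , drop = FALSE]
    if (nrow(pp) && nrow(ch) >= 2L) {
      match_child <- function(mzval) {
        d <- abs(ch$precursor_mz - mzval)
        i <- which.min(d)
        if (length(i) && d[i] / mzval <= 2 * tol$ppm * 1e-6) i else NA_integer_
      }
      for (q in seq_len(nrow(pp))) {
        ci <- match_child(pp$mz_i[q])
        cj <- match_child(pp$mz_j[q])
        if (is.na(ci) || is.na(cj) || ci == cj) next
        a <- ch[ci, ]; b <- ch[cj, ]
        mo <- c(a$moiety, b$moiety)
        if (sum(mo == "alkene") != 1L ||
            sum(mo %in% c("sulfenic", "thiol")) != 1L) next
        if (b$moiety == "alkene") { tmp <- a; a <- b; b <- tmp }
        plain <- function(s) peptide_mass(modified_peptide(s))
        model <- plain(a$sequence) + plain(b$sequence) + bridge_mass(linker)
        err <- .ppm(model, M)
        if (abs(err) > tol$ppm) next
        amb <- as.integer(strsplit(b$ambiguity, ",")[[1]])
        res <- data.frame(
          kind = "interlink", linker = linker$name,
          alpha_seq = a$sequence, alpha_protein = a$protein,
          alpha_start = a$start, alpha_site = a$site,
          alpha_res = a$start + a$site - 1L,
          beta_seq = b$sequence, beta_protein = b$protein,
          beta_start = b$start, beta_site = b$site,
          beta_res = b$start + b$site - 1L,
          beta_ambiguity = b$ambiguity,
          beta_amb_res = paste(b$start + amb - 1L, collapse = ","),
          n_beta_amb = b$n_ambiguous,
          score = min(a$score, b$score), ppm_error = err,
          is_decoy = a$is_decoy || b$is_decoy, ms2_scan = sp$scan)
        break
      }
    }

    # --- single-fragment species: dead-end or intralink mass models
    if (is.null(res)) {
      best <- ch[which.max(ch$score), ]
      plain_m <- peptide_mass(modified_peptide(best$sequence))
      err_de <- .ppm(plain_m + bridge_mass(linker) + WATER_MASS, M)
      err_il <- .ppm(plain_m + bridge_mass(linker), M)
      amb <- as.integer(strsplit(best$ambiguity, ",")[[1]])
      if (best$moiety == "alkene+thiol" && abs(err_il) <= tol$ppm) {
        res <- data.frame(
          kind = "intralink", linker = linker$name,
          alpha_seq = best$sequence, alpha_protein = best$protein,
          alpha_start = best$start, alpha_site = best$site,
          alpha_res = best$start + best$site - 1L,
          beta_seq = NA_character_, beta_protein = best$protein,
          beta_start = best$start, beta_site = NA_integer_,
          beta_res = NA_integer_,
          beta_ambiguity = best$ambiguity,
          beta_amb_res = paste(best$start + amb - 1L, collapse = ","),
          n_beta_amb = best$n_ambiguous,
          score = best$score, ppm_error = err_il,
          is_decoy = best$is_decoy, ms2_scan = sp$scan)
      } else if (best$moiety %in% c("alkene", "sulfenic", "thiol") &&
                 abs(err_de) <= tol$ppm) {
        res <- data.frame(
          kind = if (best$moiety == "alkene") "deadend_diazirine_hydrolyzed"
                 else "deadend_nhs_hydrolyzed",
          linker = linker$name,
          alpha_seq = best$sequence, alpha_protein = best$protein,
          alpha_start = best$start, alpha_site = best$site,
          alpha_res = best$start + best$site - 1L,
          beta_seq = NA_character_, beta_protein = NA_character_,
          beta_start = NA_integer_, beta_site = NA_integer_,
          beta_res = NA_integer_,
          beta_ambiguity = best$ambiguity,
          beta_amb_res = paste(best$start + amb - 1L, collapse = ","),
          n_beta_amb = best$n_ambiguous,
          score = best$score, ppm_error = err_de,
          is_decoy = best$is_decoy, ms2_scan = sp$scan)
      }
    }
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  if (!length(out)) return(.empty_xlid())
  ids <- do.call(rbind, out)
  rownames(ids) <- NULL
  ids
}

#' Target-decoy FDR filtering of cross-link identifications
#'
#' Identifications are ranked by score; the applied cut is the most
#' permissive one at which the decoy-based estimate
#' FDR = (decoy-containing IDs) / (target IDs) stays at or below the
#' threshold.
#'
#' @param ids Assembled identifications (with \code{is_decoy}).
#' @param threshold Maximum FDR as a fraction (default 0.01).
#' @return List with \code{ids} (the filtered target identifications,
#'   decoys removed), \code{fdr_percent} (estimate at the cut) and
#'   \code{n_decoy}, \code{n_target} at the cut.
#' @export
fdr_filter <- function(ids, threshold = 0.01) {
  if (!nrow(ids)) stop("no identifications to filter")
  if (!any(!ids$is_decoy)) stop("no target identifications; FDR undefined")
  o <- order(ids$score, decreasing = TRUE)
  dec <- cumsum(ids$is_decoy[o])
  tgt <- cumsum(!ids$is_decoy[o])
  fdr <- ifelse(tgt > 0, dec / tgt, Inf)
  keep_n <- max(c(0L, which(fdr <= threshold)))
  if (keep_n == 0L) {
    return(list(ids = ids[0, ], fdr_percent = NA_real_,
                n_decoy = 0L, n_target = 0L))
  }
  sel <- o[seq_len(keep_n)]
  list(ids = ids[sel[!ids$is_decoy[sel]], ],
       fdr_percent = 100 * fdr[keep_n],
       n_decoy = dec[keep_n], n_target = tgt[keep_n])
}

#' Compute the decoy-based FDR of a fixed identification list
#'
#' @param ids Identifications.
#' @return FDR as a percentage (decoys / targets x 100).
#' @export
fdr_estimate <- function(ids) {
  n_t <- sum(!ids$is_decoy)
  if (n_t == 0L) stop("no target identifications; FDR undefined")
  100 * sum(ids$is_decoy) / n_t
}

.linkage_key <- function(ids) {
  beta <- ifelse(is.na(ids$beta_res) & nzchar(ids$beta_amb_res %||% ""),
                 ids$beta_amb_res, as.character(ids$beta_res))
  amb <- strsplit(ids$beta_amb_res, ",")
  interval <- vapply(seq_along(amb), function(i) {
    v <- suppressWarnings(as.integer(amb[[i]]))
    v <- v[!is.na(v)]
    if (!length(v)) return(as.character(ids$beta_res[i]))
    if (length(v) == 1L) as.character(v) else
      sprintf("%d-%d", min(v), max(v))
  }, character(1))
  paste0(ids$alpha_protein, ":K", ids$alpha_res, "--",
         ids$beta_protein, ":X(", interval, ")")
}

#' Collapse identifications to unique peptide pairs and residue linkages
#'
#' Sequence-level collapse ignores site localization (unordered pair of
#' peptide sequences). Linkage-level collapse maps peptide-relative
#' ambiguity sets to protein residue intervals, giving K-X linkages in the
#' notation \code{P1:K155--P2:X(128-131)}.
#'
#' @param ids Identifications (typically interlinks after FDR filtering).
#' @return List with \code{sequences} (data.frame \code{key}, \code{n_spectra})
#'   and \code{linkages} (data.frame \code{key}, \code{alpha_protein},
#'   \code{alpha_res}, \code{beta_protein}, \code{beta_res_min},
#'   \code{beta_res_max}, \code{n_spectra}).
#' @export
collapse_ids <- function(ids) {
  inter <- ids[ids$kind == "interlink", , drop = FALSE]
  if (!nrow(inter)) {
    return(list(sequences = data.frame(key = character(), n_spectra = integer()),
                linkages = data.frame(key = character(),
                                      alpha_protein = character(),
                                      alpha_res = integer(),
                                      beta_protein = character(),
                                      beta_res_min = integer(),
                                      beta_res_max = integer(),
                                      n_spectra = integer())))
  }
  seq_key <- vapply(seq_len(nrow(inter)), function(i) {
    paste(sort(c(inter$alpha_seq[i], inter$beta_seq[i])), collapse = "|")
  }, character(1))
  seq_tab <- as.data.frame(table(key = seq_key), stringsAsFactors = FALSE)
  names(seq_tab)[2] <- "n_spectra"

  lkey <- .linkage_key(inter)
  amb <- lapply(strsplit(inter$beta_amb_res, ","), function(v) {
    v <- suppressWarnings(as.integer(v)); v[!is.na(v)]
  })
  bmin <- vapply(seq_along(amb), function(i) {
    if (length(amb[[i]])) min(amb[[i]]) else inter$beta_res[i]
  }, integer(1))
  bmax <- vapply(seq_along(amb), function(i) {
    if (length(amb[[i]])) max(amb[[i]]) else inter$beta_res[i]
  }, integer(1))
  ldf <- data.frame(key = lkey, alpha_protein = inter$alpha_protein,
                    alpha_res = inter$alpha_res,
                    beta_protein = inter$beta_protein,
                    beta_res_min = bmin, beta_res_max = bmax)
  agg <- ldf[!duplicated(ldf$key), , drop = FALSE]
  agg$n_spectra <- as.integer(table(ldf$key)[agg$key])
  agg <- agg[order(agg$key), ]
  rownames(agg) <- NULL
  list(sequences = seq_tab, linkages = agg)
}

#' Replicate-overlap metrics
#'
#' Given per-replicate sets of identifications (character vectors of
#' sequence or linkage keys), reports three overlap readings: the fraction
#' of the union found in at least two replicates, the fraction found in all
#' replicates, and the mean pairwise Jaccard index.
#'
#' @param replicates List (length >= 2) of character vectors.
#' @return List with \code{frac_ge2}, \code{frac_all}, \code{jaccard_mean},
#'   \code{jaccard_matrix}.
#' @export
replicate_overlap <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least two replicates")
  replicates <- lapply(replicates, unique)
  univ <- unique(unlist(replicates))
  counts <- rowSums(vapply(replicates, function(r) univ %in% r,
                           logical(length(univ))))
  nrep <- length(replicates)
  jm <- matrix(1, nrep, nrep)
  for (i in seq_len(nrep - 1L)) for (j in (i + 1L):nrep) {
    u <- length(union(replicates[[i]], replicates[[j]]))
    jm[i, j] <- jm[j, i] <-
      if (u == 0L) 0 else length(intersect(replicates[[i]], replicates[[j]])) / u
  }
  list(frac_ge2 = if (length(univ)) mean(counts >= 2L) else 0,
       frac_all = if (length(univ)) mean(counts == nrep) else 0,
       jaccard_mean = mean(jm[upper.tri(jm)]),
       jaccard_matrix = jm)
}

#' Export residue linkages as xiNET-compatible CSV
#'
#' @param linkages The \code{linkages} table from \code{\link{collapse_ids}}.
#' @param path Output CSV path.
#' @export
export_xinet <- function(linkages, path) {
  df <- data.frame(Protein1 = linkages$alpha_protein,
                   Protein2 = linkages$beta_protein,
                   Res1 = linkages$alpha_res,
                   Res2 = linkages$beta_res_min,
                   Score = linkages$n_spectra)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cross-link identifications as TSV
#' @param ids Identification data.frame.
#' @param path Output path.
#' @export
write_ids_tsv <- function(ids, path) {
  utils::write.table(ids, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
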