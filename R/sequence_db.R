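# FASTA I/O, in-silico protease digestion, decoy construction, and candidate
# modified-peptide enumeration against a precursor mass window.

.DECOY_PREFIX <- "DECOY_"

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @param strict If \code{TRUE} (default) non-standard residue letters are an
#'   error; if \code{FALSE} records containing them are dropped with a warning.
#' @return data.frame with columns \code{accession}, \code{sequence},
#'   \code{is_decoy}. Sequences are uppercased; accession is the first
#'   whitespace-delimited token of the header. Duplicate accessions error.
#' @export
read_fasta <- function(path, strict = TRUE) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  ok <- grepl("^[GASPVTCLINDQKEMHFRYW]+$", sq)
  if (!all(ok)) {
    if (strict) stop("illegal residue characters in record(s): ",
                     paste(acc[!ok], collapse = ", "))
    warning("dropping ", sum(!ok), " record(s) with illegal residues")
    acc <- acc[ok]; sq <- sq[ok]
  }
  data.frame(accession = acc, sequence = unname(sq),
             is_decoy = startsWith(acc, .DECOY_PREFIX))
}

#' Write a protein database as FASTA
#' @param db data.frame as from \code{\link{read_fasta}}.
#' @param path Output path.
#' @export
write_fasta <- function(db, path) {
  x <- Biostrings::AAStringSet(stats::setNames(db$sequence, db$accession))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Digestion parameters
#'
#' Trypsin cleaves C-terminal to K/R, chymotrypsin C-terminal to F/W/Y/L;
#' neither cleaves before proline. Defaults follow the search settings used
#' throughout the package: 3 missed cleavages for trypsin, 4 for
#' chymotrypsin, peptide length 4-50.
#'
#' @param enzyme \code{"trypsin"} or \code{"chymotrypsin"}.
#' @param max_missed Maximum missed cleavages (default 3 / 4 by enzyme).
#' @param min_length,max_length Peptide length bounds (residues).
#' @return A list of class \code{digest_params}.
#' @export
digest_params <- function(enzyme = c("trypsin", "chymotrypsin"),
                          max_missed = NULL, min_length = 4L,
                          max_length = 50L) {
  enzyme <- match.arg(enzyme)
  if (is.null(max_missed)) {
    max_missed <- if (enzyme == "trypsin") 3L else 4L
  }
  stopifnot(max_missed >= 0L, min_length >= 1L, max_length >= min_length)
  structure(list(enzyme = enzyme, max_missed = as.integer(max_missed),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_params")
}

.cleavage_residues <- function(enzyme) {
  switch(enzyme, trypsin = c("K", "R"), chymotrypsin = c("F", "W", "Y", "L"),
         stop("unknown enzyme '", enzyme, "'"))
}

# 0-based cut positions after residue i (i in 1..n-1), excluding before-P.
.cut_sites <- function(sequence, enzyme) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  i[ch[i] %in% .cleavage_residues(enzyme) & ch[i + 1L] != "P"]
}

#' In-silico digestion of one protein
#'
#' Enumerates all peptides obeying the cleavage rule with 0..max_missed
#' missed cleavages, filtered by length. Spans are 1-based inclusive.
#'
#' @param sequence Protein sequence string (or a single-row db data.frame).
#' @param params A \code{\link{digest_params}} object.
#' @return data.frame with columns \code{start}, \code{end}, \code{sequence},
#'   \code{missed}.
#' @export
digest <- function(sequence, params = digest_params()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  n <- nchar(sequence)
  cuts <- .cut_sites(sequence, params$enzyme)
  bounds <- c(0L, cuts, n)            # segment boundaries
  ns <- length(bounds) - 1L           # number of fully-cleaved segments
  out <- list()
  k <- 0L
  for (i in seq_len(ns)) {
    jmax <- min(ns, i + params$max_missed)
    for (j in i:jmax) {
      st <- bounds[i] + 1L
      en <- bounds[j + 1L]
      len <- en - st + 1L
      if (len < params$min_length || len > params$max_length) next
      k <- k + 1L
      out[[k]] <- c(st, en, j - i)
    }
  }
  if (k == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), missed = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2],
             sequence = substring(sequence, m[, 1], m[, 2]),
             missed = m[, 3])
}

#' Build a concatenated target-decoy database
#'
#' One decoy per target, the sequence randomly shuffled (or reversed) with
#' the given seed; same length and residue composition. Decoy accessions are
#' prefixed with \code{DECOY_}.
#'
#' @param db Target data.frame (\code{accession}, \code{sequence}).
#' @param seed Integer seed for the shuffle.
#' @param method \code{"shuffle"} (default) or \code{"reverse"}.
#' @return The concatenated target + decoy data.frame.
#' @export
make_decoys <- function(db, seed = 1L, method = c("shuffle", "reverse")) {
  method <- match.arg(method)
  if (any(db$is_decoy %||% FALSE)) stop("input must contain targets only")
  dec_seq <- if (method == "reverse") {
    vapply(db$sequence,
           function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE)
  } else NULL
  if (method == "shuffle") {
    old <- .Random.seed_exists()
    set.seed(seed)
    dec_seq <- vapply(db$sequence, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste(sample(ch), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  dec <- data.frame(accession = paste0(.DECOY_PREFIX, db$accession),
                    sequence = dec_seq, is_decoy = TRUE)
  tgt <- db
  tgt$is_decoy <- FALSE
  rbind(tgt, dec)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  } else NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a digest index over a protein database
#'
#' Digests every protein and precomputes unmodified peptide masses, lysine
#' positions and terminal flags, for fast candidate lookup.
#'
#' @param db Protein data.frame (targets, or concatenated target+decoy).
#' @param params A \code{\link{digest_params}}.
#' @return data.frame of class \code{digest_index} with one row per peptide
#'   occurrence: \code{accession}, \code{start}, \code{end}, \code{sequence},
#'   \code{missed}, \code{mass}, \code{is_decoy}, \code{at_protein_cterm}.
#' @export
build_digest_index <- function(db, params = digest_params()) {
  pieces <- lapply(seq_len(nrow(db)), function(i) {
    d <- digest(db$sequence[i], params)
    if (!nrow(d)) return(NULL)
    d$accession <- db$accession[i]
    d$is_decoy <- db$is_decoy[i] %||% FALSE
    d$at_protein_cterm <- d$end == nchar(db$sequence[i])
    d
  })
  idx <- do.call(rbind, pieces)
  if (is.null(idx)) stop("digestion produced no peptides")
  idx$mass <- vapply(idx$sequence, function(s) {
    sum(residue_mass(strsplit(s, "")[[1]])) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
  class(idx) <- c("digest_index", class(idx))
  idx
}

#' Export a digest index as TSV
#' @param idx A \code{digest_index}.
#' @param path Output path.
#' @export
write_digest_tsv <- function(idx, path) {
  utils::write.table(
    idx[, c("accession", "start", "end", "sequence", "missed")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate candidate remnant-modified peptides in a mass window
#'
#' Side \code{"A"} (NHS/lysine side) candidates carry the alkene remnant on
#' an uncleaved lysine: a K that is not the peptide C-terminus, unless the
#' peptide ends at the protein C-terminus. Side \code{"B"} (diazirine side)
#' candidates carry the sulfenic or thiol remnant; every residue position is
#' a possible site, so one candidate per position per moiety. Candidates are
#' filtered to \code{target_mass} within \code{ppm}.
#'
#' @param idx A \code{\link{build_digest_index}} result (or a db data.frame,
#'   which is indexed on the fly).
#' @param linker \code{crosslinker_spec} or name.
#' @param side \code{"A"} or \code{"B"}.
#' @param target_mass Neutral query mass (Da).
#' @param ppm Mass tolerance in parts per million (default 20).
#' @param moieties For side B, which remnants to consider
#'   (default both sulfenic and thiol).
#' @param params Digestion parameters when \code{idx} is a raw database.
#' @return List of \code{modified_peptide} candidates (possibly empty).
#' @export
candidate_peptides <- function(idx, linker, side = c("A", "B"),
                               target_mass, ppm = 20,
                               moieties = c("sulfenic", "thiol"),
                               params = digest_params()) {
  side <- match.arg(side)
  if (is.character(linker)) linker <- get_linker(linker)
  if (!inherits(idx, "digest_index")) idx <- build_digest_index(idx, params)
  tol <- target_mass * ppm * 1e-6
  out <- list()
  if (side == "A") {
    mods_mass <- linker$alkene$mono_mass
    hit <- which(abs(idx$mass + mods_mass - target_mass) <= tol)
    for (i in hit) {
      seqc <- strsplit(idx$sequence[i], "")[[1]]
      kpos <- which(seqc == "K")
      # remnant-blocked cleavage: modified K must be internal unless the
      # peptide ends at the protein C-terminus
      kpos <- kpos[kpos < length(seqc) | idx$at_protein_cterm[i]]
      for (kp in kpos) {
        out[[length(out) + 1L]] <- modified_peptide(
          idx$sequence[i],
          mods = data.frame(pos = kp, name = "alkene",
                            mass = linker$alkene$mono_mass),
          protein = idx$accession[i], start = idx$start[i],
          is_decoy = idx$is_decoy[i])
      }
    }
  } else {
    for (mo in moieties) {
      mods_mass <- linker[[mo]]$mono_mass
      hit <- which(abs(idx$mass + mods_mass - target_mass) <= tol)
      for (i in hit) {
        allowed <- which(strsplit(idx$sequence[i], "")[[1]] %in% linker$end_b_targets)
        for (pp in allowed) {
          out[[length(out) + 1L]] <- modified_peptide(
            idx$sequence[i],
            mods = data.frame(pos = pp, name = mo, mass = mods_mass),
            protein = idx$accession[i], start = idx$start[i],
            is_decoy = idx$is_decoy[i])
        }
      }
    }
  }
  out
}
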