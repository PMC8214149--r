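# Elemental-formula mass arithmetic, the cleavable-linker registry, and all
# peptide / fragment mass and m/z computation used by the rest of the package.

# Monoisotopic atomic masses (IUPAC), hard-coded to >= 6 decimals.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706912
)

#' Mass of a proton in Dalton
#' @export
PROTON_MASS <- 1.00728

#' Monoisotopic mass of water in Dalton
#' @export
WATER_MASS <- 18.010565

# Amino-acid residue elemental compositions (the residue, i.e. minus water).
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Parse an elemental formula string
#'
#' Parses strings such as \code{"C7H13NO2S"} into element counts. An omitted
#' count means 1. Only C, H, N, O and S are accepted (the elements occurring
#' in the linker remnants and amino-acid residues handled here).
#'
#' @param text Formula string, e.g. \code{"C3H2O"}.
#' @return An object of class \code{elemental_formula}: a named integer vector
#'   of element counts.
#' @examples
#' parse_formula("C3H2O")
#' mono_mass(parse_formula("C7H13NO2S"))
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text) || !grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("malformed elemental formula: '", text, "'")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(elems, names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, factor(elems, levels = names(.ATOMIC_MASS)), sum)
  out <- out[!is.na(out)]
  out <- stats::setNames(as.integer(out), names(out))
  if (sum(out) == 0L) stop("empty formula")
  structure(out, class = "elemental_formula")
}

#' Monoisotopic mass of an elemental formula
#'
#' @param f An \code{elemental_formula} (from \code{\link{parse_formula}}) or
#'   a formula string.
#' @return Monoisotopic mass in Dalton.
#' @export
mono_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(.ATOMIC_MASS[names(f)] * as.numeric(f))
}

# precomputed at build time; mono_mass over the composition table
.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, function(f) {
  m <- gregexpr("[A-Z][0-9]*", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]$", toks), sub("^[A-Z]", "", toks), "1"))
  sum(.ATOMIC_MASS[el] * ct)
}, numeric(1))

#' Monoisotopic residue masses
#'
#' @param residues Character vector of one-letter residue codes.
#' @return Numeric vector of residue (i.e. water-free) monoisotopic masses.
#' @export
residue_mass <- function(residues) {
  out <- .RESIDUE_MASS[residues]
  if (anyNA(out)) {
    stop("unknown residue letter(s): ",
         paste(unique(residues[is.na(out)]), collapse = ", "))
  }
  out
}

# ---------------------------------------------------------------------------
# Moieties and linkers

.moiety <- function(name, formula) {
  structure(list(name = name, formula = formula, mono_mass = mono_mass(formula)),
            class = "moiety")
}

.make_linker <- function(name, sulfenic_formula, thiol_formula, end_b_targets,
                         symmetric, spacer_len, max_ca_ca) {
  lk <- list(
    name = name,
    end_a_targets = "K",
    end_b_targets = end_b_targets,
    alkene   = .moiety("alkene", "C3H2O"),
    sulfenic = .moiety("sulfenic", sulfenic_formula),
    thiol    = .moiety("thiol", thiol_formula),
    symmetric = symmetric,
    spacer_len = spacer_len,
    max_ca_ca = max_ca_ca
  )
  # thiol is the dehydrated sulfenic acid, per linker
  stopifnot(abs(lk$thiol$mono_mass - (lk$sulfenic$mono_mass - WATER_MASS)) < 1e-6)
  class(lk) <- "crosslinker_spec"
  lk
}

.AA20 <- names(.RESIDUE_FORMULA)

.LINKER_REGISTRY <- new.env(parent = emptyenv())

.register_builtin_linkers <- function() {
  assign("DSSO",
         .make_linker("DSSO", "C3H4O2S", "C3H2SO", "K",
                      symmetric = TRUE, spacer_len = 10.3, max_ca_ca = 30),
         envir = .LINKER_REGISTRY)
  assign("SDASO-L",
         .make_linker("SDASO-L", "C7H13NO2S", "C7H11NOS", .AA20,
                      symmetric = FALSE, spacer_len = 12.5, max_ca_ca = 35),
         envir = .LINKER_REGISTRY)
  assign("SDASO-M",
         .make_linker("SDASO-M", "C5H10OS", "C5H8S", .AA20,
                      symmetric = FALSE, spacer_len = 10.2, max_ca_ca = 30),
         envir = .LINKER_REGISTRY)
  assign("SDASO-S",
         .make_linker("SDASO-S", "C4H8OS", "C4H6S", .AA20,
                      symmetric = FALSE, spacer_len = 7.7, max_ca_ca = 30),
         envir = .LINKER_REGISTRY)
}

#' Look up a registered cross-linker
#'
#' Four linkers are built in: \code{DSSO} (symmetric, amine-reactive both
#' ends) and the heterobifunctional NHS-diazirine linkers \code{SDASO-L},
#' \code{SDASO-M}, \code{SDASO-S} (lysine-reactive NHS end, photoactivated
#' diazirine end reacting with any residue). Each carries its alkene,
#' sulfenic-acid and thiol remnant moieties and a Calpha-Calpha distance
#' threshold (35 Angstrom for SDASO-L, 30 for the others).
#'
#' @param name Linker name.
#' @return A \code{crosslinker_spec} object.
#' @export
get_linker <- function(name) {
  if (!exists(name, envir = .LINKER_REGISTRY, inherits = FALSE)) {
    stop("unknown linker '", name, "'; registered: ",
         paste(list_linkers(), collapse = ", "))
  }
  get(name, envir = .LINKER_REGISTRY, inherits = FALSE)
}

#' @rdname get_linker
#' @export
list_linkers <- function() sort(ls(.LINKER_REGISTRY))

#' Register a cross-linker from a config-style description
#'
#' Allows users to add linkers without code changes. \code{spec} is a list
#' with fields \code{name}, \code{sulfenic}, \code{thiol} (elemental
#' formulas; the alkene end is always C3H2O), \code{end_b_targets} (residue
#' letters, or \code{"all"}), \code{symmetric}, \code{spacer_len},
#' \code{max_ca_ca}.
#'
#' @param spec A list as described (e.g. one block of a YAML config).
#' @return The registered \code{crosslinker_spec}, invisibly.
#' @export
register_linker <- function(spec) {
  targets <- spec$end_b_targets
  if (identical(targets, "all")) targets <- .AA20
  lk <- .make_linker(spec$name, spec$sulfenic, spec$thiol, targets,
                     isTRUE(spec$symmetric),
                     as.numeric(spec$spacer_len), as.numeric(spec$max_ca_ca))
  assign(spec$name, lk, envir = .LINKER_REGISTRY)
  invisible(lk)
}

#' @export
print.crosslinker_spec <- function(x, ...) {
  cat(sprintf("<crosslinker %s>%s\n", x$name,
              if (x$symmetric) " (symmetric)" else ""))
  cat(sprintf("  alkene   %-10s %9.4f Da\n", x$alkene$formula, x$alkene$mono_mass))
  cat(sprintf("  sulfenic %-10s %9.4f Da\n", x$sulfenic$formula, x$sulfenic$mono_mass))
  cat(sprintf("  thiol    %-10s %9.4f Da\n", x$thiol$formula, x$thiol$mono_mass))
  cat(sprintf("  bridge addition %.4f Da; max Calpha-Calpha %.0f A\n",
              bridge_mass(x), x$max_ca_ca))
  invisible(x)
}

#' Intact bridge mass addition of a linker
#'
#' The mass added to the summed peptide masses by an intact cross-link
#' bridge: alkene + sulfenic remnants.
#'
#' @param linker A \code{crosslinker_spec} or linker name.
#' @return Mass in Dalton.
#' @export
bridge_mass <- function(linker) {
  if (is.character(linker)) linker <- get_linker(linker)
  linker$alkene$mono_mass + linker$sulfenic$mono_mass
}

# ---------------------------------------------------------------------------
# Modified peptides

#' Construct a modified peptide
#'
#' A peptide sequence with positioned modifications; the unit of MS3
#' identification. At most one cross-link remnant (alkene / sulfenic /
#' thiol) may be present.
#'
#' @param sequence Residue string (standard 20 letters).
#' @param mods \code{NULL} or a data.frame with columns \code{pos}
#'   (1-based), \code{name}, \code{mass} (Da). For the three remnant names
#'   and the standard variable modifications \code{mass} may be \code{NA}
#'   and is filled in (remnants require \code{linker}).
#' @param linker Optional \code{crosslinker_spec} / name used to resolve
#'   remnant masses.
#' @param protein Optional protein accession the peptide maps to.
#' @param start Optional 1-based start offset within \code{protein}.
#' @param is_decoy Logical decoy flag.
#' @return An object of class \code{modified_peptide}.
#' @export
modified_peptide <- function(sequence, mods = NULL, linker = NULL,
                             protein = NA_character_, start = NA_integer_,
                             is_decoy = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  residue_mass(strsplit(sequence, "")[[1]])  # validates letters
  if (is.null(mods)) {
    mods <- data.frame(pos = integer(), name = character(), mass = numeric())
  } else {
    mods <- as.data.frame(mods)
    stopifnot(all(c("pos", "name") %in% names(mods)))
    if (is.null(mods$mass)) mods$mass <- NA_real_
    need <- is.na(mods$mass)
    if (any(need)) {
      mods$mass[need] <- vapply(mods$name[need], function(nm) {
        if (nm %in% c("alkene", "sulfenic", "thiol")) {
          if (is.null(linker)) stop("remnant mod '", nm, "' needs a linker")
          if (is.character(linker)) linker <- get_linker(linker)
          linker[[nm]]$mono_mass
        } else if (nm %in% names(.VARIABLE_MODS)) {
          .VARIABLE_MODS[[nm]]
        } else stop("unknown modification '", nm, "' without a mass")
      }, numeric(1))
    }
    if (any(mods$pos < 1L | mods$pos > nchar(sequence))) {
      stop("modification position out of range")
    }
    # one remnant per linker end: at most one alkene (NHS side) and at most
    # one sulfenic/thiol (diazirine side; both present only for intralinks)
    if (sum(mods$name == "alkene") > 1L ||
        sum(mods$name %in% c("sulfenic", "thiol")) > 1L) {
      stop("at most one cross-link remnant per linker end")
    }
  }
  structure(list(sequence = sequence, mods = mods,
                 protein = protein, start = as.integer(start),
                 is_decoy = isTRUE(is_decoy)),
            class = "modified_peptide")
}

# Standard variable modifications (masses from standard monoisotopic values).
.VARIABLE_MODS <- c(
  carbamidomethyl = 57.021464,   # C on Cys
  oxidation       = 15.994915,   # Met
  acetyl          = 42.010565,   # protein N-terminus
  pyro_glu        = -17.026549   # N-terminal Gln -> pyroGlu
)

#' Table of supported variable modifications
#' @return Named numeric vector of modification masses (Da).
#' @export
variable_mods <- function() .VARIABLE_MODS

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Residue-mass sum + water + the sum of modification masses.
#'
#' @param p A \code{modified_peptide}.
#' @return Neutral mass in Dalton.
#' @export
peptide_mass <- function(p) {
  if (is.character(p)) p <- modified_peptide(p)
  sum(residue_mass(strsplit(p$sequence, "")[[1]])) + WATER_MASS +
    sum(p$mods$mass)
}

#' @export
print.modified_peptide <- function(x, ...) {
  lab <- x$sequence
  if (nrow(x$mods)) {
    lab <- paste0(lab, " [", paste(sprintf("%s@%d", x$mods$name, x$mods$pos),
                                   collapse = ", "), "]")
  }
  cat(sprintf("<peptide %s  M = %.4f Da%s>\n", lab, peptide_mass(x),
              if (x$is_decoy) " decoy" else ""))
  invisible(x)
}

#' m/z of a neutral mass at charge z
#'
#' @param neutral_mass Neutral mass in Dalton.
#' @param z Positive integer charge.
#' @return (M + z * 1.00728) / z.
#' @export
mz <- function(neutral_mass, z) {
  if (any(z < 1)) stop("charge must be >= 1")
  (neutral_mass + z * PROTON_MASS) / z
}

#' Neutral mass from m/z at charge z
#' @param m m/z value.
#' @param z Positive integer charge.
#' @return Neutral mass in Dalton.
#' @export
neutral_mass <- function(m, z) {
  if (any(z < 1)) stop("charge must be >= 1")
  m * z - z * PROTON_MASS
}

#' Theoretical b/y fragment ions of a modified peptide
#'
#' Neutral b/y fragment masses with modifications assigned by position.
#' When \code{neutral_loss = TRUE}, every fragment containing a sulfenic
#' moiety also emits a companion 18.010565 Da lower, reflecting the
#' sulfenic-to-thiol dehydration observed alongside backbone fragmentation.
#'
#' @param p A \code{modified_peptide} (length >= 2).
#' @param series Character subset of \code{c("b", "y")}.
#' @param neutral_loss Emit -H2O companions for sulfenic-containing fragments.
#' @return data.frame with columns \code{ion}, \code{series}, \code{index},
#'   \code{mass} (neutral, Da).
#' @export
fragment_ions <- function(p, series = c("b", "y"), neutral_loss = FALSE) {
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  n <- nchar(p$sequence)
  if (n < 2L) stop("peptide too short to fragment")
  rm <- residue_mass(strsplit(p$sequence, "")[[1]])
  modv <- numeric(n)
  sulf <- logical(n)
  if (nrow(p$mods)) {
    for (i in seq_len(nrow(p$mods))) {
      modv[p$mods$pos[i]] <- modv[p$mods$pos[i]] + p$mods$mass[i]
      if (p$mods$name[i] == "sulfenic") sulf[p$mods$pos[i]] <- TRUE
    }
  }
  csum <- cumsum(rm + modv)
  csulf <- cumsum(sulf)
  out <- list()
  if ("b" %in% series) {
    i <- seq_len(n - 1L)
    out$b <- data.frame(ion = paste0("b", i), series = "b", index = i,
                        mass = csum[i], has_sulfenic = csulf[i] > 0L)
  }
  if ("y" %in% series) {
    j <- seq_len(n - 1L)
    out$y <- data.frame(ion = paste0("y", j), series = "y", index = j,
                        mass = csum[n] - csum[n - j] + WATER_MASS,
                        has_sulfenic = (csulf[n] - csulf[n - j]) > 0L)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (neutral_loss && any(res$has_sulfenic)) {
    nl <- res[res$has_sulfenic, ]
    nl$ion <- paste0(nl$ion, "-H2O")
    nl$mass <- nl$mass - WATER_MASS
    res <- rbind(res, nl)
  }
  res$has_sulfenic <- NULL
  res
}

#' Neutral mass of an intact cross-linked peptide pair
#'
#' Both peptides are given without remnants; the intact bridge contributes
#' alkene + sulfenic. On CID cleavage of the C-S bond the pair separates
#' into an alkene-modified and a sulfenic-modified chain whose masses sum
#' exactly to this value.
#'
#' @param alpha,beta \code{modified_peptide}s carrying no remnant mods.
#' @param linker A \code{crosslinker_spec} or linker name.
#' @return Neutral mass in Dalton.
#' @export
crosslinked_pair_mass <- function(alpha, beta, linker) {
  if (is.character(linker)) linker <- get_linker(linker)
  for (p in list(alpha, beta)) {
    if (any(p$mods$name %in% c("alkene", "sulfenic", "thiol"))) {
      stop("constituents of a cross-linked pair must not carry remnants")
    }
  }
  peptide_mass(alpha) + peptide_mass(beta) + bridge_mass(linker)
}
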