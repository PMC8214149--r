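# Mapping residue linkages onto structure models: Calpha-Calpha distances,
# satisfaction rates, state-specific classification, and the Euclidean
# random-distance null.

#' Read CA-level structure models from a PDB file
#'
#' Parses a (possibly multi-MODEL) PDB file and extracts the Calpha trace
#' of every model, preserving author chain ids and residue numbering.
#'
#' @param path PDB file path.
#' @param model_ids Optional character ids for the models (default
#'   \code{s1..sN}, the conventional naming for conformational states).
#' @param chain_map Optional named character vector mapping chain id to
#'   subunit name (stored as an attribute; unmapped chains are kept with a
#'   warning when a map is supplied).
#' @return List of \code{structure_model} objects, each with \code{id} and
#'   an \code{atoms} data.frame (\code{chain}, \code{resno}, \code{resid},
#'   \code{x}, \code{y}, \code{z}).
#' @export
read_structure <- function(path, model_ids = NULL, chain_map = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  if (!length(sel$atom)) stop("no CA atoms in ", path)
  at <- pdb$atom[sel$atom, c("chain", "resno", "resid")]
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  n_models <- nrow(xyz)
  if (is.null(model_ids)) model_ids <- paste0("s", seq_len(n_models))
  stopifnot(length(model_ids) == n_models)
  if (!is.null(chain_map)) {
    unmapped <- setdiff(unique(at$chain), names(chain_map))
    if (length(unmapped)) {
      warning("chains without subunit mapping: ",
              paste(unmapped, collapse = ", "))
    }
  }
  lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                        x = co[, 1], y = co[, 2], z = co[, 3])
    if (anyDuplicated(atoms[, c("chain", "resno")])) {
      stop("duplicate residue keys within a chain in ", path)
    }
    structure(list(id = model_ids[m], atoms = atoms,
                   chain_map = chain_map),
              class = "structure_model")
  })
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure model %s: %d CA atoms, chains %s>\n", x$id,
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

.ca_coord <- function(model, chain, resno) {
  i <- which(model$atoms$chain == chain & model$atoms$resno %in% resno)
  if (!length(i)) return(NULL)
  as.matrix(model$atoms[i, c("x", "y", "z")])
}

#' Calpha-Calpha Euclidean distance between two sites
#'
#' A site is a (chain, residue) pair; the residue may be an interval
#' (integer vector), in which case the minimum distance over the interval
#' is returned (the most permissive reading of an ambiguous localization).
#'
#' @param model A \code{structure_model}.
#' @param chain_a,res_a First site (residue scalar or vector).
#' @param chain_b,res_b Second site.
#' @return Distance in Angstrom, or \code{NA} if either site is unresolved.
#' @export
ca_distance <- function(model, chain_a, res_a, chain_b, res_b) {
  A <- .ca_coord(model, chain_a, res_a)
  B <- .ca_coord(model, chain_b, res_b)
  if (is.null(A) || is.null(B)) return(NA_real_)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Distance satisfaction of residue linkages across structure models
#'
#' Computes the Calpha-Calpha distance of each linkage in every model and
#' the per-model satisfaction rate at the linker's threshold (distance <=
#' max Calpha-Calpha counts as satisfied). Linkages unresolved in a model
#' are excluded from that model's denominator.
#'
#' @param linkages data.frame with \code{chain_a}, \code{res_a},
#'   \code{chain_b}, \code{beta_res_min}, \code{beta_res_max} (or
#'   \code{res_b}).
#' @param models List of \code{structure_model}.
#' @param linker \code{crosslinker_spec} or name (threshold source), or a
#'   numeric threshold in Angstrom.
#' @return List with \code{distances} (matrix linkage x model),
#'   \code{satisfied} (logical matrix), \code{rates} (per-model), and
#'   \code{mean_rate}.
#' @export
satisfaction <- function(linkages, models, linker) {
  thr <- if (is.numeric(linker)) linker else {
    if (is.character(linker)) linker <- get_linker(linker)
    linker$max_ca_ca
  }
  if (!length(models)) stop("need at least one structure model")
  if (is.null(linkages$res_b)) {
    linkages$res_b <- NA_integer_
  }
  D <- sapply(models, function(md) {
    vapply(seq_len(nrow(linkages)), function(i) {
      rb <- if (!is.na(linkages$res_b[i])) linkages$res_b[i] else
        seq(linkages$beta_res_min[i], linkages$beta_res_max[i])
      ca_distance(md, linkages$chain_a[i], linkages$res_a[i],
                  linkages$chain_b[i], rb)
    }, numeric(1))
  })
  D <- matrix(D, nrow = nrow(linkages),
              dimnames = list(NULL, vapply(models, `[[`, character(1), "id")))
  S <- D <= thr
  rates <- colMeans(S, na.rm = TRUE)
  if (all(is.na(D))) stop("no resolvable linkages on the supplied models")
  list(distances = D, satisfied = S, rates = rates,
       mean_rate = mean(rates, na.rm = TRUE), threshold = thr)
}

#' Classify linkages into state-specific satisfaction categories
#'
#' Given satisfaction flags over (normally four) models, linkages satisfied
#' by every model or by none are set aside; the remainder are state-specific
#' and fall into one of the 2^n - 2 proper non-empty subsets (14 categories
#' for four states), labelled by the satisfied models, e.g.
#' \code{"s1-s2-s3"}.
#'
#' @param sat Result of \code{\link{satisfaction}} (or a logical matrix of
#'   satisfied flags with model-id column names).
#' @return List with \code{category} (per linkage; \code{"all"},
#'   \code{"none"}, \code{NA} for unresolved-anywhere, or the subset
#'   label), \code{counts} (table over the proper subsets),
#'   \code{n_state_specific}.
#' @export
state_classify <- function(sat) {
  S <- if (is.list(sat) && !is.null(sat$satisfied)) sat$satisfied else sat
  nm <- colnames(S)
  n <- ncol(S)
  if (n != 4L) {
    warning("state classification generalized to ", 2^n - 2,
            " categories for ", n, " models")
  }
  category <- apply(S, 1, function(fl) {
    if (any(is.na(fl))) return(NA_character_)
    k <- sum(fl)
    if (k == n) "all" else if (k == 0L) "none" else
      paste(nm[fl], collapse = "-")
  })
  # all proper non-empty subsets, in size-then-position order
  subsets <- unlist(lapply(seq_len(n - 1L), function(k) {
    utils::combn(nm, k, paste, collapse = "-")
  }))
  counts <- table(factor(category[!category %in% c("all", "none")],
                         levels = subsets))
  list(category = category, counts = counts,
       n_state_specific = sum(counts))
}

#' Random cross-link distance null
#'
#' All lysine-to-any-residue Calpha Euclidean distances in a model, capped
#' at a maximum distance (100 Angstrom is appropriate for a single protein
#' the size of BSA, 300 Angstrom for an assembly the size of the 26S
#' proteasome); the solvent-path distance is deliberately not computed.
#'
#' @param model A \code{structure_model}.
#' @param cap Maximum distance retained (Angstrom).
#' @param bin Histogram bin width (default 5 Angstrom).
#' @return List with \code{distances} (numeric vector) and \code{histogram}
#'   (data.frame \code{lower}, \code{upper}, \code{count}).
#' @export
random_null <- function(model, cap = 300, bin = 5) {
  at <- model$atoms
  kidx <- which(at$resid == "LYS")
  if (!length(kidx)) stop("no lysines in model ", model$id)
  co <- as.matrix(at[, c("x", "y", "z")])
  d <- numeric(0)
  for (k in kidx) {
    dk <- sqrt(colSums((t(co) - co[k, ])^2))
    d <- c(d, dk[-k])
  }
  d <- d[d <= cap]
  if (length(d)) {
    br <- seq(0, bin * ceiling(max(d) / bin + 1), by = bin)
    h <- graphics::hist(d, breaks = br, plot = FALSE)
    hist_df <- data.frame(lower = utils::head(br, -1), upper = br[-1],
                          count = h$counts)
  } else {
    hist_df <- data.frame(lower = numeric(), upper = numeric(),
                          count = integer())
  }
  list(distances = d, histogram = hist_df)
}

#' Compare observed cross-link distances to the random null
#'
#' Two-sample Kolmogorov-Smirnov test of the observed distance sample
#' against the random-linkage distance distribution.
#'
#' @param observed Numeric vector of observed distances.
#' @param null Numeric vector of null distances (e.g.
#'   \code{random_null()$distances}).
#' @return List with \code{statistic} (D) and \code{p_value}.
#' @export
compare_to_null <- function(observed, null) {
  observed <- observed[is.finite(observed)]
  null <- null[is.finite(null)]
  if (!length(observed) || !length(null)) stop("degenerate distance samples")
  kt <- suppressWarnings(stats::ks.test(observed, null))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
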