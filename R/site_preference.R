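# Ambiguity-weighted amino-acid occurrence statistic for diazirine labeling
# and localization-precision summaries.

#' Ambiguity-weighted residue occurrence (Wx', Px)
#'
#' For a cross-linked peptide localized to \code{n} possible ambiguous
#' sites, each site \code{x} receives the weight \code{Wx = a_xr / n},
#' where \code{a_xr} is the reagent's prior preference for the residue at
#' \code{x} (1 for every residue under the equal-preference assumption).
#' The total weighted score of a residue type is the sum over its
#' occurrences, \code{Wx' = sum_i Wx}, and the insertion likelihood is the
#' normalized \code{Px = Wx' / sum_k Wk'}. Only diazirine-side constituents
#' should be supplied.
#'
#' @param ambiguity_sets List of character vectors: for each linkage, the
#'   residue letters of its ambiguity set (length = n). A data.frame with a
#'   \code{beta_amb_residues} comma-separated column is also accepted.
#' @param priors Optional named numeric prior \code{a_xr} per residue
#'   (default 1 for every residue).
#' @return data.frame with columns \code{residue}, \code{W} (Wx'),
#'   \code{P} (Px), sorted by decreasing \code{P}. \code{sum(P)} is 1.
#' @export
weighted_occurrence <- function(ambiguity_sets, priors = NULL) {
  if (is.data.frame(ambiguity_sets)) {
    ambiguity_sets <- strsplit(ambiguity_sets$beta_amb_residues, ",")
  }
  if (!length(ambiguity_sets)) stop("no linkages supplied")
  W <- numeric(0)
  for (s in ambiguity_sets) {
    s <- s[nzchar(s)]
    n <- length(s)
    if (!n) next
    for (x in s) {
      a <- if (!is.null(priors) && x %in% names(priors)) priors[[x]] else 1
      W[x] <- (if (x %in% names(W)) W[[x]] else 0) + a / n
    }
  }
  if (!length(W)) stop("no sites in any ambiguity set")
  df <- data.frame(residue = names(W), W = unname(W),
                   P = unname(W) / sum(W))
  df[order(-df$P, df$residue), ] -> df
  rownames(df) <- NULL
  df
}

#' Localization-precision histogram
#'
#' Distribution of ambiguity-set sizes over the bins n = 1, 2, 3 and >= 4:
#' the fraction of linkages localized to exactly one site, one of two, one
#' of three, or four and more possible sites.
#'
#' @param n_ambiguous Integer vector of ambiguity-set sizes (one per
#'   linkage), or a data.frame with an \code{n_beta_amb} /
#'   \code{n_ambiguous} column.
#' @return data.frame with \code{bin} (\code{"1","2","3",">=4"}) and
#'   \code{fraction} (summing to 1), plus attribute \code{"empty"} when no
#'   linkages were supplied (all fractions 0).
#' @export
localization_precision <- function(n_ambiguous) {
  if (is.data.frame(n_ambiguous)) {
    n_ambiguous <- n_ambiguous$n_beta_amb %||% n_ambiguous$n_ambiguous
  }
  bins <- c("1", "2", "3", ">=4")
  if (!length(n_ambiguous)) {
    out <- data.frame(bin = bins, fraction = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  stopifnot(all(n_ambiguous >= 1L))
  b <- cut(n_ambiguous, c(0.5, 1.5, 2.5, 3.5, Inf), labels = bins)
  out <- data.frame(bin = bins,
                    fraction = as.numeric(table(b)[bins]) / length(n_ambiguous))
  attr(out, "empty") <- FALSE
  out
}

#' Write a Px table as CSV
#' @param px Result of \code{\link{weighted_occurrence}}.
#' @param path Output path.
#' @export
write_px_csv <- function(px, path) {
  utils::write.csv(px, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
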