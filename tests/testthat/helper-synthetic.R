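# Shared fixture builders and independent oracles used across the test files.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random protein with mildly elevated K/R content (digestible)
random_protein <- function(len) {
  paste(sample(AAS, len, replace = TRUE,
               prob = ifelse(AAS %in% c("K", "R"), 2.5, 1)), collapse = "")
}

synthetic_db <- function(n = 4, len = 250, seed = 42) {
  set.seed(seed)
  data.frame(accession = paste0("SYN", seq_len(n)),
             sequence = vapply(rep(len, n), random_protein, character(1)),
             is_decoy = FALSE)
}

# Deterministic synthetic protein embedding the two worked-example peptides
# at their album-style coordinates: DLGEEHFK at 37-44, ADEKK at 152-156.
bsa_like_protein <- function() {
  s <- paste0(strrep("GASVT", 7), "R",            # 1-36
              "DLGEEHFK",                          # 37-44
              strrep("HNQAG", 21), "VR",           # 45-151
              "ADEKK",                             # 152-156
              strrep("GASVT", 3))                  # 157-171
  stopifnot(substring(s, 37, 44) == "DLGEEHFK", substring(s, 152, 156) == "ADEKK")
  data.frame(accession = "SYNBSA", sequence = s, is_decoy = FALSE)
}

# truth row for the worked-example interlink ADEKK(K155) x DLGEEHFK(E41)
worked_example_truth <- function(linker = "SDASO-M", z = 4L) {
  M <- crosslinked_pair_mass(modified_peptide("ADEKK"),
                             modified_peptide("DLGEEHFK"), linker)
  data.frame(kind = "interlink", linker = linker,
             alpha_seq = "ADEKK", alpha_protein = "SYNBSA",
             alpha_start = 152L, alpha_site = 4L, alpha_res = 155L,
             beta_seq = "DLGEEHFK", beta_protein = "SYNBSA",
             beta_start = 37L, beta_site = 5L, beta_res = 41L,
             precursor_mz = mz(M, z), z = z, neutral_mass = M,
             ms2_scan = NA_integer_, truth_id = 1L)
}

# ---------------------------------------------------------------------------
# Independent oracles

# digestion by substring enumeration
oracle_digest <- function(sequence, params) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  cl <- switch(params$enzyme, trypsin = c("K", "R"),
               chymotrypsin = c("F", "W", "Y", "L"))
  is_cut <- function(i) i >= 1 && i < n && ch[i] %in% cl && ch[i + 1] != "P"
  out <- list()
  for (st in 1:n) for (en in st:n) {
    len <- en - st + 1
    if (len < params$min_length || len > params$max_length) next
    if (!(st == 1 || is_cut(st - 1))) next
    if (!(en == n || is_cut(en))) next
    internal <- sum(vapply(st:(en - 1), is_cut, logical(1)))
    if (en == st) internal <- 0
    if (internal > params$max_missed) next
    out[[length(out) + 1L]] <- data.frame(
      start = st, end = en,
      sequence = substring(sequence, st, en), missed = internal)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), missed = integer()))
  }
  do.call(rbind, out)
}

# all-pairs signature-pair search over every charge split
oracle_pairs <- function(spectrum, linker, tol = tolerances()) {
  if (is.character(linker)) linker <- get_linker(linker)
  M <- neutral_mass(spectrum$precursor_mz, spectrum$precursor_z)
  abs_tol <- M * tol$ppm * 1e-6
  np <- length(spectrum$mz)
  zmax <- spectrum$precursor_z - 1L
  found <- list()
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i >= j) next
    for (zi in 1:zmax) for (zj in 1:zmax) {
      if (zi + zj != spectrum$precursor_z) next
      s <- neutral_mass(spectrum$mz[i], zi) + neutral_mass(spectrum$mz[j], zj)
      for (tp in c("A+S", "A+T")) {
        targ <- if (tp == "A+S") M else M - WATER_MASS
        if (abs(s - targ) <= abs_tol) {
          found[[length(found) + 1L]] <-
            data.frame(peak_i = i, z_i = zi, peak_j = j, z_j = zj,
                       pair_type = tp)
        }
      }
    }
  }
  if (!length(found)) {
    return(data.frame(peak_i = integer(), z_i = integer(),
                      peak_j = integer(), z_j = integer(),
                      pair_type = character()))
  }
  unique(do.call(rbind, found))
}

# brute-force K-to-all-residue distance enumeration
oracle_null <- function(model, cap) {
  at <- model$atoms
  k <- which(at$resid == "LYS")
  d <- numeric(0)
  for (i in k) for (j in seq_len(nrow(at))) {
    if (i == j) next
    d <- c(d, sqrt(sum((at[i, c("x", "y", "z")] - at[j, c("x", "y", "z")])^2)))
  }
  d[d <= cap]
}

# canonical sorted key for pair data.frames (oracle comparison)
pair_key <- function(p) {
  if (!nrow(p)) return(character())
  sort(sprintf("%d/%d+%d/%d:%s", p$peak_i, p$z_i, p$peak_j, p$z_j, p$pair_type))
}

# recovery bookkeeping: which true interlinks appear in an id table
interlink_recovery <- function(ids, truth) {
  tt <- truth[truth$kind == "interlink", , drop = FALSE]
  inter <- ids[ids$kind == "interlink", , drop = FALSE]
  keys_true <- paste(tt$alpha_seq, tt$alpha_res, tt$beta_seq, tt$beta_protein)
  keys_got <- paste(inter$alpha_seq, inter$alpha_res, inter$beta_seq,
                    inter$beta_protein)
  mean(keys_true %in% keys_got)
}
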