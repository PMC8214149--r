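# Orchestration: structured run configuration, stage sequencing, stage TSV
# outputs and a run summary.

#' Load a run configuration
#'
#' Reads a YAML run configuration (or normalizes an equivalent list).
#' Recognized fields: \code{linker}, \code{seed}, \code{out_dir},
#' \code{fasta} (target database path), \code{mgf} (optional: search an
#' existing MGF instead of simulating), \code{enzyme}, \code{max_missed},
#' \code{ppm}, \code{ms3_window}, \code{fdr_threshold}, \code{simulate}
#' (species counts, \code{ppm_sigma}, \code{noise_peaks}), \code{structure}
#' (\code{pdb} path + \code{chain_map} accession->chain), stage toggles
#' \code{run_structure}, \code{run_preference}.
#'
#' @param config Path to a YAML file, or a list.
#' @return Normalized configuration list of class \code{run_config}.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(linker = "SDASO-M", seed = 1L, out_dir = tempfile("xlrun"),
                   enzyme = "trypsin", max_missed = NULL, ppm = 20,
                   ms3_window = 0.6, fdr_threshold = 0.01,
                   run_structure = FALSE, run_preference = TRUE,
                   simulate = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$fasta)) stop("config requires a 'fasta' path")
  if (!file.exists(cfg$fasta)) stop("FASTA not found: ", cfg$fasta)
  if (!is.null(cfg$mgf) && !file.exists(cfg$mgf)) {
    stop("MGF not found: ", cfg$mgf)
  }
  if (isTRUE(cfg$run_structure)) {
    if (is.null(cfg$structure$pdb) || !file.exists(cfg$structure$pdb)) {
      stop("structure stage enabled but PDB not found: ",
           cfg$structure$pdb %||% "<missing>")
    }
  }
  get_linker(cfg$linker)  # validates registration
  class(cfg) <- "run_config"
  cfg
}

#' Run the full MSn cross-link pipeline
#'
#' Sequences the stages: (optional) simulation of cross-linked species and
#' MSn spectra, digestion and decoy database construction, MS2/MS3 search,
#' cross-link assembly, FDR filtering, redundancy collapse, optional
#' structural validation, and the diazirine residue-preference statistic.
#' All stage tables are written as TSV/CSV under \code{out_dir}.
#'
#' @param config A \code{\link{load_config}} result, YAML path, or list.
#' @param quiet Suppress stage messages.
#' @return List of class \code{xlmsn_run} with stage outputs and a
#'   \code{summary} of counts and rates.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say("stage %-12s %6.1fs", name, proc.time()[["elapsed"]] - t)
    r
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- digest_params(cfg$enzyme, max_missed = cfg$max_missed)
  tol <- tolerances(ppm = cfg$ppm, ms3_window = cfg$ms3_window)

  targets <- stage("read_fasta", read_fasta(cfg$fasta))
  db <- stage("decoys", make_decoys(targets, seed = cfg$seed))
  idx <- stage("digest", build_digest_index(db, params))
  write_digest_tsv(idx, file.path(cfg$out_dir, "digest_index.tsv"))

  truth <- NULL
  if (is.null(cfg$mgf)) {
    sim <- cfg$simulate
    scfg <- sim_config(
      linker = cfg$linker,
      n_interlink = sim$n_interlink %||% 20L,
      n_deadend_nhs = sim$n_deadend_nhs %||% 5L,
      n_deadend_diazirine = sim$n_deadend_diazirine %||% 5L,
      n_intralink = sim$n_intralink %||% 5L,
      ppm_sigma = sim$ppm_sigma %||% 0,
      noise_peaks = sim$noise_peaks %||% 0L,
      seed = cfg$seed)
    truth <- stage("simulate", simulate_crosslinks(targets, scfg, params))
    spectra <- stage("render", render_spectra(truth, scfg))
    truth <- attr(spectra, "truth")
    write_truth_tsv(truth, file.path(cfg$out_dir, "truth.tsv"))
    write_mgf(spectra, file.path(cfg$out_dir, "spectra.mgf"))
  } else {
    spectra <- stage("read_mgf", read_mgf(cfg$mgf))
  }

  search <- stage("search", search_msn(spectra, idx, cfg$linker, tol))
  utils::write.table(search$psms, file.path(cfg$out_dir, "psms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- stage("assemble", assemble(spectra, search, cfg$linker, tol))
  write_ids_tsv(ids, file.path(cfg$out_dir, "crosslinks_all.tsv"))
  filt <- stage("fdr", fdr_filter(ids, cfg$fdr_threshold))
  write_ids_tsv(filt$ids, file.path(cfg$out_dir, "crosslinks_filtered.tsv"))
  coll <- stage("collapse", collapse_ids(filt$ids))
  write_ids_tsv(coll$linkages, file.path(cfg$out_dir, "linkages.tsv"))
  export_xinet(coll$linkages, file.path(cfg$out_dir, "linkages_xinet.csv"))

  struct_res <- NULL
  if (isTRUE(cfg$run_structure) && nrow(coll$linkages)) {
    struct_res <- stage("structure", {
      models <- read_structure(cfg$structure$pdb)
      cm <- unlist(cfg$structure$chain_map %||% list())
      lk <- coll$linkages
      lk$chain_a <- if (length(cm)) unname(cm[lk$alpha_protein]) else
        models[[1]]$atoms$chain[1]
      lk$chain_b <- if (length(cm)) unname(cm[lk$beta_protein]) else
        models[[1]]$atoms$chain[1]
      lk <- lk[!is.na(lk$chain_a) & !is.na(lk$chain_b), , drop = FALSE]
      lk$res_a <- lk$alpha_res
      sat <- satisfaction(lk, models, cfg$linker)
      cls <- if (ncol(sat$satisfied) >= 2L) state_classify(sat) else NULL
      null <- random_null(models[[1]],
                          cap = cfg$structure$cap %||% 300)
      obs <- sat$distances[, 1]
      cmp <- if (sum(is.finite(obs)) > 0 && length(null$distances))
        compare_to_null(obs, null$distances) else NULL
      list(satisfaction = sat, classification = cls, null = null,
           null_test = cmp)
    })
  }

  pref <- NULL
  if (isTRUE(cfg$run_preference)) {
    inter <- filt$ids[filt$ids$kind == "interlink", , drop = FALSE]
    if (nrow(inter)) {
      pref <- stage("preference", {
        sets <- lapply(seq_len(nrow(inter)), function(i) {
          amb <- as.integer(strsplit(inter$beta_ambiguity[i], ",")[[1]])
          strsplit(inter$beta_seq[i], "")[[1]][amb]
        })
        px <- weighted_occurrence(sets)
        write_px_csv(px, file.path(cfg$out_dir, "preference_px.csv"))
        list(px = px,
             precision = localization_precision(inter$n_beta_amb))
      })
    }
  }

  summary <- list(
    n_spectra_ms2 = sum(vapply(spectra, function(s) s$ms_level == 2L, logical(1))),
    n_spectra_ms3 = sum(vapply(spectra, function(s) s$ms_level == 3L, logical(1))),
    n_psms = nrow(search$psms),
    n_ids = nrow(ids),
    n_ids_filtered = nrow(filt$ids),
    fdr_percent = filt$fdr_percent,
    n_unique_sequences = nrow(coll$sequences),
    n_unique_linkages = nrow(coll$linkages),
    kinds = table(filt$ids$kind),
    elapsed_s = proc.time()[["elapsed"]] - t0)
  res <- structure(list(config = cfg, truth = truth, spectra = spectra,
                        search = search, ids = ids, filtered = filt,
                        collapsed = coll, structure = struct_res,
                        preference = pref, summary = summary),
                   class = "xlmsn_run")
  saveRDS_summary <- file.path(cfg$out_dir, "summary.tsv")
  utils::write.table(
    data.frame(key = c("ms2", "ms3", "psms", "ids", "ids_filtered",
                       "fdr_percent", "unique_sequences", "unique_linkages"),
               value = c(summary$n_spectra_ms2, summary$n_spectra_ms3,
                         summary$n_psms, summary$n_ids, summary$n_ids_filtered,
                         summary$fdr_percent %||% NA,
                         summary$n_unique_sequences,
                         summary$n_unique_linkages)),
    saveRDS_summary, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

#' @export
print.xlmsn_run <- function(x, ...) {
  s <- x$summary
  cat("<xlmsn run>\n")
  cat(sprintf("  linker          %s\n", x$config$linker))
  cat(sprintf("  spectra         %d MS2 / %d MS3\n",
              s$n_spectra_ms2, s$n_spectra_ms3))
  cat(sprintf("  PSMs            %d\n", s$n_psms))
  cat(sprintf("  cross-links     %d assembled, %d after FDR (est. %.3f%%)\n",
              s$n_ids, s$n_ids_filtered,
              if (is.na(s$fdr_percent)) 0 else s$fdr_percent))
  cat(sprintf("  unique          %d peptide pairs, %d K-X linkages\n",
              s$n_unique_sequences, s$n_unique_linkages))
  if (!is.null(x$structure)) {
    cat(sprintf("  satisfaction    mean %.1f%% at <=%.0f A\n",
                100 * x$structure$satisfaction$mean_rate,
                x$structure$satisfaction$threshold))
  }
  if (!is.null(x$preference)) {
    top <- x$preference$px[1, ]
    cat(sprintf("  top residue Px  %s = %.3f\n", top$residue, top$P))
  }
  cat(sprintf("  elapsed         %.1fs\n", s$elapsed_s))
  invisible(x)
}
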