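#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named list of sequence strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  out <- lapply(recs, function(r) toupper(as.character(r)[1]))
  names(out) <- names(recs)
  out
}

# separator by extension: .csv -> comma, anything else -> tab
sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a typed numeric table
#'
#' Reads a CSV/TSV (separator chosen by extension) and validates it against
#' the expected column names. Every declared column must parse as numeric
#' unless listed in `character_columns`; rows that fail report their file
#' line numbers.
#'
#' @param path File path.
#' @param columns Character vector of required column names, in order.
#' @param character_columns Columns exempt from numeric coercion.
#' @return data.frame with the declared columns.
#' @export
read_table <- function(path, columns, character_columns = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  if (nrow(df) == 0) stop("empty input: ", path, " has a header but no data rows",
                          call. = FALSE)
  if (!identical(names(df), as.character(columns))) {
    stop("header mismatch in ", path, ": expected [",
         paste(columns, collapse = ", "), "], found [",
         paste(names(df), collapse = ", "), "]", call. = FALSE)
  }
  for (col in setdiff(columns, character_columns)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("malformed numeric value(s) in column '", col, "' of ", path,
           " at line(s) ", paste(bad + 1L, collapse = ", "),
           " (1-based, counting the header)", call. = FALSE)
    }
    df[[col]] <- vals
  }
  df
}

#' Write a table as CSV/TSV
#'
#' Separator chosen by extension; full-precision numeric round-trip.
#'
#' @param df data.frame to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.exchange_series <- function(x, ...) {
  data.frame(time_h = x$times, integral = x$integrals)
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  if (x$unit == "C") {
    data.frame(temp_C = x$times, signal = x$signal)
  } else {
    out <- data.frame(x$times, x$signal)
    names(out) <- c(paste0("time_", x$unit), "signal")
    out
  }
}

#' @export
as.data.frame.cd_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, theta_mdeg = x$theta)
}

pipeline_schema <- list(
  top = c("seed", "out_dir", "scan", "enumerate", "simulate_folding",
          "cd_quant", "fit_kinetics", "fit_hdx", "fit_melt", "simulate_hdx"),
  scan = c("fasta", "sequence", "min_repeats"),
  enumerate = c("n_repeats", "fold_repeats", "maximal_only"),
  simulate_folding = c("n_repeats", "n_molecules", "fold_repeats"),
  cd_quant = c("sample", "reference", "concentration", "path_length", "n_nt",
               "wavelengths"),
  fit_kinetics = c("path", "unit"),
  fit_hdx = c("path", "mode"),
  fit_melt = c("path"),
  simulate_hdx = c("k_flip", "k_unfold", "flank_5", "flank_3", "n_molecules",
                   "times")
)

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  unknown <- setdiff(names(config), pipeline_schema$top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (stage in intersect(names(config), names(pipeline_schema))) {
    if (stage == "top") next
    bad <- setdiff(names(config[[stage]]), pipeline_schema[[stage]])
    if (length(bad)) {
      stop("unknown key(s) in stage '", stage, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run an analysis pipeline from a validated configuration
#'
#' Executes the requested stages — sequence scan, fold-placement
#' enumeration, sequential-folding simulation, CD quantification, kinetic /
#' HDX / melt fits, register-exchange simulation — in a fixed order, and
#' writes a JSON result bundle, TSV tables, and a run log (package version,
#' config hash, seed) to `out_dir` if one is given. The configuration is
#' schema-validated before any computation; unknown keys are rejected.
#'
#' @param config Named list. Recognised top-level keys: `seed`, `out_dir`,
#'   and one sub-list per stage (`scan`, `enumerate`, `simulate_folding`,
#'   `cd_quant`, `fit_kinetics`, `fit_hdx`, `fit_melt`, `simulate_hdx`);
#'   see the package vignette for stage keys.
#' @return List of class `pugfold_bundle` with one element per executed
#'   stage plus `meta` (version, seed, config hash, result hash).
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  bundle <- list()

  if (!is.null(config$scan)) {
    sc <- config$scan
    min_rep <- if (is.null(sc$min_repeats)) 1 else sc$min_repeats
    runs <- if (!is.null(sc$fasta)) scan_fasta(sc$fasta, min_rep)
            else if (!is.null(sc$sequence)) find_pug_runs(sc$sequence, min_rep)
            else stop("scan stage needs 'fasta' or 'sequence'", call. = FALSE)
    bundle$scan <- runs
  }
  if (!is.null(config$enumerate)) {
    en <- config$enumerate
    if (is.null(en$n_repeats)) stop("enumerate stage needs 'n_repeats'",
                                    call. = FALSE)
    fr <- if (is.null(en$fold_repeats)) 12 else en$fold_repeats
    mx <- isTRUE(en$maximal_only)
    cfgs <- enumerate_configurations(en$n_repeats, fr, mx)
    stats <- if (length(cfgs)) unclass(adjacency_stats(cfgs)) else
      list(n_configs = 0L)
    bundle$enumerate <- stats
  }
  if (!is.null(config$simulate_folding)) {
    sf <- config$simulate_folding
    fr <- if (is.null(sf$fold_repeats)) 12 else sf$fold_repeats
    ens <- simulate_sequential_folding(sf$n_repeats, sf$n_molecules,
                                       seed = seed, fold_repeats = fr)
    bundle$simulate_folding <- unclass(adjacency_stats(ens))
  }
  if (!is.null(config$cd_quant)) {
    cq <- config$cd_quant
    wl <- if (is.null(cq$wavelengths)) c(245, 281, 304) else cq$wavelengths
    samp_df <- read_table(cq$sample, c("wavelength_nm", "theta_mdeg"))
    samp <- molar_cd(cd_spectrum(samp_df$wavelength_nm, samp_df$theta_mdeg,
                                 cq$concentration, cq$path_length, cq$n_nt))
    ref <- if (is.null(cq$reference)) reference_gu12(samp_df$wavelength_nm)
    else {
      ref_df <- read_table(cq$reference, c("wavelength_nm", "theta_mdeg"))
      molar_cd(cd_spectrum(ref_df$wavelength_nm, ref_df$theta_mdeg,
                           cq$concentration, cq$path_length, 24))
    }
    ff <- fraction_folded(samp, ref, wavelengths = wl)
    bundle$cd_quant <- list(
      per_peak = as.list(ff$per_peak),
      mean_fraction = ff$mean_fraction,
      implied_mean_folds = mean_folds_from_fraction(
        min(max(ff$mean_fraction, 0), 1), cq$n_nt))
  }
  if (!is.null(config$fit_kinetics)) {
    fk <- config$fit_kinetics
    unit <- if (is.null(fk$unit)) "min" else fk$unit
    df <- read_table(fk$path, c(paste0("time_", unit), "signal"))
    fit <- fit_single_exponential(kinetic_trace(df[[1]], df$signal, unit))
    bundle$fit_kinetics <- fit[c("k", "t_half", "s0", "s_inf", "fit_r2",
                                 "no_transition")]
  }
  if (!is.null(config$fit_hdx)) {
    fh <- config$fit_hdx
    mode <- if (is.null(fh$mode)) "mono" else fh$mode
    df <- read_table(fh$path, c("time_h", "integral"))
    ser <- exchange_series(df$time_h, df$integral)
    fit <- if (mode == "biexp") fit_hdx_biexponential(ser) else
      fit_hdx_mono(ser)
    bundle$fit_hdx <- unclass(fit)
  }
  if (!is.null(config$fit_melt)) {
    df <- read_table(config$fit_melt$path, c("temp_C", "signal"))
    fit <- fit_boltzmann_melt(kinetic_trace(df$temp_C, df$signal, "C"))
    bundle$fit_melt <- unclass(fit)
  }
  if (!is.null(config$simulate_hdx)) {
    sh <- config$simulate_hdx
    mdl <- register_exchange_model(
      k_flip = sh$k_flip, k_unfold = sh$k_unfold,
      flank_5 = if (is.null(sh$flank_5)) 0 else sh$flank_5,
      flank_3 = if (is.null(sh$flank_3)) 0 else sh$flank_3)
    times <- if (is.null(sh$times)) hdx_default_schedule() else sh$times
    pred <- gillespie_hdx(mdl, sh$n_molecules, times, seed = seed)
    bundle$simulate_hdx <- list(
      fast_amplitude = pred$fast_amplitude,
      k_fast_effective = pred$k_fast_effective,
      k_slow_effective = pred$k_slow_effective,
      survival = data.frame(time_h = pred$times, survival = pred$survival,
                            mc_se = pred$mc_se))
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  meta <- list(
    package_version = as.character(utils::packageVersion("pugfold")),
    seed = seed,
    config_hash = hash_string(cfg_json)
  )
  res_json <- jsonlite::toJSON(strip_frames(bundle), auto_unbox = TRUE,
                               digits = NA, null = "null")
  meta$result_hash <- hash_string(res_json)
  bundle$meta <- meta

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(res_json, file.path(config$out_dir, "results.json"))
    for (nm in names(bundle)) {
      if (is.data.frame(bundle[[nm]])) {
        write_table(bundle[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".tsv")))
      }
    }
    writeLines(c(
      sprintf("pugfold %s", meta$package_version),
      sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("seed %d", seed),
      sprintf("config hash %s", meta$config_hash),
      sprintf("result hash %s", meta$result_hash)
    ), file.path(config$out_dir, "run.log"))
  }
  structure(bundle, class = "pugfold_bundle")
}

# data.frames are serialized row-wise by toJSON; keep only scalar summaries
# out of the hashed result document so hashing is stable across platforms
strip_frames <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, strip_frames))
  x
}

hash_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Write a result bundle to a JSON report
#'
#' @param bundle A `pugfold_bundle` from [run_pipeline()], or any list.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
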