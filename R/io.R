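#' Read protein sequences from FASTA
#'
#' Reads amino-acid sequences and validates each against the canonical
#' 20-letter alphabet (lowercase is normalized to uppercase). Record names
#' are taken from the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Named list of [target_protein()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no records in FASTA file: ", path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(seqs), function(i)
    target_protein(nm[i], as.character(seqs[[i]])))
  stats::setNames(out, nm)
}

# Required columns per trace-table schema; names carry the units.
trace_schemas <- list(
  tht = c("time_s", "F", "binder_conc_M", "replicate"),
  bli = c("time_s", "conc_M", "phase", "replicate", "response"),
  mds = c("conc_M", "replicate", "fraction_bound"),
  trajectory = c("t_s", "m_M", "M_M", "P_M")
)

#' Read an assay trace table from CSV
#'
#' Long/tidy CSV with unit-bearing column names (`time_s`, `conc_M`, ...);
#' the required columns are checked against the declared schema and
#' duplicate (condition, time, replicate) rows are rejected with their line
#' numbers. Units are always explicit in headers; no unit guessing.
#'
#' @param path CSV file.
#' @param schema one of `"tht"`, `"bli"`, `"mds"`, `"trajectory"`.
#' @return Data frame with attribute `schema`.
#' @export
read_trace_csv <- function(path, schema = names(trace_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("CSV file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- trace_schemas[[schema]]
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("CSV ", path, " is missing required column(s) for schema '",
         schema, "': ", paste(miss, collapse = ", "))
  keycols <- intersect(c("binder_conc_M", "conc_M", "phase", "replicate",
                         "time_s", "t_s"), names(d))
  key <- do.call(paste, c(d[keycols], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate rows in ", path, " (data line ",
         paste(utils::head(dup, 5L), collapse = ", "),
         "): same condition, time and replicate")
  for (col in intersect(need, c("time_s", "t_s", "conc_M", "binder_conc_M",
                                "response", "F", "fraction_bound")))
    if (!is.numeric(d[[col]]))
      stop("column '", col, "' in ", path, " is not numeric")
  attr(d, "schema") <- schema
  d
}

#' Write analysis results atomically with a manifest
#'
#' Writes a named list of result objects into a directory: data frames as
#' CSV, everything else as JSON. Each file is written to a temporary path
#' and renamed into place, and a `manifest.json` listing every artifact
#' with its MD5 content hash is written last.
#'
#' @param dir output directory (created if needed).
#' @param objects named list; names become file stems.
#' @return The manifest data frame (`file`, `md5`), invisibly.
#' @export
write_results <- function(dir, objects) {
  stopifnot(is.list(objects), !is.null(names(objects)),
            all(nzchar(names(objects))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      fn <- file.path(dir, paste0(nm, ".csv"))
      tmp <- tempfile(tmpdir = dir, fileext = ".csv")
      utils::write.csv(obj, tmp, row.names = FALSE)
    } else {
      fn <- file.path(dir, paste0(nm, ".json"))
      tmp <- tempfile(tmpdir = dir, fileext = ".json")
      jsonlite::write_json(strip_for_json(obj), tmp, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null",
                           force = TRUE)
    }
    file.rename(tmp, fn)
    files <- c(files, fn)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  mtmp <- tempfile(tmpdir = dir, fileext = ".json")
  jsonlite::write_json(manifest, mtmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(mtmp, file.path(dir, "manifest.json"))
  invisible(manifest)
}

# Drop closures and heavy embedded data before JSON serialization.
strip_for_json <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- x[!vapply(x, is.function, logical(1))]
    return(lapply(x, strip_for_json))
  }
  x
}

#' Run the full inhibition-analysis pipeline
#'
#' Orchestrates the analysis end to end, in the order of the experimental
#' workflow: obtain a ThT dataset (from CSV or, by default, the synthetic
#' generator), normalize it, fit the uninhibited model, score the
#' sequestration-only prediction, fit the secondary-nucleation modulation
#' and compute the potency concentration; results are written via
#' [write_results()]. Fully deterministic given the config and seed.
#'
#' @param config named list (or path to a YAML file) with any of:
#'   `seed` (default 1), `outdir` (default `tempfile()`), `tht_csv`
#'   (optional input CSV; synthetic data are generated when absent),
#'   `monomer_conc` (M, required with `tht_csv`), `binder_Kd` (M),
#'   `mode` (`"table"` or `"parametric"`), `potency_increase`
#'   (default 0.5), plus `synth` (a sub-list of [gen_tht_dataset()]
#'   arguments). Unknown keys are rejected.
#' @return List with `status` (0 on success), `outdir`, `manifest`, and the
#'   fitted objects (`uninhibited`, `inhibition`, `potency_M`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "outdir", "tht_csv", "monomer_conc", "binder_Kd",
             "mode", "potency_increase", "synth")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% tempfile("amytrap_run_")
  mode <- config$mode %||% "table"
  inc <- config$potency_increase %||% 0.5

  if (!is.null(config$tht_csv)) {
    if (is.null(config$monomer_conc))
      stop("monomer_conc is required when reading a ThT CSV")
    traces <- read_trace_csv(config$tht_csv, "tht")
    ds <- tht_dataset(traces, monomer_conc = config$monomer_conc,
                      binder_Kd = config$binder_Kd %||% NA_real_)
  } else {
    ds <- do.call(gen_tht_dataset, c(list(seed = seed), config$synth))
  }
  if (!nrow(ds)) stop("empty dataset")
  binder_Kd <- config$binder_Kd %||% attr(ds, "binder_Kd")

  nds <- normalize_tht(ds)
  fit0 <- fit_uninhibited(nds)
  concs <- sort(unique(nds$binder_conc_M))
  seqpred <- predict_sequestration_only(fit0, binder_Kd,
                                        concs[concs > 0], ndata = nds)
  inh_fit <- fit_secondary_modulation(nds, fit0, binder_Kd, mode = mode)
  potency <- tryCatch(potency_concentration(inh_fit, increase = inc),
                      warning = function(w) NA_real_)

  manifest <- write_results(outdir, list(
    normalized_traces = as.data.frame(nds),
    uninhibited_fit = list(products = as.list(fit0$products),
                           orders = as.list(fit0$orders),
                           m_total = fit0$m_total, rss = fit0$rss,
                           converged = fit0$converged),
    sequestration_only_residuals = seqpred$residuals,
    modulation_fit = inh_fit$factors,
    potency = list(increase = inc, potency_conc_M = potency,
                   binder_Kd = binder_Kd,
                   t_half_uninhibited_s = inh_fit$t_half_uninhibited)
  ))
  list(status = 0L, outdir = outdir, manifest = manifest,
       uninhibited = fit0, inhibition = inh_fit, potency_M = potency)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an aggregation trajectory as CSV
#'
#' @param traj an `aggregation_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- data.frame(t_s = traj$t, m_M = traj$m, M_M = traj$M, P_M = traj$P)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
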