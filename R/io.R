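#' Read a FASTA file of transcripts
#'
#' Sequences are uppercased and DNA T is normalised to U (with a note).
#' Uses Biostrings when installed, otherwise a small base-R parser; either
#' way the result is a plain named character vector.
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  seqs <- if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop_domain("no FASTA records found", "m6aj_parse_error")
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    starts <- hdr + 1L
    ends <- c(hdr[-1L] - 1L, length(lines))
    stats::setNames(vapply(seq_along(hdr), function(k) {
      paste(lines[seq.int(starts[k], max(starts[k], ends[k]))], collapse = "")
    }, ""), ids)
  }
  if (!length(seqs) || all(!nzchar(seqs)))
    stop_domain("empty FASTA file", "m6aj_parse_error")
  if (anyDuplicated(names(seqs)))
    stop_domain(sprintf("duplicate FASTA ids: %s",
                        paste(unique(names(seqs)[duplicated(names(seqs))]),
                              collapse = ", ")), "m6aj_parse_error")
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  if (any(grepl("T", seqs))) {
    message("read_fasta: DNA input detected, normalising T to U")
    seqs <- gsub("T", "U", seqs)
  }
  for (s in seqs) validate_rna_string(s)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[k]), seqs[[k]]), con)
  invisible(path)
}

#' Read an m6A site list (TSV)
#'
#' Expects a header with columns `transcript_id`, `position` (1-based) and
#' `strand` (+/-). Malformed rows are dropped with a per-row report.
#'
#' @param path TSV file.
#' @return data frame of valid sites with attribute `rejected` (data frame
#'   of dropped rows with reasons).
#' @export
read_site_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "strand")
  if (!all(need %in% names(df)))
    stop_domain(sprintf("site list must have columns %s",
                        paste(need, collapse = ", ")), "m6aj_parse_error")
  pos <- suppressWarnings(as.integer(df$position))
  bad_pos <- is.na(pos) | pos < 1L
  bad_strand <- !df$strand %in% c("+", "-")
  bad <- bad_pos | bad_strand
  rejected <- data.frame(row = which(bad),
                         reason = ifelse(bad_pos[bad], "invalid position",
                                         "invalid strand"))
  if (nrow(rejected))
    message(sprintf("read_site_list: rejected %d row(s): %s", nrow(rejected),
                    paste(utils::head(rejected$row, 5L), collapse = ", ")))
  out <- df[!bad, need]
  out$position <- pos[!bad]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' @rdname read_site_list
#' @param sites site data frame.
#' @export
write_site_list <- function(sites, path) {
  utils::write.table(sites[, c("transcript_id", "position", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a melting curve from CSV
#'
#' Columns `temperature_C` (or `temperature_K`) and `signal`.
#'
#' @param path CSV file.
#' @inheritParams melting_curve
#' @return A [melting_curve()].
#' @export
read_melting_csv <- function(path, signal_kind = c("fraction", "absorbance"),
                             ct = NULL) {
  df <- utils::read.csv(path)
  if ("temperature_K" %in% names(df)) {
    TT <- df$temperature_K; unit <- "K"
  } else if ("temperature_C" %in% names(df)) {
    TT <- df$temperature_C; unit <- "C"
  } else stop_domain("need a temperature_C or temperature_K column",
                     "m6aj_parse_error")
  if (!"signal" %in% names(df)) stop_domain("need a signal column", "m6aj_parse_error")
  melting_curve(TT, df$signal, signal_kind = match.arg(signal_kind), ct = ct,
                unit = unit)
}

#' Read an FP titration from CSV
#'
#' Columns `protein_conc_M`, `anisotropy`, optional `intensity`.
#'
#' @param path CSV file.
#' @param rt trace RNA concentration in mol/L.
#' @return A [titration_curve()].
#' @export
read_titration_csv <- function(path, rt) {
  df <- utils::read.csv(path)
  need <- c("protein_conc_M", "anisotropy")
  if (!all(need %in% names(df)))
    stop_domain("need protein_conc_M and anisotropy columns", "m6aj_parse_error")
  titration_curve(df$protein_conc_M, df$anisotropy, rt = rt,
                  intensity = df$intensity)
}

#' Run configuration for the survey pipeline
#'
#' A validated, JSON-serialisable bundle of the survey parameters. Unknown
#' keys are rejected so configs cannot silently drift.
#'
#' @param fasta path to transcript FASTA.
#' @param sites path to the m6A site TSV.
#' @param out_dir output directory.
#' @param window_length,a_offset window geometry (41 / 21).
#' @param thresholds survey energy thresholds, kcal/mol.
#' @param subopt_window enumeration window (defaults to `max(thresholds)`).
#' @param max_structures per-window enumeration guard.
#' @param energy_model_path optional serialized energy model (JSON); default
#'   table when NULL.
#' @param seed seed recorded with the outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta, sites, out_dir = ".", window_length = 41L,
                       a_offset = 21L, thresholds = 0:3, subopt_window = NULL,
                       max_structures = 20000L, energy_model_path = NULL,
                       seed = 1L) {
  cfg <- list(fasta = fasta, sites = sites, out_dir = out_dir,
              window_length = as.integer(window_length),
              a_offset = as.integer(a_offset),
              thresholds = as.numeric(thresholds),
              subopt_window = if (is.null(subopt_window)) max(thresholds)
                              else as.numeric(subopt_window),
              max_structures = as.integer(max_structures),
              energy_model_path = energy_model_path,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("fasta", "sites", "out_dir", "window_length", "a_offset",
             "thresholds", "subopt_window", "max_structures",
             "energy_model_path", "seed")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    stop_domain(paste("unknown config keys:", paste(extra, collapse = ", ")),
                "m6aj_config_error")
  do.call(run_config, obj[intersect(names(obj), known)])
}

#' Run the site-survey workflow end to end
#'
#' Reads transcripts and sites, extracts analysis windows, enumerates each
#' window's suboptimal ensemble, classifies the focal A in every structure
#' and writes the survey: `survey.csv` (one row per threshold with the
#' junctional 5'-bulge populations), `survey.json` (full result including
#' MFE-mode category counts, skipped sites and the configuration), and
#' `skipped.csv`. Deterministic given the config; output files contain no
#' timestamps so identical configs produce identical bytes.
#'
#' @param cfg a [run_config()] (or a list coercible to one).
#' @return list with `survey` (a `survey_result`), `skipped`, `failed`
#'   (windows whose enumeration errored) and `files`.
#' @export
run_survey_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  transcripts <- read_fasta(cfg$fasta)
  sites <- read_site_list(cfg$sites)
  ext <- extract_windows(transcripts, sites, length = cfg$window_length,
                         a_offset = cfg$a_offset)
  model <- if (is.null(cfg$energy_model_path)) default_energy_model()
           else read_energy_model(cfg$energy_model_path)
  win <- max(cfg$subopt_window, max(cfg$thresholds))
  failed <- list()
  ensembles <- list()
  a_idx <- integer()
  for (w in ext$windows) {
    ens <- tryCatch(subopt(w$sequence, model, window = win,
                           max_structures = cfg$max_structures),
                    error = function(e) e)
    if (inherits(ens, "condition")) {
      failed[[length(failed) + 1L]] <- data.frame(
        transcript_id = w$source_id, position = w$source_pos,
        reason = conditionMessage(ens))
    } else {
      ensembles[[length(ensembles) + 1L]] <- ens
      a_idx <- c(a_idx, w$a_index)
    }
  }
  survey <- survey_sites(ensembles, a_idx, thresholds = cfg$thresholds)

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  f_csv <- file.path(cfg$out_dir, "survey.csv")
  f_json <- file.path(cfg$out_dir, "survey.json")
  f_skip <- file.path(cfg$out_dir, "skipped.csv")
  utils::write.csv(survey$by_threshold, f_csv, row.names = FALSE)
  failed_df <- if (length(failed)) do.call(rbind, failed) else
    data.frame(transcript_id = character(), position = integer(),
               reason = character())
  jsonlite::write_json(list(
    config = unclass(cfg),
    energy_model_version = model$version,
    n_sites = survey$n, n_skipped = nrow(ext$skipped),
    n_failed = nrow(failed_df),
    mfe_counts = as.list(survey$mfe_counts),
    mfe_fractions = as.list(survey$mfe_fractions),
    by_threshold = survey$by_threshold),
    f_json, digits = NA, auto_unbox = TRUE, pretty = TRUE, null = "null")
  utils::write.csv(rbind(ext$skipped,
                         stats::setNames(failed_df, names(ext$skipped))),
                   f_skip, row.names = FALSE)
  list(survey = survey, skipped = ext$skipped, failed = failed_df,
       files = c(csv = f_csv, json = f_json, skipped = f_skip))
}
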