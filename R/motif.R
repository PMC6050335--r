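#' Motif taxonomy for the structural context of a focal adenosine
#'
#' Every secondary structure maps the focal A to exactly one of eight
#' categories: `duplex_AU` / `duplex_AY` (paired, helix intact on both
#' sides), `unpaired`, the junctional categories `fiveB_AU` / `fiveB_AY`
#' (>= 1 bulged nucleotide immediately 5' of A), `AU_threeB` / `AY_threeB`
#' (bulge immediately 3' of A), and `partner_bulge` (bulge adjacent to the
#' partner nucleotide, opposite strand). `_AU` means the partner is uridine
#' (Watson-Crick), `_AY` a non-U mismatch partner.
#'
#' @name motif-taxonomy
NULL

MOTIF_CATEGORIES <- c("duplex_AU", "duplex_AY", "unpaired",
                      "fiveB_AU", "fiveB_AY", "AU_threeB", "AY_threeB",
                      "partner_bulge")

#' Classify the structural context of the focal adenosine
#'
#' Decision procedure: (1) if A is unpaired, attempt mismatch imputation (an
#' unpaired A immediately adjacent to a canonical pair, facing exactly one
#' unpaired nucleotide across an internal loop, is counted as a mismatch with
#' that nucleotide — the convention for predictors that only emit canonical
#' pairs); failing that the call is `unpaired`. (2) If (really or imputedly)
#' paired, the pair is junctional iff at least one of the four flanking
#' positions (i-1, i+1, j-1, j+1) is unpaired or breaks the helix; otherwise
#' a duplex call. (3) Junctional pairs are assigned a bulge side with
#' precedence 5'-of-A > 3'-of-A > partner-side; a junctional pair with no
#' unpaired neighbour at all (abutting helices, chain ends) falls back to the
#' duplex call. G-U wobbles count as canonical pairs throughout.
#'
#' @param x an `rna_structure`.
#' @param a_index 1-based position of the focal adenosine.
#' @return An object of class `motif_call`: `category`, `partner` (NA when
#'   unpaired), `partner_base`, `junctional`, `bulge_side`
#'   (`"5prime"`/`"3prime"`/`"partner"`/NA), `bulge_len`, `mismatch_imputed`.
#' @examples
#' s <- parse_dotbracket("GGCGACUUUCGAGUGCC", "(((.(((....))))))")
#' classify_motif(s, 5)$category  # junctional A-U with a 5' bulge
#' @export
classify_motif <- function(x, a_index) {
  stopifnot(inherits(x, "rna_structure"))
  n <- nchar(x$sequence)
  if (a_index < 1L || a_index > n)
    stop_domain("`a_index` out of range", "m6aj_validation_error")
  b <- strsplit(x$sequence, "")[[1L]]
  if (b[a_index] != "A")
    stop_domain(sprintf("base at a_index %d is %s, not A", a_index, b[a_index]),
                "m6aj_validation_error")
  pt <- pair_table(x)
  a <- a_index
  partner <- pt[a]
  imputed <- FALSE

  if (partner == 0L) {
    imp <- impute_mismatch(pt, a)
    if (is.na(imp)) return(new_motif_call("unpaired", NA_integer_, NA_character_,
                                          FALSE, NA_character_, 0L, FALSE))
    partner <- imp
    imputed <- TRUE
  }

  i <- min(a, partner); j <- max(a, partner)
  out_intact <- i > 1L && j < n && pt[i - 1L] == j + 1L
  in_intact <- i + 1L < j - 1L && pt[i + 1L] == j - 1L
  junctional <- !(out_intact && in_intact)
  y_suffix <- if (b[partner] == "U") "AU" else "AY"

  duplex_call <- function() new_motif_call(
    paste0("duplex_", y_suffix), partner, b[partner], junctional,
    NA_character_, 0L, imputed)
  if (!junctional) return(duplex_call())

  unp <- function(p) p >= 1L && p <= n && pt[p] == 0L && p != a && p != partner
  run_len <- function(p, step) {
    len <- 0L
    while (unp(p)) { len <- len + 1L; p <- p + step }
    len
  }
  if (unp(a - 1L)) {
    cat_name <- if (y_suffix == "AU") "fiveB_AU" else "fiveB_AY"
    return(new_motif_call(cat_name, partner, b[partner], TRUE, "5prime",
                          run_len(a - 1L, -1L), imputed))
  }
  if (unp(a + 1L)) {
    cat_name <- if (y_suffix == "AU") "AU_threeB" else "AY_threeB"
    return(new_motif_call(cat_name, partner, b[partner], TRUE, "3prime",
                          run_len(a + 1L, +1L), imputed))
  }
  if (unp(partner - 1L) || unp(partner + 1L)) {
    len <- max(run_len(partner - 1L, -1L), run_len(partner + 1L, +1L))
    return(new_motif_call("partner_bulge", partner, b[partner], TRUE,
                          "partner", len, imputed))
  }
  # junctional by helix break or chain end but with no bulged neighbour
  duplex_call()
}

new_motif_call <- function(category, partner, partner_base, junctional,
                           bulge_side, bulge_len, mismatch_imputed) {
  structure(list(category = category, partner = partner,
                 partner_base = partner_base, junctional = junctional,
                 bulge_side = bulge_side, bulge_len = bulge_len,
                 mismatch_imputed = mismatch_imputed),
            class = "motif_call")
}

#' @export
print.motif_call <- function(x, ...) {
  cat(sprintf("<motif_call> %s%s%s\n", x$category,
              if (!is.na(x$partner)) sprintf(" (partner %d%s)", x$partner,
                                             if (x$mismatch_imputed) ", imputed" else "")
              else "",
              if (!is.na(x$bulge_side)) sprintf(", bulge %s x%d", x$bulge_side,
                                                x$bulge_len) else ""))
  invisible(x)
}

# Mismatch imputation: unpaired focal A inside an internal loop, immediately
# adjacent to one of the loop's closing pairs, facing exactly one unpaired
# nucleotide on the opposite strand. Returns the partner index or NA.
impute_mismatch <- function(pt, a) {
  n <- length(pt)
  li <- a - 1L
  while (li >= 1L && pt[li] == 0L) li <- li - 1L
  ri <- a + 1L
  while (ri <= n && pt[ri] == 0L) ri <- ri + 1L
  if (li < 1L || ri > n) return(NA_integer_)
  if (li != a - 1L && ri != a + 1L) return(NA_integer_)  # adjacency rule
  mli <- pt[li]; mri <- pt[ri]
  if (mli == ri) return(NA_integer_)  # hairpin loop: no opposite strand
  lo <- min(mli, mri); hi <- max(mli, mri)
  if (hi - lo != 2L) return(NA_integer_)  # exactly one facing position
  y <- lo + 1L
  if (pt[y] != 0L) return(NA_integer_)
  # the two closing pairs must close a common internal loop (nested, with the
  # opposite segment strictly between their partners)
  if (!(max(li, ri) < lo || hi < min(li, ri))) return(NA_integer_)
  y
}

#' Extract a fixed-length analysis window around an m6A site
#'
#' Cuts the subsequence placing the site's adenosine at `a_offset` within a
#' window of `length` nucleotides (defaults: 41 nt with the A at position
#' 21, the middle). Minus-strand sites are extracted as the reverse
#' complement of the plus-strand context.
#'
#' @param transcript RNA (or DNA; T is normalised to U) sequence string.
#' @param position 1-based site position on the transcript (plus strand).
#' @param length window length in nt.
#' @param a_offset 1-based position of the focal A within the window.
#' @param strand `"+"` or `"-"`.
#' @param id transcript identifier carried into the window.
#' @return An object of class `site_window`: `sequence`, `a_index`,
#'   `source_id`, `source_pos`, `strand`. Sites whose window does not fit the
#'   transcript raise a condition of class `m6aj_window_oob` (callers batch
#'   these into a skipped-sites report).
#' @export
extract_window <- function(transcript, position, length = 41L, a_offset = 21L,
                           strand = "+", id = NA_character_) {
  transcript <- validate_rna_string(gsub("T", "U", toupper(transcript)))
  n <- nchar(transcript)
  if (a_offset < 1L || a_offset > length)
    stop_domain("`a_offset` must lie within the window", "m6aj_argument_error")
  start <- position - a_offset + 1L
  end <- start + length - 1L
  if (start < 1L || end > n)
    stop(structure(class = c("m6aj_window_oob", "error", "condition"),
                   list(message = sprintf(
                     "site %s:%d: window [%d, %d] out of bounds (transcript %d nt)",
                     id, position, start, end, n), call = sys.call())))
  win <- substr(transcript, start, end)
  if (strand == "-") {
    win <- revcomp(win)
    # on the reverse complement the focal base lands mirrored in the window
    a_idx <- length - a_offset + 1L
    win_a <- a_idx
  } else {
    win_a <- a_offset
  }
  base <- substr(win, win_a, win_a)
  if (base != "A")
    stop_domain(sprintf("site %s:%d(%s): focal base is %s, not A",
                        id, position, strand, base), "m6aj_validation_error")
  structure(list(sequence = win, a_index = win_a, source_id = id,
                 source_pos = position, strand = strand),
            class = "site_window")
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1L]]), collapse = "")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s:%d(%s) %d nt, A at %d\n",
              x$source_id, x$source_pos, x$strand, nchar(x$sequence), x$a_index))
  invisible(x)
}

#' Extract windows for a site list, with a skipped-sites report
#'
#' @param transcripts named character vector of transcript sequences.
#' @param sites data frame with columns `transcript_id`, `position`, `strand`.
#' @inheritParams extract_window
#' @return list with `windows` (list of `site_window`) and `skipped`
#'   (data frame of excluded sites with reasons).
#' @export
extract_windows <- function(transcripts, sites, length = 41L, a_offset = 21L) {
  windows <- list()
  skipped <- list()
  for (r in seq_len(nrow(sites))) {
    tid <- as.character(sites$transcript_id[r])
    if (!tid %in% names(transcripts)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        transcript_id = tid, position = sites$position[r],
        reason = "unknown transcript")
      next
    }
    w <- tryCatch(
      extract_window(transcripts[[tid]], sites$position[r], length = length,
                     a_offset = a_offset, strand = as.character(sites$strand[r]),
                     id = tid),
      m6aj_window_oob = function(e) e, m6aj_validation_error = function(e) e)
    if (inherits(w, "condition")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        transcript_id = tid, position = sites$position[r],
        reason = conditionMessage(w))
    } else {
      windows[[length(windows) + 1L]] <- w
    }
  }
  list(windows = windows,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(transcript_id = character(), position = integer(),
                    reason = character()))
}

#' Survey motif populations over a set of sites
#'
#' For each site the category of its minimum-free-energy structure is
#' counted (MFE mode), and for each energy threshold a site counts toward
#' the `fiveB_AU` (junctional A-U, 5' bulge) or `fiveB_AX` (5' bulge with
#' any partner: `fiveB_AU` or `fiveB_AY`) populations if any structure
#' within that window of the site's MFE exhibits the motif. Fractions are
#' counts divided by the number of surveyed sites, matching the
#' population-of-sites read-out used for transcriptome-scale m6A surveys.
#'
#' @param ensembles list of `subopt_ensemble` objects, one per site, each
#'   enumerated to at least `max(thresholds)`.
#' @param a_indices focal-A index per site (recycled if scalar).
#' @param thresholds energy thresholds in kcal/mol (default 0:3).
#' @return An object of class `survey_result`: `n`, `mfe_counts`,
#'   `mfe_fractions` (per category), `by_threshold` data frame with
#'   `threshold`, `fiveB_AU_*`, `fiveB_AX_*` counts and fractions, and
#'   `n_excluded` (empty ensembles, logged and dropped).
#' @export
survey_sites <- function(ensembles, a_indices, thresholds = 0:3) {
  if (length(a_indices) == 1L) a_indices <- rep(a_indices, length(ensembles))
  stopifnot(length(a_indices) == length(ensembles))
  keep <- vapply(ensembles, function(e) length(e$structures) > 0L, TRUE)
  if (any(!keep))
    message(sprintf("survey_sites: excluding %d site(s) with empty ensembles",
                    sum(!keep)))
  ensembles <- ensembles[keep]
  a_indices <- a_indices[keep]
  n <- length(ensembles)

  cats_per_site <- lapply(seq_len(n), function(s) {
    vapply(ensembles[[s]]$structures,
           function(x) classify_motif(x, a_indices[s])$category, "")
  })
  mfe_cat <- vapply(cats_per_site, `[[`, "", 1L)
  mfe_counts <- vapply(MOTIF_CATEGORIES,
                       function(cc) sum(mfe_cat == cc), 0L)

  by_thr <- lapply(thresholds, function(thr) {
    hit_au <- 0L; hit_ax <- 0L
    for (s in seq_len(n)) {
      en <- vapply(ensembles[[s]]$structures, `[[`, 0, "energy")
      cats <- cats_per_site[[s]][en <= ensembles[[s]]$mfe + thr + 1e-9]
      if (any(cats == "fiveB_AU")) hit_au <- hit_au + 1L
      if (any(cats %in% c("fiveB_AU", "fiveB_AY"))) hit_ax <- hit_ax + 1L
    }
    data.frame(threshold = thr, fiveB_AU_count = hit_au,
               fiveB_AX_count = hit_ax,
               fiveB_AU_fraction = if (n) hit_au / n else NA_real_,
               fiveB_AX_fraction = if (n) hit_ax / n else NA_real_)
  })

  structure(list(n = n, n_excluded = sum(!keep),
                 mfe_counts = mfe_counts,
                 mfe_fractions = if (n) mfe_counts / n else mfe_counts * NA_real_,
                 by_threshold = do.call(rbind, by_thr)),
            class = "survey_result")
}

#' @export
print.survey_result <- function(x, ...) {
  cat(sprintf("<survey_result> %d sites (%d excluded)\n", x$n, x$n_excluded))
  cat("MFE-mode fractions:\n")
  print(round(x$mfe_fractions, 3))
  cat("threshold mode:\n")
  print(x$by_threshold, row.names = FALSE)
  invisible(x)
}

#' Context-dependent m6A free-energy offsets
#'
#' Signed per-category offsets (kcal/mol, negative = methylation stabilises)
#' measured on hairpin model constructs by UV melting: with Mg2+ the 5'
#' bulge junctional A-U motif is stabilised by 0.9 kcal/mol while duplex A-U
#' (+0.6), 3' bulge (+1.2), bulged/unpaired A (+0.7) and partner-side bulge
#' (+0.4) contexts are destabilised; without Mg2+ the stabilisation shrinks
#' to 0.3 and duplex/partner-side destabilisation grows (+0.8 / +1.4). No
#' measurement exists for the A-Y mismatch categories; their offsets default
#' to 0. Applying hairpin-derived offsets to arbitrary contexts is an
#' approximation, flagged on the table.
#'
#' @param condition `"with_mg"` or `"no_mg"`.
#' @return Named numeric vector of ddG offsets over [MOTIF_CATEGORIES], with
#'   attributes `condition` and `approximation`.
#' @export
m6a_penalty_table <- function(condition = c("with_mg", "no_mg")) {
  condition <- match.arg(condition)
  tab <- if (condition == "with_mg") {
    c(duplex_AU = 0.6, duplex_AY = 0, unpaired = 0.7,
      fiveB_AU = -0.9, fiveB_AY = 0, AU_threeB = 1.2, AY_threeB = 0,
      partner_bulge = 0.4)
  } else {
    c(duplex_AU = 0.8, duplex_AY = 0, unpaired = 0.7,
      fiveB_AU = -0.3, fiveB_AY = 0, AU_threeB = 1.2, AY_threeB = 0,
      partner_bulge = 1.4)
  }
  tab <- tab[MOTIF_CATEGORIES]
  attr(tab, "condition") <- condition
  attr(tab, "approximation") <- "hairpin-derived offsets applied per category"
  tab
}

#' Re-rank a suboptimal ensemble with m6A context offsets
#'
#' Adds to each structure's energy the offset of its motif category at the
#' focal A (methylation rewards the 5' bulge junctional motif and penalises
#' duplex/bulge contexts), re-sorts, and reports whether the identity of the
#' minimum-energy structure changed — the mechanism by which methylation can
#' bias a folding landscape toward junctional motifs.
#'
#' @param ensemble a `subopt_ensemble`.
#' @param a_index focal-A index.
#' @param penalties named offsets as from [m6a_penalty_table()].
#' @return list with `ensemble` (re-ranked; energies adjusted), `mfe_changed`
#'   (logical), `categories` (per input structure) and `penalties_used`.
#' @export
rerank_with_m6a <- function(ensemble, a_index,
                            penalties = m6a_penalty_table("with_mg")) {
  stopifnot(inherits(ensemble, "subopt_ensemble"))
  if (!length(ensemble$structures)) stop_domain("empty ensemble")
  if (!all(MOTIF_CATEGORIES %in% names(penalties)))
    stop_domain("penalty table must cover every motif category",
                "m6aj_argument_error")
  old_top <- format_dotbracket(ensemble$structures[[1L]])
  cats <- vapply(ensemble$structures,
                 function(x) classify_motif(x, a_index)$category, "")
  adj <- lapply(seq_along(ensemble$structures), function(k) {
    x <- ensemble$structures[[k]]
    x$energy <- x$energy + unname(penalties[cats[k]])
    x
  })
  en <- vapply(adj, `[[`, 0, "energy")
  db <- vapply(adj, format_dotbracket, "")
  o <- order(en, db)
  out <- new_subopt_ensemble(adj[o], mfe = min(en), window = ensemble$window,
                             mode = ensemble$mode)
  list(ensemble = out, mfe_changed = !identical(db[o][1L], old_top),
       categories = cats, penalties_used = penalties)
}

#' Sample control sites lacking the DRACH consensus
#'
#' Draws A-centred windows uniformly from a transcript set, rejecting any
#' window whose sequence contains a DRACH match (D = A/G/U, R = A/G, AC
#' core, H = A/C/U) anywhere — the construction of the unmethylated control
#' population for motif surveys. Deterministic given the seed.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param n number of control sites wanted.
#' @param length,a_offset window geometry (defaults 41 / 21).
#' @param seed RNG seed.
#' @param max_tries sampling attempts before giving up.
#' @return list of `site_window` objects (length `n`); raises an error
#'   reporting the achieved count if `n` cannot be reached.
#' @export
make_control_sites <- function(transcripts, n, length = 41L, a_offset = 21L,
                               seed = 1L, max_tries = 400L * n) {
  stopifnot(is.character(transcripts), !is.null(names(transcripts)), n >= 1L)
  lens <- nchar(transcripts)
  ok_t <- which(lens >= length)
  if (!length(ok_t))
    stop_domain("no transcript is long enough to host a window",
                "m6aj_argument_error")
  with_seed(seed, {
    out <- list()
    seen <- character()
    tries <- 0L
    while (length(out) < n && tries < max_tries) {
      tries <- tries + 1L
      ti <- ok_t[sample.int(length(ok_t), 1L)]
      pos <- sample.int(lens[ti] - length + 1L, 1L) + a_offset - 1L
      key <- paste(names(transcripts)[ti], pos)
      if (key %in% seen) next
      w <- tryCatch(extract_window(transcripts[[ti]], pos, length = length,
                                   a_offset = a_offset, strand = "+",
                                   id = names(transcripts)[ti]),
                    error = function(e) NULL)
      if (is.null(w)) next
      if (grepl(DRACH_REGEX, w$sequence)) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- w
    }
    if (length(out) < n)
      stop_domain(sprintf(
        "could only find %d/%d DRACH-free control windows in %d tries",
        length(out), n, tries), "m6aj_sampling_error")
    out
  })
}
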