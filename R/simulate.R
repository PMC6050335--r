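#' Seeded generators for synthetic inputs
#'
#' Every stage of the pipeline can be exercised without external data:
#' melting curves are drawn from the two-state models, titrations from the
#' binding isotherms, transcripts from a uniform base composition with
#' planted DRACH sites, and motif windows from designed hairpin templates
#' with ground-truth labels. All generators are pure functions of their seed
#' (i.i.d. Gaussian noise; defaults sigma = 0.01 folded-fraction units and
#' 0.002 anisotropy units).
#'
#' @name synthetic-data
NULL

#' Simulate a UV melting curve
#'
#' Evaluates the two-state folded fraction on a temperature grid (default 81
#' points over 15-95 C, the standard melt range) and adds Gaussian noise.
#'
#' @param model `"hairpin"` or `"duplex"`.
#' @param Tm,dH generating parameters (kelvin, kcal/mol).
#' @param ct total strand concentration (carried on the curve for duplex fits).
#' @param sigma noise SD in folded-fraction units.
#' @param seed RNG seed.
#' @param t_min_C,t_max_C,n_points temperature grid (celsius endpoints).
#' @return A [melting_curve()] with `signal_kind = "fraction"`.
#' @export
gen_melting_curve <- function(model = c("hairpin", "duplex"), Tm, dH, ct = NULL,
                              sigma = 0.01, seed = 1L,
                              t_min_C = 15, t_max_C = 95, n_points = 81L) {
  model <- match.arg(model)
  if (sigma < 0) stop_domain("`sigma` must be >= 0")
  TT <- seq(t_min_C, t_max_C, length.out = n_points) + 273.15
  f <- if (model == "hairpin") fraction_folded_hairpin(TT, Tm, dH)
       else fraction_folded_duplex(TT, Tm, dH)
  y <- if (sigma > 0) with_seed(seed, f + stats::rnorm(length(f), sd = sigma)) else f
  melting_curve(TT, pmin(pmax(y, -0.05), 1.05), signal_kind = "fraction", ct = ct)
}

#' Simulate an FP titration
#'
#' @param model `"one_site"` or `"two_site"`.
#' @param params named list of generating parameters: `KD`, `A`, `B` for
#'   one-site; `KD1`, `KD2`, `A`, `B`, `C` for two-site (mol/L, anisotropy).
#' @param rt trace RNA concentration, mol/L.
#' @param conc protein concentration grid, mol/L (default 12 points,
#'   log-spaced 1 nM - 30 uM).
#' @param sigma anisotropy noise SD.
#' @param seed RNG seed.
#' @return A [titration_curve()].
#' @export
gen_titration <- function(model = c("one_site", "two_site"), params, rt = 2e-9,
                          conc = 10^seq(log10(1e-9), log10(30e-6), length.out = 12),
                          sigma = 0.002, seed = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stop_domain("`sigma` must be >= 0")
  y <- if (model == "one_site") {
    anisotropy_one_site(conc, rt, params$KD, params$A, params$B)
  } else {
    anisotropy_two_site(conc, params$KD1, params$KD2, params$A, params$B, params$C)
  }
  if (sigma > 0) y <- with_seed(seed, y + stats::rnorm(length(y), sd = sigma))
  titration_curve(conc, y, rt = rt)
}

#' Two-state parameters encoding a target methylation ddG
#'
#' Given the unmodified parameters and a signed target
#' \eqn{\Delta\Delta G = \Delta G_{m6A} - \Delta G_{unmod}} at `t_eval`,
#' solves for the methylated Tm at a chosen methylated enthalpy (the free
#' energy at `t_eval` is \eqn{\Delta H (1 - T/T_m)} for a hairpin, plus
#' \eqn{T R \ln(C_T/2)} for a duplex). Used to build paired synthetic melts
#' whose generating contrast is known exactly.
#'
#' @param Tm_u,dH_u unmodified parameters.
#' @param ddG signed target difference, kcal/mol (negative = stabilising).
#' @param dH_m methylated enthalpy, kcal/mol.
#' @param model `"hairpin"` or `"duplex"` (duplex needs `ct`).
#' @param ct total strand concentration, mol/L.
#' @param t_eval evaluation temperature, kelvin.
#' @return list with `Tm`, `dH` for the methylated construct and the exact
#'   `dG_u`, `dG_m` at `t_eval`.
#' @export
gen_paired_melt_params <- function(Tm_u, dH_u, ddG, dH_m,
                                   model = c("hairpin", "duplex"), ct = NULL,
                                   t_eval = 310.15) {
  model <- match.arg(model)
  lterm <- if (model == "duplex") {
    if (is.null(ct)) stop_domain("`ct` required for duplex", "m6aj_argument_error")
    t_eval * RGAS * log(ct / 2)
  } else 0
  dG_u <- dH_u * (1 - t_eval / Tm_u) + lterm
  dG_m <- dG_u + ddG
  Tm_m <- dH_m * t_eval / (dH_m - dG_m + lterm)
  list(Tm = Tm_m, dH = dH_m, dG_u = dG_u, dG_m = dG_m)
}

DRACH_D <- c("A", "G", "U")
DRACH_R <- c("A", "G")
DRACH_H <- c("A", "C", "U")

#' Simulate transcripts with planted m6A consensus sites
#'
#' Generates random-composition transcripts and plants DRACH 5-mers
#' (D = A/G/U, R = A/G, AC core, H = A/C/U; the planted A is the site) at
#' recorded, non-overlapping positions placed so a default analysis window
#' fits around each site. Background composition is uniform by default with
#' a tunable GC content.
#'
#' @param n_transcripts number of transcripts.
#' @param length transcript length(s), recycled.
#' @param sites_per_transcript planted DRACH sites per transcript (0 = none).
#' @param gc background GC fraction.
#' @param seed RNG seed.
#' @param margin minimum distance of a planted A from either transcript end
#'   (default 20 nt, so 41-nt centred windows fit).
#' @return list with `transcripts` (named character vector) and `sites`
#'   (data frame `transcript_id`, `position`, `strand`).
#' @export
gen_transcripts <- function(n_transcripts, length = 300L, sites_per_transcript = 2L,
                            gc = 0.5, seed = 1L, margin = 20L) {
  if (sites_per_transcript < 0) stop_domain("`sites_per_transcript` must be >= 0")
  lens <- rep_len(as.integer(length), n_transcripts)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  with_seed(seed, {
    transcripts <- character(n_transcripts)
    names(transcripts) <- sprintf("tx%03d", seq_len(n_transcripts))
    site_rows <- list()
    for (t in seq_len(n_transcripts)) {
      L <- lens[t]
      b <- sample(names(probs), L, replace = TRUE, prob = probs)
      if (sites_per_transcript > 0) {
        lo <- margin + 1L + 2L            # planted A needs margin; A is 5-mer pos 3
        hi <- L - margin - 2L
        candidates <- if (hi >= lo) seq.int(lo, hi) else integer()
        placed <- integer()
        for (s in seq_len(sites_per_transcript)) {
          ok <- candidates[vapply(candidates,
                                  function(p) all(abs(p - placed) >= 5L), TRUE)]
          if (!length(ok))
            stop_domain(sprintf(
              "transcript %d: cannot place %d non-overlapping DRACH sites",
              t, sites_per_transcript), "m6aj_sampling_error")
          p <- ok[sample.int(length(ok), 1L)]
          placed <- c(placed, p)
          fivemer <- c(sample(DRACH_D, 1L), sample(DRACH_R, 1L), "A", "C",
                       sample(DRACH_H, 1L))
          b[(p - 2L):(p + 2L)] <- fivemer
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            transcript_id = names(transcripts)[t], position = p, strand = "+")
        }
      }
      transcripts[t] <- paste(b, collapse = "")
    }
    sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(transcript_id = character(), position = integer(),
                 strand = character())
    list(transcripts = transcripts, sites = sites)
  })
}

# Designed hairpin templates realising each motif category at the focal A.
# The canonical-category templates are designed so their drawn structure is
# also the MFE under the default energy model (asserted in the test suite);
# the A-Y templates exist as drawn structures for classifier testing since
# the engine itself never emits non-canonical pairs.
motif_templates <- function() {
  list(
    fiveB_AU = list(sequence = "GGCGACUUUCGAGUGCC",
                    dotbracket = "(((.(((....))))))", a_index = 5L),
    duplex_AU = list(sequence = "GGCACGGUUCGCCGUGCC",
                     dotbracket = "(((((((....)))))))", a_index = 4L),
    unpaired = list(sequence = "GGCGCAAUAAGCGCC",
                    dotbracket = "(((((.....)))))", a_index = 6L),
    AU_threeB = list(sequence = "GGCAUGGCUUCGGCCUGCC",
                     dotbracket = "((((.(((....)))))))", a_index = 4L),
    partner_bulge = list(sequence = "GGCAGCGAAAAGCAUGCC",
                         dotbracket = "((((((.....)).))))", a_index = 4L),
    fiveB_AY = list(sequence = "GGCAAGCAAAAGCCGCC",
                    dotbracket = "(((..((....)).)))", a_index = 5L),
    AY_threeB = list(sequence = "GGCAAGCAAAAGCCGCC",
                     dotbracket = "(((..((....)).)))", a_index = 4L),
    duplex_AY = list(sequence = "GGCAGCGAAAGCCGCC",
                     dotbracket = "(((.((....)).)))", a_index = 4L)
  )
}

#' Generate labelled motif windows from designed templates
#'
#' Builds hairpin windows whose designed structure realises a requested mix
#' of motif categories at the focal A, with ground-truth labels attached for
#' classifier and end-to-end testing. Counts are allocated deterministically
#' by largest remainder; the seed only shuffles the output order.
#'
#' @param mix named fractions over motif categories (must sum to 1).
#' @param n number of windows.
#' @param seed RNG seed (output order).
#' @return list of entries, each with `sequence`, `a_index`, `structure`
#'   (the designed `rna_structure`) and `label`.
#' @export
gen_motif_windows <- function(mix, n, seed = 1L) {
  if (abs(sum(mix) - 1) > 1e-9)
    stop_domain("category fractions must sum to 1", "m6aj_argument_error")
  tpl <- motif_templates()
  unknown <- setdiff(names(mix), names(tpl))
  if (length(unknown))
    stop_domain(paste("no template for category:", paste(unknown, collapse = ", ")),
                "m6aj_argument_error")
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1L
  }
  out <- list()
  for (cat_name in names(mix)) {
    t <- tpl[[cat_name]]
    st <- parse_dotbracket(t$sequence, t$dotbracket)
    st$energy <- structure_energy(st)
    for (k in seq_len(counts[[cat_name]])) {
      out[[length(out) + 1L]] <- list(sequence = t$sequence,
                                      a_index = t$a_index,
                                      structure = st, label = cat_name)
    }
  }
  with_seed(seed, out[sample.int(length(out))])
}
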