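# Internal helpers shared across modules.

# Gas constant in kcal mol^-1 K^-1, the unit system used throughout.
RGAS <- 0.0019872

# DRACH consensus: D = A/G/U, R = A/G, then AC core, H = A/C/U.
DRACH_REGEX <- "[AGU][AG]AC[ACU]"

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_domain <- function(msg, class = "m6aj_domain_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validate_rna_string <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop_domain("`sequence` must be a single non-empty string")
  s <- toupper(sequence)
  if (grepl("[^ACGU]", s))
    stop_domain(sprintf("invalid characters in RNA sequence: %s",
                        gsub("[ACGU]", "", s)))
  s
}
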