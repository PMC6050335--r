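#' RNA secondary structure objects
#'
#' A secondary structure is a sequence over \{A,C,G,U\} plus a set of
#' non-crossing base pairs (1-based, fully closed coordinates) and an energy
#' in kcal/mol. Allowed pairs are the Watson-Crick pairs plus G-U wobbles;
#' hairpin loops must enclose at least `min_loop` unpaired nucleotides.
#' Pseudoknots are not representable.
#'
#' @param sequence RNA string over A/C/G/U (case-insensitive).
#' @param pairs two-column integer matrix of pairs `(i, j)` with `i < j`,
#'   or an empty matrix/NULL for the open chain.
#' @param energy energy in kcal/mol (the open chain has energy 0).
#' @param modified optional integer vector of m6A positions (adenosines
#'   carrying the N6-methyl flag; pairing legality is unchanged).
#' @param validate check the structural invariants (default TRUE).
#' @param min_loop minimum hairpin loop size used for validation.
#' @return An object of class `rna_structure`.
#' @examples
#' parse_dotbracket("GGGAAAACCC", "(((....)))")
#' @export
rna_structure <- function(sequence, pairs = NULL, energy = 0, modified = integer(),
                          validate = TRUE, min_loop = 3L) {
  sequence <- validate_rna_string(sequence)
  n <- nchar(sequence)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  x <- structure(list(sequence = sequence, pairs = pairs,
                      energy = as.numeric(energy),
                      modified = as.integer(modified)),
                 class = "rna_structure")
  if (validate) validate_structure(x, min_loop = min_loop)
  x
}

# partner vector: pt[i] = partner of i, 0 if unpaired
pair_table <- function(x) {
  n <- nchar(x$sequence)
  pt <- integer(n)
  if (nrow(x$pairs)) {
    pt[x$pairs[, 1L]] <- x$pairs[, 2L]
    pt[x$pairs[, 2L]] <- x$pairs[, 1L]
  }
  pt
}

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

can_pair <- function(b1, b2) paste0(b1, b2) %in% ALLOWED_PAIRS

#' Validate the invariants of a secondary structure
#'
#' Checks index ranges, that no base is in two pairs, that all pairs are in
#' the allowed set (Watson-Crick + G-U), that hairpin loops enclose at least
#' `min_loop` unpaired bases, and that no two pairs cross (pseudoknot-free).
#'
#' @param x an `rna_structure`.
#' @param min_loop minimum hairpin loop size (default 3).
#' @return `x`, invisibly; errors on violation.
#' @export
validate_structure <- function(x, min_loop = 3L) {
  stopifnot(inherits(x, "rna_structure"))
  n <- nchar(x$sequence)
  p <- x$pairs
  if (!nrow(p)) return(invisible(x))
  if (any(p < 1L) || any(p > n))
    stop_domain("pair index out of range", "m6aj_structure_error")
  if (any(p[, 1L] >= p[, 2L]))
    stop_domain("pairs must satisfy i < j", "m6aj_structure_error")
  idx <- c(p)
  if (anyDuplicated(idx))
    stop_domain("a base participates in more than one pair", "m6aj_structure_error")
  if (any(p[, 2L] - p[, 1L] - 1L < min_loop))
    stop_domain(sprintf("hairpin loop smaller than min_loop = %d", min_loop),
                "m6aj_structure_error")
  b <- strsplit(x$sequence, "")[[1L]]
  bad <- !paste0(b[p[, 1L]], b[p[, 2L]]) %in% ALLOWED_PAIRS
  if (any(bad))
    stop_domain(sprintf("disallowed base pair at (%d,%d)",
                        p[which(bad)[1L], 1L], p[which(bad)[1L], 2L]),
                "m6aj_structure_error")
  # crossing check: for sorted pairs, every later pair must nest or be disjoint
  for (k in seq_len(nrow(p) - 1L)) {
    i <- p[k, 1L]; j <- p[k, 2L]
    inside <- p[, 1L] > i & p[, 1L] < j
    if (any(p[inside, 2L] > j))
      stop_domain("crossing pairs (pseudoknot)", "m6aj_structure_error")
  }
  invisible(x)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", format_dotbracket(x), sprintf(" (%.2f)\n", x$energy), sep = "")
  invisible(x)
}

#' Dot-bracket serialisation
#'
#' `format_dotbracket()` renders the pair set as a Vienna dot-bracket string;
#' `parse_dotbracket()` builds an `rna_structure` from one.
#'
#' @param x an `rna_structure`.
#' @return For `format_dotbracket`, a string of `(`, `)` and `.`.
#' @export
format_dotbracket <- function(x) {
  n <- nchar(x$sequence)
  db <- rep(".", n)
  if (nrow(x$pairs)) {
    db[x$pairs[, 1L]] <- "("
    db[x$pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

#' @rdname format_dotbracket
#' @param sequence RNA string.
#' @param dotbracket matching dot-bracket string.
#' @param energy energy annotation in kcal/mol.
#' @inheritParams rna_structure
#' @export
parse_dotbracket <- function(sequence, dotbracket, energy = 0, validate = TRUE,
                             min_loop = 3L) {
  if (nchar(sequence) != nchar(dotbracket))
    stop_domain("sequence and structure lengths differ", "m6aj_parse_error")
  ch <- strsplit(dotbracket, "")[[1L]]
  if (any(!ch %in% c("(", ")", ".")))
    stop_domain("dot-bracket may only contain '(', ')' and '.'", "m6aj_parse_error")
  stack <- integer(0)
  pairs <- matrix(integer(), ncol = 2L)
  plist <- list()
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (!length(stack))
        stop_domain(sprintf("unbalanced ')' at position %d", k), "m6aj_parse_error")
      plist[[length(plist) + 1L]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop_domain(sprintf("unbalanced '(' at position %d", stack[1L]), "m6aj_parse_error")
  if (length(plist)) pairs <- do.call(rbind, plist)
  rna_structure(sequence, pairs, energy = energy, validate = validate,
                min_loop = min_loop)
}

#' Read and write CT (connectivity table) files
#'
#' The standard 6-column CT layout: a header line `n  title [energy]`
#' followed by one row per nucleotide with index, base, i-1, i+1, pairing
#' partner (0 if unpaired) and the index again. Files may concatenate several
#' records.
#'
#' @param path file path.
#' @param structures list of `rna_structure` objects (for writing).
#' @return `read_ct()` returns a list of `rna_structure` objects.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  k <- 1L
  while (k <= length(lines)) {
    hdr <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    n <- suppressWarnings(as.integer(hdr[1L]))
    if (is.na(n) || n < 1L)
      stop_domain(sprintf("CT line %d: expected a record header", k), "m6aj_parse_error")
    energy <- 0
    rest <- sub("^\\s*[0-9]+", "", lines[k])
    em <- regmatches(rest, regexpr("-?[0-9]+\\.?[0-9]*", rest))
    if (length(em)) energy <- as.numeric(em[1L])
    if (k + n > length(lines))
      stop_domain(sprintf("CT line %d: truncated record (need %d rows)", k, n),
                  "m6aj_parse_error")
    bases <- character(n)
    partner <- integer(n)
    for (r in seq_len(n)) {
      f <- strsplit(trimws(lines[k + r]), "\\s+")[[1L]]
      if (length(f) < 6L)
        stop_domain(sprintf("CT line %d: expected 6 columns", k + r), "m6aj_parse_error")
      idx <- as.integer(f[1L])
      if (idx != r)
        stop_domain(sprintf("CT line %d: index %s out of order", k + r, f[1L]),
                    "m6aj_parse_error")
      bases[r] <- f[2L]
      partner[r] <- as.integer(f[5L])
    }
    if (any(partner > n | partner < 0L))
      stop_domain(sprintf("CT record at line %d: partner index out of range", k),
                  "m6aj_parse_error")
    bad <- which(partner > 0L & partner[pmax(partner, 1L)] != seq_len(n))
    if (length(bad))
      stop_domain(sprintf("CT record at line %d: inconsistent pairing at row %d",
                          k, bad[1L]), "m6aj_parse_error")
    pr <- which(partner > seq_len(n))
    pairs <- cbind(pr, partner[pr])
    out[[length(out) + 1L]] <- rna_structure(paste(bases, collapse = ""),
                                             pairs, energy = energy)
    k <- k + n + 1L
  }
  if (!length(out)) stop_domain("empty CT file", "m6aj_parse_error")
  out
}

#' @rdname read_ct
#' @export
write_ct <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (x in structures) {
    n <- nchar(x$sequence)
    b <- strsplit(x$sequence, "")[[1L]]
    pt <- pair_table(x)
    writeLines(sprintf("%d  ENERGY = %.2f", n, x$energy), con)
    writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), b,
                       seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                       pt, seq_len(n)), con)
  }
  invisible(path)
}

#' Import externally predicted structures
#'
#' Adapter so that output from external structure-prediction programs can
#' drive the motif classifier. Dot-bracket files contain an optional `>id`
#' header, a sequence line, then one or more structure lines each optionally
#' suffixed with an energy in parentheses; CT files follow the standard
#' 6-column layout.
#'
#' @param path input file.
#' @param format `"dotbracket"` or `"ct"`.
#' @return A [subopt_ensemble] (list of structures sorted by energy).
#' @export
import_structures <- function(path, format = c("dotbracket", "ct")) {
  format <- match.arg(format)
  structs <- if (format == "ct") read_ct(path) else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && startsWith(lines[1L], ">")) lines <- lines[-1L]
    if (length(lines) < 2L)
      stop_domain("dot-bracket file needs a sequence line and a structure line",
                  "m6aj_parse_error")
    seqline <- toupper(trimws(lines[1L]))
    seqline <- gsub("T", "U", seqline)
    lapply(seq.int(2L, length(lines)), function(k) {
      ln <- trimws(lines[k])
      energy <- 0
      m <- regmatches(ln, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", ln))
      if (length(m)) {
        energy <- as.numeric(gsub("[() ]", "", m))
        ln <- trimws(sub("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", ln))
      }
      tryCatch(parse_dotbracket(seqline, ln, energy = energy),
               error = function(e) stop_domain(
                 sprintf("line %d: %s", k, conditionMessage(e)), "m6aj_parse_error"))
    })
  }
  structs <- structs[order(vapply(structs, `[[`, 0, "energy"))]
  new_subopt_ensemble(structs, mfe = structs[[1L]]$energy, window = NA_real_)
}

#' Write structures as a Vienna dot-bracket file
#'
#' @param structures an `rna_structure`, a list of them, or a
#'   `subopt_ensemble`; all must share one sequence.
#' @param path output file.
#' @param id FASTA-style identifier for the header line.
#' @export
write_dotbracket <- function(structures, path, id = "seq") {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  if (inherits(structures, "subopt_ensemble")) structures <- structures$structures
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0(">", id), structures[[1L]]$sequence), con)
  for (x in structures)
    writeLines(sprintf("%s (%.2f)", format_dotbracket(x), x$energy), con)
  invisible(path)
}
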