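#' Minimum-free-energy folding and exhaustive suboptimal enumeration
#'
#' `fold_mfe()` computes a minimum-free-energy secondary structure by
#' dynamic programming over the loop-based energy model; `subopt()`
#' enumerates, by Wuchty-style backtracking with exact lower bounds, the
#' complete, duplicate-free set of structures within an energy window of the
#' MFE; `enumerate_all_structures()` is the brute-force oracle that lists
#' every valid structure of a short sequence and scores it with the same
#' [structure_energy()] used everywhere else.
#'
#' The DP uses an unambiguous decomposition (exterior / closed / multiloop
#' with >= 1 branch / multiloop with >= 2 branches), so each structure is
#' produced exactly once during enumeration. Ties in the MFE are broken
#' deterministically toward 5'-most pairing (lexicographically smallest
#' dot-bracket string).
#'
#' @param sequence RNA string over A/C/G/U.
#' @param model an [default_energy_model()].
#' @name folding
NULL

# DP matrices for the unambiguous grammar:
#   V[i,j]  best energy with (i,j) paired
#   M[i,j]  multiloop segment, >= 1 branch (unpaired cost c, branch cost b)
#   M2[i,j] multiloop segment, >= 2 branches
#   W[j]    exterior prefix 1..j (index offset by 1; W[1] is the empty prefix)
fold_matrices <- function(sequence, model = default_energy_model()) {
  s <- validate_rna_string(sequence)
  b <- strsplit(s, "")[[1L]]
  n <- length(b)
  ml <- model$min_loop
  P <- matrix(FALSE, n, n)
  pcode <- matrix(NA_character_, n, n)
  if (n >= ml + 2L) {
    for (i in seq_len(n - ml - 1L)) for (j in seq.int(i + ml + 1L, n)) {
      cd <- paste0(b[i], b[j])
      if (cd %in% ALLOWED_PAIRS) { P[i, j] <- TRUE; pcode[i, j] <- cd }
    }
  }
  V <- matrix(Inf, n, n)
  M <- matrix(Inf, n, n)
  M2 <- matrix(Inf, n, n)
  if (n >= ml + 2L) for (d in seq.int(ml + 1L, n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      if (P[i, j]) {
        best <- loop_penalty(model$hairpin, j - i - 1L, model)
        kmax <- min(j - ml - 2L, i + 1L + model$max_interior)
        if (kmax >= i + 1L) for (k in seq.int(i + 1L, kmax)) {
          n1 <- k - i - 1L
          lmin <- max(k + ml + 1L, j - 1L - (model$max_interior - n1))
          if (lmin <= j - 1L) for (l in seq.int(lmin, j - 1L)) {
            if (P[k, l] && is.finite(V[k, l])) {
              e2 <- two_loop_energy(model, pcode[i, j], pcode[k, l], n1, j - l - 1L)
              cand <- e2 + V[k, l]
              if (cand < best) best <- cand
            }
          }
        }
        if (is.finite(M2[i + 1L, j - 1L])) {
          cand <- model$ml_a + model$ml_b + M2[i + 1L, j - 1L]
          if (cand < best) best <- cand
        }
        V[i, j] <- best
      }
      # M[i,j]: j unpaired | last branch (k,j) with left side empty or >= 1 branch
      best <- if (j - 1L >= i && is.finite(M[i, j - 1L])) M[i, j - 1L] + model$ml_c else Inf
      for (k in seq.int(i, max(i, j - ml - 1L))) {
        if (k <= j - ml - 1L && P[k, j] && is.finite(V[k, j])) {
          cand <- (k - i) * model$ml_c + V[k, j] + model$ml_b
          if (cand < best) best <- cand
          if (k - 1L >= i && is.finite(M[i, k - 1L])) {
            cand <- M[i, k - 1L] + V[k, j] + model$ml_b
            if (cand < best) best <- cand
          }
        }
      }
      M[i, j] <- best
      best <- if (j - 1L >= i && is.finite(M2[i, j - 1L])) M2[i, j - 1L] + model$ml_c else Inf
      for (k in seq.int(i + 1L, max(i + 1L, j - ml - 1L))) {
        if (k <= j - ml - 1L && P[k, j] && is.finite(V[k, j]) &&
            k - 1L >= i && is.finite(M[i, k - 1L])) {
          cand <- M[i, k - 1L] + V[k, j] + model$ml_b
          if (cand < best) best <- cand
        }
      }
      M2[i, j] <- best
    }
  }
  W <- numeric(n + 1L)  # W[j+1] = best energy on prefix 1..j
  for (j in seq_len(n)) {
    best <- W[j]
    if (j >= ml + 2L) for (k in seq_len(j - ml - 1L)) {
      if (P[k, j] && is.finite(V[k, j])) {
        cand <- W[k] + V[k, j]
        if (cand < best) best <- cand
      }
    }
    W[j + 1L] <- best
  }
  list(sequence = s, n = n, P = P, pcode = pcode, V = V, M = M, M2 = M2, W = W,
       model = model)
}

new_subopt_ensemble <- function(structures, mfe, window, mode = "kcal") {
  structure(list(structures = structures, mfe = mfe, window = window,
                 mode = mode), class = "subopt_ensemble")
}

#' @export
print.subopt_ensemble <- function(x, ...) {
  cat(sprintf("<subopt_ensemble> %d structures, MFE %.2f kcal/mol, window %s %s\n",
              length(x$structures), x$mfe,
              if (is.na(x$window)) "?" else format(x$window), x$mode))
  invisible(x)
}

#' @export
length.subopt_ensemble <- function(x) length(x$structures)

#' @rdname folding
#' @param window energy window above the MFE: kcal/mol (`mode = "kcal"`) or a
#'   percentage (`mode = "percent"`, threshold = MFE + |MFE| * window/100).
#' @param mode window semantics, `"kcal"` or `"percent"`.
#' @param max_structures guard against combinatorial explosion; exceeding it
#'   raises a truncation error carrying the count reached.
#' @return `subopt()` returns a `subopt_ensemble`: all valid structures with
#'   energy at or below the threshold, sorted by energy (ties by dot-bracket
#'   string), MFE structure first.
#' @export
subopt <- function(sequence, model = default_energy_model(), window = 3,
                   mode = c("kcal", "percent"), max_structures = 20000L) {
  mode <- match.arg(mode)
  if (!is.finite(window) || window < 0) stop_domain("`window` must be >= 0")
  fm <- fold_matrices(sequence, model)
  mfe <- fm$W[fm$n + 1L]
  thr <- if (mode == "kcal") mfe + window else mfe + abs(mfe) * window / 100
  structs <- enumerate_within(fm, thr, max_structures)
  db <- vapply(structs, format_dotbracket, "")
  en <- vapply(structs, `[[`, 0, "energy")
  o <- order(en, db)
  new_subopt_ensemble(structs[o], mfe = mfe, window = window, mode = mode)
}

# Wuchty-style exhaustive backtracking: expand partial states whose exact
# lower bound stays within `thr`; emits every qualifying structure once.
enumerate_within <- function(fm, thr, max_structures) {
  eps <- 1e-6
  ml <- fm$model$min_loop
  a <- fm$model$ml_a; bb <- fm$model$ml_b; cc <- fm$model$ml_c
  bnd <- function(iv) {
    switch(iv[1L],
           fm$V[iv[2L], iv[3L]],
           fm$M[iv[2L], iv[3L]],
           fm$M2[iv[2L], iv[3L]],
           fm$W[iv[3L] + 1L])
  }
  out <- list()
  # state: list(iv = list of c(type, i, j), E, pairs = list of c(i,j))
  stack <- list(list(iv = if (fm$n >= 1L) list(c(4L, 1L, fm$n)) else list(),
                     E = 0, pairs = list()))
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!length(st$iv)) {
      out[[length(out) + 1L]] <- st
      if (length(out) > max_structures)
        stop(structure(class = c("m6aj_truncation_error", "error", "condition"),
                       list(message = sprintf(
                         "suboptimal enumeration exceeded max_structures = %d",
                         max_structures), call = sys.call())))
      next
    }
    iv <- st$iv[[1L]]
    rest <- st$iv[-1L]
    rest_bound <- if (length(rest)) sum(vapply(rest, bnd, 0)) else 0
    base <- st$E + rest_bound
    push <- function(dE, new_iv, new_pair = NULL) {
      nb <- sum(vapply(new_iv, bnd, 0))
      if (base + dE + nb <= thr + eps) {
        stack[[length(stack) + 1L]] <<- list(
          iv = c(new_iv, rest), E = st$E + dE,
          pairs = if (is.null(new_pair)) st$pairs else c(st$pairs, list(new_pair)))
      }
    }
    type <- iv[1L]; i <- iv[2L]; j <- iv[3L]
    if (type == 4L) {            # exterior prefix 1..j
      if (j == 0L) { st$iv <- rest; stack[[length(stack) + 1L]] <- st; next }
      push(0, if (j > 1L) list(c(4L, 1L, j - 1L)) else list())
      if (j >= ml + 2L) for (k in seq_len(j - ml - 1L)) {
        if (fm$P[k, j] && is.finite(fm$V[k, j]))
          push(0, c(list(c(1L, k, j)), if (k > 1L) list(c(4L, 1L, k - 1L))),
               new_pair = c(k, j))
      }
    } else if (type == 1L) {     # V: (i,j) is paired
      hp <- loop_penalty(fm$model$hairpin, j - i - 1L, fm$model)
      if (is.finite(hp)) push(hp, list())
      kmax <- min(j - ml - 2L, i + 1L + fm$model$max_interior)
      if (kmax >= i + 1L) for (k in seq.int(i + 1L, kmax)) {
        n1 <- k - i - 1L
        lmin <- max(k + ml + 1L, j - 1L - (fm$model$max_interior - n1))
        if (lmin <= j - 1L) for (l in seq.int(lmin, j - 1L)) {
          if (fm$P[k, l] && is.finite(fm$V[k, l])) {
            e2 <- two_loop_energy(fm$model, fm$pcode[i, j], fm$pcode[k, l],
                                  n1, j - l - 1L)
            if (is.finite(e2)) push(e2, list(c(1L, k, l)), new_pair = c(k, l))
          }
        }
      }
      if (j - 1L >= i + 1L && is.finite(fm$M2[i + 1L, j - 1L]))
        push(a + bb, list(c(3L, i + 1L, j - 1L)))
    } else if (type == 2L) {     # M: >= 1 branch on i..j
      if (j - 1L >= i && is.finite(fm$M[i, j - 1L]))
        push(cc, list(c(2L, i, j - 1L)))
      if (j >= i + ml + 1L) for (k in seq.int(i, j - ml - 1L)) {
        if (fm$P[k, j] && is.finite(fm$V[k, j])) {
          push((k - i) * cc + bb, list(c(1L, k, j)), new_pair = c(k, j))
          if (k - 1L >= i && is.finite(fm$M[i, k - 1L]))
            push(bb, list(c(2L, i, k - 1L), c(1L, k, j)), new_pair = c(k, j))
        }
      }
    } else {                     # M2: >= 2 branches on i..j
      if (j - 1L >= i && is.finite(fm$M2[i, j - 1L]))
        push(cc, list(c(3L, i, j - 1L)))
      if (j >= i + ml + 2L) for (k in seq.int(i + 1L, j - ml - 1L)) {
        if (fm$P[k, j] && is.finite(fm$V[k, j]) && is.finite(fm$M[i, k - 1L]))
          push(bb, list(c(2L, i, k - 1L), c(1L, k, j)), new_pair = c(k, j))
      }
    }
  }
  lapply(out, function(st) {
    pairs <- if (length(st$pairs)) do.call(rbind, st$pairs) else NULL
    rna_structure(fm$sequence, pairs, energy = st$E, validate = FALSE)
  })
}

#' @rdname folding
#' @return `fold_mfe()` returns the MFE `rna_structure` (the open chain with
#'   energy 0 when no pairing is favourable).
#' @export
fold_mfe <- function(sequence, model = default_energy_model()) {
  ens <- subopt(sequence, model, window = 0, mode = "kcal")
  ens$structures[[1L]]
}

#' @rdname folding
#' @param min_loop minimum hairpin loop size for the oracle (taken from the
#'   model).
#' @param max_len refuse sequences longer than this (exhaustive recursion).
#' @return `enumerate_all_structures()` returns a list of every valid
#'   `rna_structure` (including the open chain), each scored with
#'   [structure_energy()], in no particular order.
#' @export
enumerate_all_structures <- function(sequence, model = default_energy_model(),
                                     max_len = 22L) {
  s <- validate_rna_string(sequence)
  n <- nchar(s)
  if (n > max_len)
    stop_domain(sprintf("refusing exhaustive enumeration beyond %d nt", max_len),
                "m6aj_guard_error")
  b <- strsplit(s, "")[[1L]]
  ml <- model$min_loop
  rec <- function(i, j) {
    if (j - i < ml + 1L) return(list(list()))
    res <- lapply(rec(i + 1L, j), identity)  # i unpaired
    for (k in seq.int(i + ml + 1L, j)) {
      if (can_pair(b[i], b[k])) {
        inner <- rec(i + 1L, k - 1L)
        outer <- rec(k + 1L, j)
        for (si in inner) for (so in outer)
          res[[length(res) + 1L]] <- c(list(c(i, k)), si, so)
      }
    }
    res
  }
  sets <- if (n >= ml + 2L) rec(1L, n) else list(list())
  lapply(sets, function(ps) {
    x <- rna_structure(s, if (length(ps)) do.call(rbind, ps) else NULL,
                       validate = FALSE)
    x$energy <- structure_energy(x, model)
    x
  })
}

#' Count valid secondary structures by an independent recurrence
#'
#' Counts non-crossing structures over the allowed pair set with the hairpin
#' constraint via the memoised recurrence
#' `N(i,j) = N(i+1,j) + sum_k pairable(i,k) N(i+1,k-1) N(k+1,j)`.
#' Used as a second, enumeration-free oracle for the structure count.
#'
#' @inheritParams folding
#' @param min_loop minimum hairpin loop size.
#' @return Integer count (includes the open chain).
#' @export
count_structures <- function(sequence, min_loop = 3L) {
  s <- validate_rna_string(sequence)
  b <- strsplit(s, "")[[1L]]
  n <- length(b)
  memo <- new.env(hash = TRUE)
  cnt <- function(i, j) {
    if (j - i < min_loop + 1L) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (can_pair(b[i], b[k]))
        total <- total + cnt(i + 1L, k - 1L) * cnt(k + 1L, j)
    }
    memo[[key]] <- total
    total
  }
  cnt(1L, n)
}
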