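#' Nussinov-Jacobson pair-additive energy model
#'
#' The energy of a secondary structure is the sum of its base-pair scores
#' (kcal/mol, negative = stabilizing); there are no stacking or loop terms.
#' Pairs are restricted to the six canonical types and must enclose more
#' than `hairpin` unpaired nucleotides (`j - i > hairpin`). `RT` sets the
#' Boltzmann scale for partition functions (0.6163 kcal/mol is 37 C).
#'
#' The default scores (CG/GC -3, AU/UA -2, GU/UG -1) reflect the usual
#' 3/2/1 hydrogen-bond weighting; every computation takes the model as an
#' argument, so none of these constants is baked in.
#'
#' @param pair_scores Named numeric vector over
#'   `c("AU","UA","CG","GC","GU","UG")`.
#' @param hairpin Minimum number of unpaired nucleotides enclosed by a
#'   hairpin (nonnegative integer).
#' @param RT Energy scale in kcal/mol, positive.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(pair_scores = c(AU = -2, UA = -2, CG = -3,
                                         GC = -3, GU = -1, UG = -1),
                         hairpin = 3L, RT = 0.6163) {
  types <- c("AU", "UA", "CG", "GC", "GU", "UG")
  if (!all(types %in% names(pair_scores)))
    stop("pair_scores must name all six pair types: ",
         paste(types, collapse = ", "))
  if (length(hairpin) != 1L || hairpin < 0) stop("hairpin must be >= 0")
  if (length(RT) != 1L || RT <= 0) stop("RT must be positive")
  structure(list(pair_scores = pair_scores[types],
                 hairpin = as.integer(hairpin), RT = as.numeric(RT)),
            class = "energy_model")
}

# 4x4 score matrix (A,C,G,U order) with NA for disallowed pairs
pair_matrix <- function(model) {
  m <- matrix(NA_real_, 4, 4, dimnames = list(NUCS, NUCS))
  for (t in names(model$pair_scores)) {
    a <- substr(t, 1, 1); b <- substr(t, 2, 2)
    m[a, b] <- model$pair_scores[[t]]
  }
  m
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> pair-additive (Nussinov level)\n")
  cat("  scores (kcal/mol):",
      paste(names(x$pair_scores), x$pair_scores, sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  min hairpin: %d nt, RT = %.4f kcal/mol\n", x$hairpin, x$RT))
  invisible(x)
}

# canonical pair-list matrix: 2 columns (i, j), i < j, sorted by i
as_pair_matrix <- function(structure) {
  if (is.null(structure) || (is.matrix(structure) && nrow(structure) == 0) ||
      length(structure) == 0)
    return(matrix(integer(0), 0, 2))
  p <- matrix(as.integer(structure), ncol = 2)
  p <- t(apply(p, 1, sort))
  p <- matrix(p, ncol = 2) # guard 1-row apply collapse
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

# check a structure against sequence and model; stop naming the bad pair
validate_structure <- function(x, pairs, model) {
  x <- rna_string(x)
  n <- nchar(x)
  chars <- strsplit(x, "")[[1]]
  p <- as_pair_matrix(pairs)
  if (nrow(p) == 0) return(p)
  bad_pair <- function(r, why)
    stop(sprintf("invalid pair (%d,%d): %s", p[r, 1], p[r, 2], why))
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1]; j <- p[r, 2]
    if (i < 1 || j > n) bad_pair(r, "out of range")
    if (j - i <= model$hairpin)
      bad_pair(r, sprintf("hairpin shorter than %d", model$hairpin + 1L))
    type <- paste0(chars[i], chars[j])
    if (!(type %in% names(model$pair_scores)))
      bad_pair(r, paste0("disallowed pair type ", type))
  }
  pos <- c(p[, 1], p[, 2])
  if (anyDuplicated(pos))
    stop(sprintf("position %d is in more than one pair",
                 pos[anyDuplicated(pos)]))
  if (nrow(p) > 1) {
    for (r in 2:nrow(p)) {
      for (s in 1:(r - 1)) {
        i <- p[s, 1]; j <- p[s, 2]; k <- p[r, 1]; l <- p[r, 2]
        if (i < k && k < j && j < l)
          stop(sprintf("crossing pairs (%d,%d) and (%d,%d)", i, j, k, l))
      }
    }
  }
  p
}

#' Free energy of a secondary structure
#'
#' Sum of pair scores under the pair-additive model; the empty structure has
#' energy 0. The structure is validated (pair types, clashes, crossings,
#' hairpin length) and rejected with the offending pair named.
#'
#' @param x mRNA sequence.
#' @param structure Pairs as a 2-column matrix of 1-based positions
#'   (or `NULL` for the open chain).
#' @param model An [energy_model()].
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(x, structure, model = energy_model()) {
  x <- rna_string(x)
  p <- validate_structure(x, structure, model)
  if (nrow(p) == 0) return(0)
  chars <- strsplit(x, "")[[1]]
  sum(model$pair_scores[paste0(chars[p[, 1]], chars[p[, 2]])])
}

#' Enumerate every secondary structure of a short sequence
#'
#' Exhaustive recursion over pseudoknot-free structures (each position in at
#' most one pair, no crossings, hairpin and pair-type constraints), always
#' including the empty structure. This is the brute-force oracle layer;
#' sequences longer than 30 nt are refused.
#'
#' @param x mRNA sequence, at most 30 nt.
#' @param model An [energy_model()].
#' @return List of pair matrices (2 columns), the first entry the empty
#'   structure.
#' @export
enumerate_structures <- function(x, model = energy_model()) {
  x <- rna_string(x)
  n <- nchar(x)
  if (n > 30) stop("sequence longer than 30 nt; enumeration refused")
  chars <- strsplit(x, "")[[1]]
  pm <- pair_matrix(model)
  h <- model$hairpin
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 1) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i, j - 1) # j unpaired
    for (k in seq(i, j - h - 1)) {
      if (k > j - h - 1) break
      if (is.na(pm[chars[k], chars[j]])) next
      left <- rec(i, k - 1)
      inner <- rec(k + 1, j - 1)
      for (a in left) for (b in inner)
        out <- c(out, list(rbind(a, matrix(c(k, j), 1, 2), b)))
    }
    out <- lapply(out, as_pair_matrix)
    memo[[key]] <- out
    out
  }
  if (n < 2) return(list(matrix(integer(0), 0, 2)))
  rec(1L, n)
}

#' Dot-bracket string for a secondary structure
#'
#' @param structure Pair matrix (2 columns, 1-based).
#' @param n Sequence length.
#' @return Character scalar of `(`, `)`, `.`.
#' @export
dot_bracket <- function(structure, n) {
  p <- as_pair_matrix(structure)
  s <- rep(".", n)
  if (nrow(p)) {
    s[p[, 1]] <- "("
    s[p[, 2]] <- ")"
  }
  paste(s, collapse = "")
}
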