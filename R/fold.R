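#' Minimum free energy structure of a single sequence
#'
#' Nussinov-style dynamic program under the pair-additive model. Among
#' equal-energy structures one with the fewest pairs is returned, via a
#' deterministic traceback (unpaired extension preferred, then the smallest
#' pairing partner), so results are reproducible.
#'
#' @param x mRNA sequence.
#' @param model An [energy_model()].
#' @return List with `energy` (kcal/mol), `structure` (pair matrix) and
#'   `dot_bracket`.
#' @examples
#' fold_mfe("GGGAAACCC")
#' @export
fold_mfe <- function(x, model = energy_model()) {
  x <- rna_string(x)
  seq_int <- match(strsplit(x, "")[[1]], NUCS) - 1L
  res <- nussinov_mfe_cpp(seq_int, pair_matrix(model), model$hairpin)
  list(energy = res$energy, structure = as_pair_matrix(res$pairs),
       dot_bracket = dot_bracket(res$pairs, nchar(x)))
}

#' Partition function, ensemble free energy and pairing probabilities
#'
#' Inside-outside dynamic program in log space over all pseudoknot-free
#' structures of `x`. The empty structure (energy 0) is always part of the
#' ensemble, so `Q >= 1` and the ensemble free energy
#' `dGens = -RT log Q <= 0`. The returned matrix `bpp` holds the pair
#' probabilities `p[i, j]` off the diagonal and the unpaired probabilities
#' `p[i, i]` on it; every row sums to 1.
#'
#' @param x mRNA sequence.
#' @param model An [energy_model()].
#' @return An object of class `ensemble_summary`: list with `sequence`,
#'   `logQ` (natural log), `efe` (kcal/mol) and `bpp`.
#' @examples
#' s <- partition_function("GAAAC")
#' s$efe
#' aup(s)
#' @export
partition_function <- function(x, model = energy_model()) {
  x <- rna_string(x)
  seq_int <- match(strsplit(x, "")[[1]], NUCS) - 1L
  res <- nussinov_pf_cpp(seq_int, pair_matrix(model), model$hairpin, model$RT)
  structure(list(sequence = x, logQ = res$logQ,
                 efe = -model$RT * res$logQ, bpp = res$bpp,
                 RT = model$RT),
            class = "ensemble_summary")
}

#' Average unpaired probability (AUP)
#'
#' Mean over positions of the probability of being unpaired in the
#' Boltzmann ensemble; lower AUP correlates with slower in-solution mRNA
#' degradation.
#'
#' @param summary An [partition_function()] result.
#' @return Fraction in `[0, 1]`.
#' @export
aup <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  mean(diag(summary$bpp))
}

#' Positional structural entropy
#'
#' `H2(i) = -sum_j p[i, j] ln p[i, j]` over each row of the pairing
#' probability matrix, including the unpaired term `p[i, i]` (natural log;
#' `0 log 0 := 0`). Higher values mean a flatter pairing distribution at
#' that position.
#'
#' @param summary An [partition_function()] result.
#' @return Numeric vector, one entropy (nats) per position.
#' @export
positional_entropy <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  apply(summary$bpp, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Write base-pairing probabilities as TSV triplets
#'
#' Rows `(i, j, p)` for `i <= j`; the diagonal rows carry the unpaired
#' probabilities.
#'
#' @param summary An [partition_function()] result.
#' @param path Output file path.
#' @param cutoff Smallest probability written (diagonal always written).
#' @return The path, invisibly.
#' @export
write_bpp_tsv <- function(summary, path, cutoff = 1e-6) {
  stopifnot(inherits(summary, "ensemble_summary"))
  b <- summary$bpp
  n <- nrow(b)
  rows <- which(upper.tri(b, diag = TRUE), arr.ind = TRUE)
  keep <- b[rows] >= cutoff | rows[, 1] == rows[, 2]
  out <- data.frame(i = rows[keep, 1], j = rows[keep, 2],
                    p = signif(b[rows[keep, , drop = FALSE]], 6))
  out <- out[order(out$i, out$j), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d nt, ln Q = %.4f, dGens = %.4f kcal/mol, AUP = %.4f\n",
              nchar(x$sequence), x$logQ, x$efe, aup(x)))
  invisible(x)
}
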