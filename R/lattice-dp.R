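# Lattice-parsing front ends: joint sequence-structure Viterbi design,
# the expected partition function over a probabilistic lattice, its
# inside-outside gradient, and the beam-pruning error probe.

beam_width <- function(beam) {
  if (is.null(beam) || !is.finite(beam) || beam <= 0) 0L else as.integer(beam)
}

#' Jointly optimal (mRNA, structure) design by Viterbi lattice parsing
#'
#' Minimizes the structure free energy jointly over every mRNA in the
#' design space and every secondary structure of that mRNA -- the MFE
#' design objective -- by running the folding recursion over the codon
#' lattice instead of a single sequence. Exact with `beam = NULL`; a
#' positive beam width keeps, in every span cell, only the best few
#' state-pair items.
#'
#' @param lattice A [build_lattice()] object (or protein, which is built).
#' @param model An [energy_model()].
#' @param beam Beam width, or `NULL` for exact search.
#' @return List with `mrna`, `energy` (kcal/mol), `structure` (pair
#'   matrix) and `dot_bracket`.
#' @examples
#' design_mfe(build_lattice("DN"))
#' @export
design_mfe <- function(lattice, model = energy_model(), beam = NULL) {
  if (!inherits(lattice, "codon_lattice")) lattice <- build_lattice(lattice)
  res <- lattice_viterbi_cpp(lattice$length, lattice$nstates,
                             lattice_matrix(lattice), pair_matrix(model),
                             model$hairpin, beam_width(beam))
  mrna <- paste(NUCS[res$seq + 1L], collapse = "")
  list(mrna = mrna, energy = res$energy,
       structure = as_pair_matrix(res$pairs),
       dot_bracket = dot_bracket(res$pairs, lattice$length))
}

#' Log expected partition function of a probabilistic lattice
#'
#' `ln Qtilde(D) = ln E_{x ~ D}[Q(x)]`: the inside (sum) semiring run over
#' the probabilistic lattice, weighting every path by its edge
#' probabilities and every structure by its Boltzmann factor. For a
#' degenerate distribution this reduces to `ln Q(x)` of the single
#' sequence. `-RT * ln Qtilde` is the Jensen surrogate for the expected
#' ensemble free energy, a lower bound that is tight at one-hot
#' distributions.
#'
#' @param D A `prob_lattice`.
#' @param model An [energy_model()].
#' @param beam Beam width, or `NULL` for exact.
#' @return `ln Qtilde(D)` (natural log, scalar).
#' @export
expected_partition_function <- function(D, model = energy_model(),
                                        beam = NULL) {
  stopifnot(inherits(D, "prob_lattice"))
  lat <- D$lattice
  lattice_inside_cpp(lat$length, lat$nstates, lattice_matrix(lat),
                     log(D$tau), pair_matrix(model), model$hairpin,
                     model$RT, beam_width(beam))
}

#' Gradient of the expected partition function
#'
#' `d Qtilde / d tau(q, x)` for every edge parameter, obtained by the
#' outside pass of the inside-outside algorithm over the probabilistic
#' lattice. Qtilde is multilinear in the edge probabilities with
#' nonnegative coefficients, so every derivative is nonnegative; values
#' are returned as log magnitudes (`-Inf` for a parameter on no surviving
#' derivation) together with `ln Qtilde` in attribute `logQ`. The
#' derivative treats the parameters as free coordinates -- feasibility is
#' the projection step's job, not the gradient's.
#'
#' @param D A `prob_lattice`.
#' @param model An [energy_model()].
#' @param beam Beam width, or `NULL` for exact.
#' @return Data frame (class `gradient_table`) with `offset`, `state`,
#'   `nuc`, `log_magnitude`, `sign`; attribute `logQ`.
#' @export
epf_gradient <- function(D, model = energy_model(), beam = NULL) {
  stopifnot(inherits(D, "prob_lattice"))
  lat <- D$lattice
  res <- lattice_grad_cpp(lat$length, lat$nstates, lattice_matrix(lat),
                          log(D$tau), pair_matrix(model), model$hairpin,
                          model$RT, beam_width(beam))
  out <- data.frame(offset = lat$edges$offset, state = lat$edges$from,
                    nuc = lat$edges$nuc, log_magnitude = res$log_grad,
                    sign = ifelse(is.finite(res$log_grad), 1L, 0L))
  attr(out, "logQ") <- res$logQ
  class(out) <- c("gradient_table", class(out))
  out
}

#' Beam-pruning search-error probe
#'
#' Runs the expected-partition-function engine at each requested beam width
#' against the exact value and reports the relative error
#' `|Qtilde_b - Qtilde| / Qtilde`, paired with the distribution's mean node
#' entropy. Pruning ranks the state-pair items competing within each span
#' cell, so a one-hot distribution (one surviving state pair per cell) is
#' searched exactly at any width, while soft distributions spread mass over
#' parallel branches and lose some of it -- search error grows with
#' entropy.
#'
#' @param D A `prob_lattice`.
#' @param model An [energy_model()].
#' @param beams Integer vector of beam widths (`Inf` or `<= 0` = exact).
#' @return Data frame with `beam`, `log_epf`, `rel_error`, `mean_entropy`.
#' @export
beam_error_probe <- function(D, model = energy_model(), beams = c(1, 2, 5)) {
  stopifnot(inherits(D, "prob_lattice"))
  exact <- expected_partition_function(D, model, beam = NULL)
  ent <- mean_entropy(D)
  rows <- lapply(beams, function(b) {
    lb <- expected_partition_function(D, model, beam = b)
    rel <- abs(expm1(lb - exact)) # |Q_b - Q| / Q, safe in log space
    data.frame(beam = b, log_epf = lb, rel_error = rel, mean_entropy = ent)
  })
  do.call(rbind, rows)
}
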