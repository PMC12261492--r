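#' Euclidean projection onto the probability simplex
#'
#' Solves `argmin_w ||w - v||^2` subject to `w >= 0`, `sum(w) = 1` by the
#' standard sort-and-threshold algorithm. Idempotent; applied per lattice
#' node after every gradient step.
#'
#' @param v Numeric vector (finite).
#' @return Nonnegative vector of the same length summing to 1.
#' @examples
#' project_simplex(c(0.5, 0.7)) # c(0.4, 0.6)
#' @export
project_simplex <- function(v) {
  if (length(v) == 0L) stop("cannot project an empty vector")
  if (!all(is.finite(v))) stop("v must be finite")
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  k <- seq_along(u)
  rho <- max(k[u - (css - 1) / k > 0])
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Optimizer settings for [ensemble_design()]
#'
#' @param alpha Initial learning rate for the ascent on `ln Qtilde`
#'   (halved, per step, while the objective would decrease; up to 20
#'   halvings).
#' @param max_steps Iteration cap per run; the gradient ascent is
#'   routinely converged well within 30 steps.
#' @param tol Relative-change convergence threshold on `ln Qtilde`.
#' @param epsilon Soft-MFE mixing fraction in `[0, 1]`: 0 starts at the
#'   one-hot MFE design, 1 at a random distribution.
#' @param runs Independent restarts (seeded `seed`, `seed + 1`, ...).
#' @param candidates_per_run Sequences decoded and scored per run: the
#'   edge-wise argmax plus seeded samples from the final distribution.
#' @param beam Beam width for the lattice engines, `NULL` = exact.
#' @return List of validated settings, class `design_control`.
#' @export
design_control <- function(alpha = 0.5, max_steps = 30L, tol = 1e-6,
                           epsilon = 0.5, runs = 20L,
                           candidates_per_run = 10L, beam = NULL) {
  if (alpha <= 0) stop("alpha must be positive")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (max_steps < 1) stop("max_steps must be >= 1")
  if (runs < 1) stop("runs must be >= 1")
  if (candidates_per_run < 1) stop("candidates_per_run must be >= 1")
  if (tol < 0) stop("tol must be nonnegative")
  structure(list(alpha = alpha, max_steps = as.integer(max_steps), tol = tol,
                 epsilon = epsilon, runs = as.integer(runs),
                 candidates_per_run = as.integer(candidates_per_run),
                 beam = beam),
            class = "design_control")
}

# shared scorer: exact EFE/MFE of a decoded candidate
score_candidate <- function(x, model) {
  partition_function(x, model)$efe
}

new_mrna_design <- function(method, lattice, mrna, model, reference = NULL,
                            extra = list()) {
  pf <- partition_function(mrna, model)
  fold <- fold_mfe(mrna, model)
  cc <- if (is.null(reference)) NA_real_ else codon_change_fraction(mrna, reference)
  structure(c(list(method = method, protein = lattice$protein,
                   mrna = mrna, efe = pf$efe, mfe = fold$energy,
                   reference = reference, codon_change = cc,
                   summary_pf = pf),
              extra),
            class = "mrna_design")
}

#' MFE design baseline
#'
#' The classical objective: the mRNA (and structure) minimizing the folding
#' free energy jointly over the design space, by Viterbi lattice parsing.
#'
#' @param protein Protein sequence or a [build_lattice()] object.
#' @param model An [energy_model()].
#' @param beam Beam width, `NULL` = exact.
#' @return An `mrna_design` object (fields `mrna`, `mfe`, `efe`,
#'   `structure`, ...).
#' @export
mfe_design <- function(protein, model = energy_model(), beam = NULL) {
  lattice <- if (inherits(protein, "codon_lattice")) protein
             else build_lattice(protein)
  res <- design_mfe(lattice, model, beam)
  new_mrna_design("mfe", lattice, res$mrna, model,
                  extra = list(structure = res$structure,
                               dot_bracket = res$dot_bracket,
                               design_energy = res$energy))
}

#' Random-walk baseline over synonymous codons
#'
#' Starting from `start` (by default the MFE design), proposes `steps`
#' single-codon changes: a uniformly random residue position, a uniformly
#' random codon from its synonym set (possibly the current one). A proposal
#' replaces the current best sequence iff its ensemble free energy is
#' strictly lower. Deterministic given `seed`.
#'
#' @param protein Protein sequence or a [build_lattice()] object.
#' @param model An [energy_model()].
#' @param start Starting mRNA (accepted by the lattice), or `NULL` for the
#'   MFE design.
#' @param steps Number of proposals.
#' @param seed Integer seed.
#' @return An `mrna_design` object; `codon_change` is measured against
#'   `start`.
#' @export
random_walk_design <- function(protein, model = energy_model(), start = NULL,
                               steps = 100L, seed = 1L) {
  lattice <- if (inherits(protein, "codon_lattice")) protein
             else build_lattice(protein)
  if (is.null(start)) start <- design_mfe(lattice, model)$mrna
  if (!accepts(lattice, start)) stop("start sequence is not in the design space")
  tab <- codon_table()
  n <- lattice$n_codons
  best <- start
  best_efe <- score_candidate(start, model)
  accepted <- data.frame(step = 0L, efe = best_efe)
  with_local_seed(seed, {
    for (s in seq_len(steps)) {
      i <- sample.int(n, 1L)
      codons <- tab[[lattice$residues[i]]]
      cod <- codons[sample.int(length(codons), 1L)]
      cand <- paste0(substr(best, 1L, 3L * (i - 1L)), cod,
                     substr(best, 3L * i + 1L, nchar(best)))
      if (cand == best) next
      efe <- score_candidate(cand, model)
      if (efe < best_efe) {
        best <- cand
        best_efe <- efe
        accepted <- rbind(accepted, data.frame(step = s, efe = efe))
      }
    }
  })
  new_mrna_design("random_walk", lattice, best, model, reference = start,
                  extra = list(steps = as.integer(steps), seed = seed,
                               accepted = accepted))
}

#' Ensemble free energy mRNA design by projected gradient ascent
#'
#' The main fitter. The synonymous design space of `protein` is relaxed to
#' a product distribution on its codon lattice; the expected partition
#' function `Qtilde(D)` is maximized by projected gradient ascent (the
#' ascent uses the gradient of `ln Qtilde`, which rescales the direction
#' without moving the fixed points), with per-node Euclidean projection
#' onto the probability simplex after every step. Each of `control$runs`
#' restarts starts from a soft-MFE initialization and is decoded into
#' `control$candidates_per_run` integral sequences (edge-wise argmax plus
#' seeded samples); every candidate is scored by its exact ensemble free
#' energy, and the best candidate over all runs is returned.
#'
#' @param protein Protein sequence or a [build_lattice()] object.
#' @param model An [energy_model()].
#' @param control A [design_control()].
#' @param seed Base integer seed; run r uses `seed + r - 1`.
#' @return An object of classes `ensemble_design` and `mrna_design`:
#'   the designed `mrna` with `efe`, `mfe`, `codon_change` (vs the MFE
#'   design), per-run optimization traces, and the winning run's final
#'   distribution. Methods: [print()], [summary()], [coef()] (final tau),
#'   [plot()] (trace), [simulate()] (sample designs).
#' @examples
#' fit <- ensemble_design("DN", control = design_control(runs = 2))
#' fit$efe
#' @export
ensemble_design <- function(protein, model = energy_model(),
                            control = design_control(), seed = 1L) {
  stopifnot(inherits(control, "design_control"))
  lattice <- if (inherits(protein, "codon_lattice")) protein
             else build_lattice(protein)
  mfe_ref <- design_mfe(lattice, model, control$beam)
  grp <- node_groups(lattice)
  runs <- vector("list", control$runs)
  for (r in seq_len(control$runs)) {
    run_seed <- as.integer(seed + r - 1L)
    runs[[r]] <- tryCatch(
      run_pga(lattice, model, control, mfe_ref$mrna, run_seed, grp),
      error = function(e) {
        warning(sprintf("run %d (seed %d) aborted: %s", r, run_seed,
                        conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all optimization runs failed")
  efes <- vapply(runs[ok], function(z) z$best_efe, numeric(1))
  best_run <- which(ok)[which.min(efes)]
  best <- runs[[best_run]]
  out <- new_mrna_design("ensemble", lattice, best$best_mrna, model,
                         reference = mfe_ref$mrna,
                         extra = list(mfe_reference = mfe_ref,
                                      runs = runs, best_run = best_run,
                                      control = control, seed = seed,
                                      model = model, lattice = lattice))
  class(out) <- c("ensemble_design", class(out))
  out
}

# one projected-gradient-ascent run; returns trace, final tau, candidates
run_pga <- function(lattice, model, control, x_mfe, run_seed, grp) {
  D <- soft_mfe_init(lattice, x_mfe, control$epsilon, seed = run_seed)
  tau <- D$tau
  logq <- expected_partition_function(D, model, control$beam)
  if (!is.finite(logq)) stop("non-finite objective at initialization")
  trace <- data.frame(iter = 0L, log_epf = logq,
                      mean_entropy = mean_entropy(D),
                      alpha = NA_real_, proj_residual = NA_real_)
  for (t in seq_len(control$max_steps)) {
    g <- lattice_grad_cpp(lattice$length, lattice$nstates,
                          lattice_matrix(lattice), log(tau),
                          pair_matrix(model), model$hairpin, model$RT,
                          beam_width(control$beam))
    if (!is.finite(g$logQ)) stop("non-finite objective during optimization")
    dir <- exp(g$log_grad - g$logQ) # gradient of ln Qtilde
    dir[!is.finite(dir)] <- 0
    alpha <- control$alpha
    accepted <- FALSE
    for (halving in 0:20) {
      cand <- tau + alpha * dir
      resid2 <- 0
      for (ix in grp) {
        p <- project_simplex(cand[ix])
        resid2 <- resid2 + sum((cand[ix] - p)^2)
        cand[ix] <- p
      }
      logq_new <- lattice_inside_cpp(lattice$length, lattice$nstates,
                                     lattice_matrix(lattice), log(cand),
                                     pair_matrix(model), model$hairpin,
                                     model$RT, beam_width(control$beam))
      if (is.finite(logq_new) && logq_new >= logq) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break # no improving step along the gradient: converged
    delta <- abs(logq_new - logq) / max(abs(logq), 1)
    tau <- cand
    logq <- logq_new
    trace <- rbind(trace,
                   data.frame(iter = t, log_epf = logq,
                              mean_entropy = mean_entropy(
                                structure(list(lattice = lattice, tau = tau),
                                          class = "prob_lattice")),
                              alpha = alpha, proj_residual = sqrt(resid2)))
    if (delta < control$tol) break
  }
  Dfin <- new_prob_lattice(lattice, tau)
  cands <- argmax_decode(Dfin)
  if (control$candidates_per_run > 1L) {
    extra <- with_local_seed(run_seed + 500000L, {
      vapply(seq_len(control$candidates_per_run - 1L),
             function(k) sample_sequence(Dfin), character(1))
    })
    cands <- unique(c(cands, extra))
  }
  efes <- vapply(cands, score_candidate, numeric(1), model = model)
  k <- which.min(efes)
  list(seed = run_seed, trace = trace, tau = tau,
       candidates = data.frame(mrna = cands, efe = as.numeric(efes),
                               row.names = NULL),
       best_mrna = cands[k], best_efe = efes[[k]])
}

#' Fraction of codons changed between two synonymous mRNAs
#'
#' @param x,reference mRNA sequences of equal length encoding the same
#'   protein.
#' @return Fraction in `[0, 1]`.
#' @export
codon_change_fraction <- function(x, reference) {
  x <- rna_string(x); reference <- rna_string(reference)
  if (nchar(x) != nchar(reference)) stop("sequences differ in length")
  if (translate_mrna(x) != translate_mrna(reference))
    stop("sequences encode different proteins")
  n <- nchar(x) / 3L
  starts <- 3L * seq_len(n) - 2L
  cx <- substring(x, starts, starts + 2L)
  cr <- substring(reference, starts, starts + 2L)
  mean(cx != cr)
}

#' Write per-run optimization traces as JSON lines
#'
#' One JSON object per line: run, seed, iteration, `ln Qtilde`, mean node
#' entropy, step size used and projection residual -- a log that survives
#' the R session and diffs cleanly.
#'
#' @param fit An [ensemble_design()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_jsonl <- function(fit, path) {
  stopifnot(inherits(fit, "ensemble_design"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_trace_jsonl requires the jsonlite package")
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_along(fit$runs)) {
    z <- fit$runs[[r]]
    if (is.null(z)) next
    for (k in seq_len(nrow(z$trace))) {
      rec <- c(list(run = r, seed = z$seed), as.list(z$trace[k, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                  digits = 10), con)
    }
  }
  invisible(path)
}

#' @export
print.mrna_design <- function(x, ...) {
  cat(sprintf("<mrna_design:%s> protein %d aa / %d nt\n",
              x$method, nchar(x$protein), nchar(x$mrna)))
  cat("  mRNA:", x$mrna, "\n")
  cat(sprintf("  MFE = %.4f kcal/mol, EFE = %.4f kcal/mol", x$mfe, x$efe))
  if (!is.na(x$codon_change))
    cat(sprintf(", codon change = %.1f%%", 100 * x$codon_change))
  cat("\n")
  invisible(x)
}

#' @export
summary.ensemble_design <- function(object, ...) {
  runs <- object$runs
  tab <- do.call(rbind, lapply(seq_along(runs), function(r) {
    z <- runs[[r]]
    if (is.null(z)) return(data.frame(run = r, seed = NA_integer_,
                                      iterations = NA_integer_,
                                      log_epf = NA_real_, efe = NA_real_))
    data.frame(run = r, seed = z$seed, iterations = max(z$trace$iter),
               log_epf = z$trace$log_epf[nrow(z$trace)], efe = z$best_efe)
  }))
  structure(list(design = object, runs = tab), class = "summary.ensemble_design")
}

#' @export
print.summary.ensemble_design <- function(x, ...) {
  print(x$design)
  cat(sprintf("  best run: %d of %d\n", x$design$best_run, nrow(x$runs)))
  print(x$runs, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ensemble_design <- function(object, ...) {
  lat <- object$lattice
  data.frame(offset = lat$edges$offset, state = lat$edges$from,
             nuc = lat$edges$nuc, tau = object$runs[[object$best_run]]$tau)
}

#' @export
plot.ensemble_design <- function(x, which = c("objective", "entropy"), ...) {
  which <- match.arg(which)
  runs <- Filter(Negate(is.null), x$runs)
  col <- if (which == "objective") "log_epf" else "mean_entropy"
  ylab <- if (which == "objective") expression(ln ~ tilde(Q)) else
    "mean node entropy (bits)"
  niter <- max(vapply(runs, function(z) max(z$trace$iter), numeric(1)))
  ys <- vapply(runs, function(z) {
    v <- z$trace[[col]]
    c(v, rep(v[length(v)], niter + 1 - length(v)))
  }, numeric(niter + 1))
  matplot(0:niter, ys, type = "l", lty = 1, xlab = "iteration", ylab = ylab,
          ...)
  invisible(x)
}

#' @export
simulate.ensemble_design <- function(object, nsim = 1, seed = NULL, ...) {
  D <- new_prob_lattice(object$lattice, object$runs[[object$best_run]]$tau)
  with_local_seed(seed, {
    vapply(seq_len(nsim), function(k) sample_sequence(D), character(1))
  })
}
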