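# Benchmark workbench: synthetic protein panels and side-by-side method
# comparisons (MFE design vs random walk vs ensemble design), reported the
# way design studies tabulate them: per-protein ddG, ddGens, codon change,
# AUP and mean positional entropy relative to the MFE solution.

#' Generate a reproducible panel of random proteins
#'
#' Residues are drawn uniformly from the 20 standard amino acids; lengths
#' are uniform on `length_range`. Deterministic given `seed` -- the panel
#' stands in for a set of natural proteins in desk-scale benchmarks.
#'
#' @param n_proteins Number of proteins.
#' @param length_range `c(min, max)` amino-acid lengths, `min >= 1`.
#' @param seed Integer seed.
#' @return Data frame with `id`, `length`, `protein`.
#' @export
generate_fixture_panel <- function(n_proteins, length_range = c(50L, 350L),
                                   seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  lo <- length_range[1]; hi <- length_range[2]
  if (lo < 1 || hi < lo) stop("length_range must satisfy 1 <= min <= max")
  aas <- setdiff(names(codon_table()), "*")
  with_local_seed(seed, {
    lens <- lo + sample.int(hi - lo + 1L, n_proteins, replace = TRUE) - 1L
    prot <- vapply(lens, function(L)
      paste(sample(aas, L, replace = TRUE), collapse = ""), character(1))
    data.frame(id = sprintf("SYN%03d", seq_len(n_proteins)),
               length = as.integer(lens), protein = prot)
  })
}

#' Compare design methods across a protein panel
#'
#' For each protein: the MFE design (Viterbi lattice parsing), a random
#' walk started from it, and the ensemble design. Energy columns follow the
#' usual reporting convention: absolute `dG` (MFE) and `dGens` (EFE) for
#' the MFE solution, and per-method differences `ddG`, `ddGens` (negative =
#' better than the MFE solution) plus the percentage of changed codons,
#' AUP, and mean positional entropy. Failures on individual proteins are
#' warned about and skipped.
#'
#' @param panel Data frame with columns `id` and `protein`
#'   (see [generate_fixture_panel()]).
#' @param model An [energy_model()].
#' @param control A [design_control()] for the ensemble designs.
#' @param rw_steps Random-walk proposals per protein.
#' @param seed Base seed; protein i derives its own method seeds from it.
#' @return Data frame, one row per protein.
#' @export
run_comparison <- function(panel, model = energy_model(),
                           control = design_control(), rw_steps = 100L,
                           seed = 1L) {
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    tryCatch({
      lat <- build_lattice(panel$protein[i])
      mfe <- mfe_design(lat, model, beam = control$beam)
      rw <- random_walk_design(lat, model, start = mfe$mrna,
                               steps = rw_steps, seed = seed + 7000L + i)
      ed <- ensemble_design(lat, model, control,
                            seed = seed + 10000L * i)
      metrics <- function(d) {
        pf <- d$summary_pf
        c(ddG = d$mfe - mfe$mfe, ddGens = d$efe - mfe$efe,
          dcodon_pct = 100 * codon_change_fraction(d$mrna, mfe$mrna),
          aup = aup(pf), entropy = mean(positional_entropy(pf)))
      }
      pfm <- mfe$summary_pf
      base <- data.frame(id = panel$id[i], aa = lat$n_codons,
                         nt = lat$length, dG_mfe = mfe$mfe,
                         dGens_mfe = mfe$efe, aup_mfe = aup(pfm),
                         entropy_mfe = mean(positional_entropy(pfm)))
      mrw <- metrics(rw); med <- metrics(ed)
      for (nm in names(mrw)) {
        base[[paste0("rw_", nm)]] <- mrw[[nm]]
        base[[paste0("ed_", nm)]] <- med[[nm]]
      }
      base$rw_mrna <- rw$mrna
      base$ed_mrna <- ed$mrna
      base$mfe_mrna <- mfe$mrna
      base
    }, error = function(e) {
      warning(sprintf("protein %s skipped: %s", panel$id[i],
                      conditionMessage(e)))
      NULL
    })
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Write a comparison report as TSV
#'
#' @param report A [run_comparison()] data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  num <- vapply(report, is.numeric, logical(1))
  report[num] <- lapply(report[num], signif, digits = 6)
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' values that parse as numbers become numeric. Used by the command-line
#' interface to override energy-model and optimizer settings.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
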