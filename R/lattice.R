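#' Build the codon lattice (DFA) of all mRNAs encoding a protein
#'
#' The design space of a protein -- every mRNA that translates to it --
#' grows exponentially with length, but is represented exactly and compactly
#' by a layered deterministic finite automaton, the *codon lattice*. Offsets
#' run 0..3n (nucleotide position k is the edge from offset k-1 to k);
#' each codon block spans three offsets and accepts exactly the synonymous
#' codons of its residue. Six-codon amino acids (Leu, Ser, Arg) and the stop
#' block produce two prefix branches that re-merge at the block boundary.
#' Branch indices are assigned by sorted codon prefixes (`A < C < G < U`),
#' so the construction is byte-for-byte reproducible.
#'
#' A trailing `*` in the protein appends one stop-codon block; otherwise stop
#' codons are excluded.
#'
#' @param protein Protein sequence (string or character vector); see
#'   [validate_protein()].
#' @param table Codon table, see [codon_table()].
#' @return An object of class `codon_lattice`: a list with `protein`,
#'   `residues`, `n_codons`, `length` (= 3 * n_codons), `nstates` (states
#'   per offset), `edges` (data frame: `offset`, `from`, `nuc`, `to`) and
#'   `multiplicities` (codon-set size per residue).
#' @examples
#' lat <- build_lattice("MS")
#' count_sequences(lat) # 6 (Met x Ser)
#' @export
build_lattice <- function(protein, table = codon_table()) {
  res <- validate_protein(protein, table)
  n <- length(res)
  nstates <- integer(3L * n + 1L)
  nstates[1L] <- 1L
  off <- integer(0); from <- integer(0); nuc <- character(0); to <- integer(0)
  mult <- integer(n)
  for (i in seq_len(n)) {
    codons <- table[[res[i]]]
    mult[i] <- length(codons)
    o <- 3L * (i - 1L)
    p1 <- unique(substr(codons, 1L, 1L)) # sorted: codons are sorted
    p2 <- unique(substr(codons, 1L, 2L))
    nstates[o + 2L] <- length(p1)
    nstates[o + 3L] <- length(p2)
    nstates[o + 4L] <- 1L
    # offset o -> o+1
    off <- c(off, rep(o, length(p1)))
    from <- c(from, rep(0L, length(p1)))
    nuc <- c(nuc, p1)
    to <- c(to, seq_along(p1) - 1L)
    # offset o+1 -> o+2
    off <- c(off, rep(o + 1L, length(p2)))
    from <- c(from, match(substr(p2, 1L, 1L), p1) - 1L)
    nuc <- c(nuc, substr(p2, 2L, 2L))
    to <- c(to, seq_along(p2) - 1L)
    # offset o+2 -> o+3 (merge into the block-final state)
    off <- c(off, rep(o + 2L, length(codons)))
    from <- c(from, match(substr(codons, 1L, 2L), p2) - 1L)
    nuc <- c(nuc, substr(codons, 3L, 3L))
    to <- c(to, rep(0L, length(codons)))
  }
  edges <- data.frame(offset = off, from = from, nuc = nuc, to = to,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$offset, edges$from, match(edges$nuc, NUCS)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(protein = paste(res, collapse = ""), residues = res,
                 n_codons = n, length = 3L * n, nstates = nstates,
                 edges = edges, multiplicities = mult),
            class = "codon_lattice")
}

#' Count the mRNA sequences accepted by a codon lattice
#'
#' The number of accepting paths equals the product over residues of their
#' codon-set sizes; it is returned exactly (arbitrary precision) together
#' with its base-10 logarithm, since realistic design spaces exceed
#' `10^600`.
#'
#' @param lattice A [build_lattice()] object.
#' @return A [big_product()] `bigcount`.
#' @export
count_sequences <- function(lattice) {
  stopifnot(inherits(lattice, "codon_lattice"))
  big_product(lattice$multiplicities)
}

#' Enumerate all mRNA sequences of a (small) design space
#'
#' Yields every accepting path's label string exactly once, in lexicographic
#' order (`A < C < G < U`). Refuses design spaces larger than `limit` --
#' enumeration is an oracle for small instances, not a scalable operation.
#'
#' @param lattice A [build_lattice()] object.
#' @param limit Maximum number of sequences allowed.
#' @return Character vector of mRNA sequences.
#' @export
enumerate_sequences <- function(lattice, limit = 10000L) {
  stopifnot(inherits(lattice, "codon_lattice"))
  cnt <- count_sequences(lattice)
  if (cnt$log10 > 15 || as.double(as.character(cnt)) > limit)
    stop(sprintf("design space (about 10^%.1f sequences) exceeds limit %d",
                 cnt$log10, limit))
  tab <- codon_table()
  seqs <- ""
  for (res in lattice$residues) {
    codons <- tab[[res]]
    seqs <- paste0(rep(seqs, each = length(codons)), codons)
  }
  seqs
}

# integer-encoded edge table for the C++ engines: (offset, from, nuc0..3, to)
lattice_matrix <- function(lattice) {
  e <- lattice$edges
  cbind(e$offset, e$from, match(e$nuc, NUCS) - 1L, e$to)
}

# edge ids along the accepting path of x, or the first mismatching position
walk_path <- function(lattice, x) {
  x <- rna_string(x)
  if (nchar(x) != lattice$length)
    stop(sprintf("sequence length %d does not match lattice length %d",
                 nchar(x), lattice$length))
  e <- lattice$edges
  key <- paste(e$offset, e$from, e$nuc)
  lookup <- stats::setNames(seq_len(nrow(e)), key)
  chars <- strsplit(x, "")[[1]]
  path <- integer(lattice$length)
  state <- 0L
  for (k in seq_len(lattice$length)) {
    id <- lookup[paste(k - 1L, state, chars[k])]
    if (is.na(id)) return(list(ok = FALSE, position = k))
    path[k] <- id
    state <- e$to[id]
  }
  list(ok = TRUE, path = path)
}

#' Does a lattice accept an mRNA sequence?
#'
#' @param lattice A [build_lattice()] object.
#' @param x mRNA sequence.
#' @return `TRUE`/`FALSE`.
#' @export
accepts <- function(lattice, x) {
  walk_path(lattice, x)$ok
}

#' Serialize a lattice to a TSV edge list
#'
#' One row per transition, states written as `offset:branch`.
#'
#' @param lattice A [build_lattice()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_lattice_tsv <- function(lattice, path) {
  e <- lattice$edges
  out <- data.frame(state = paste0(e$offset, ":", e$from),
                    nucleotide = e$nuc,
                    next_state = paste0(e$offset + 1L, ":", e$to))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein records from a FASTA file
#'
#' @param path FASTA file with one or more protein records.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' @export
print.codon_lattice <- function(x, ...) {
  cnt <- count_sequences(x)
  cat(sprintf("<codon_lattice> %d residues, %d nt, %d states, %d edges\n",
              x$n_codons, x$length, sum(x$nstates), nrow(x$edges)))
  cat(sprintf("  design space: %.4f x 10^%d sequences\n",
              10^(cnt$log10 - floor(cnt$log10)), as.integer(floor(cnt$log10))))
  invisible(x)
}
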