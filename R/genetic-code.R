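#' The standard genetic code as an amino-acid to codon-set table
#'
#' Inverts the standard genetic code (from [Biostrings::GENETIC_CODE]) into a
#' mapping from one-letter amino-acid codes to their synonymous codon sets,
#' written in the RNA alphabet (`A`, `C`, `G`, `U`). The stop "residue" `*`
#' maps to the three stop codons. Codon sets are sorted in the fixed
#' nucleotide order `A < C < G < U`, which makes every downstream
#' construction (lattice states, enumeration order, tie-breaks) reproducible.
#'
#' @return A named list: for each amino-acid code (and `*`), a sorted
#'   character vector of RNA codons. Set sizes are 1, 2, 3, 4 or 6.
#' @examples
#' codon_table()[["M"]] # "AUG"
#' codon_table()[["L"]] # six codons
#' @export
codon_table <- function() {
  if (is.null(.efed_cache$codon_table)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- chartr("T", "U", names(gc))
    tab <- split(codons, unname(gc))
    tab <- lapply(tab, sort)
    .efed_cache$codon_table <- tab
  }
  .efed_cache$codon_table
}

.efed_cache <- new.env(parent = emptyenv())

# reverse map codon -> amino acid (RNA alphabet)
codon_to_aa <- function(table = codon_table()) {
  if (is.null(.efed_cache$codon_to_aa)) {
    aa <- rep(names(table), lengths(table))
    .efed_cache$codon_to_aa <- stats::setNames(aa, unlist(table))
  }
  .efed_cache$codon_to_aa
}

#' Validate a protein sequence for mRNA design
#'
#' Accepts a single string (or character vector of single letters) over the
#' 20 standard amino-acid codes, with an optional single trailing `*`
#' denoting a stop codon to be appended to the design. Lowercase input is
#' accepted; an unknown residue is rejected with its position.
#'
#' @param protein Character scalar (e.g. `"MKV"`) or vector of one-letter
#'   codes.
#' @param table Codon table, see [codon_table()].
#' @return A character vector of residues (including a trailing `"*"` when
#'   present), with attribute `has_stop`.
#' @export
validate_protein <- function(protein, table = codon_table()) {
  if (length(protein) == 1L && nchar(protein) > 1L)
    protein <- strsplit(protein, "")[[1]]
  res <- toupper(as.character(protein))
  if (length(res) < 1L) stop("protein must contain at least one residue")
  valid <- setdiff(names(table), "*")
  stops <- which(res == "*")
  if (length(stops) > 1L || (length(stops) == 1L && stops != length(res)))
    stop("'*' is only allowed as the final residue")
  body <- res[res != "*"]
  if (length(body) < 1L) stop("protein must contain at least one residue")
  bad <- which(!(body %in% valid))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", body[bad[1]], bad[1]))
  structure(res, has_stop = length(stops) == 1L)
}

#' Translate an mRNA back to its protein
#'
#' In-frame translation under the standard genetic code; the RNA and DNA
#' alphabets are both accepted (`T` is read as `U`). A trailing stop codon
#' is rendered as `*`.
#'
#' @param x mRNA sequence (character scalar), length a multiple of 3.
#' @param table Codon table.
#' @return Character scalar of one-letter residues.
#' @export
translate_mrna <- function(x, table = codon_table()) {
  x <- rna_string(x)
  if (nchar(x) %% 3L != 0L) stop("mRNA length must be a multiple of 3")
  cods <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  aa <- codon_to_aa(table)[cods]
  if (anyNA(aa)) stop("invalid codon: ", cods[which(is.na(aa))[1]])
  paste(aa, collapse = "")
}

# normalize to the RNA alphabet, uppercase; reject anything else
rna_string <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", toupper(as.character(x))))
  if (length(x) != 1L) stop("expected a single sequence string")
  chars <- strsplit(x, "")[[1]]
  bad <- which(!(chars %in% NUCS))
  if (length(bad))
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[1]], bad[1]))
  x
}
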