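# Brute-force oracles and random-instance generators. Everything here is
# independent of the dynamic-programming engines it checks: energies come
# from structure_energy over exhaustive enumeration, counts from a direct
# recursion, sequences from the codon table.

AA20 <- setdiff(names(codon_table()), "*")

# canonical pair-matrix form, for comparing structures
as_pm <- function(p) efedesign:::as_pair_matrix(p)

rand_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                    collapse = "")

rand_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                       replace = TRUE), collapse = "")

# random interior-point distribution on a lattice (flat Dirichlet per node)
rand_tau <- function(lattice, seed) soft_mfe_init(
  lattice, design_mfe(lattice)$mrna, epsilon = 1, seed = seed)

# independent recursive count of valid structures (never builds them)
count_structures_rec <- function(x, model) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  h <- model$hairpin
  ok <- names(model$pair_scores)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 1) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- rec(i, j - 1)
    k <- i
    while (k <= j - h - 1) {
      if (paste0(chars[k], chars[j]) %in% ok)
        total <- total + rec(i, k - 1) * rec(k + 1, j - 1)
      k <- k + 1
    }
    memo[[key]] <- total
    total
  }
  rec(1L, n)
}

# partition function by exhaustive enumeration
brute_Q <- function(x, model) {
  structs <- enumerate_structures(x, model)
  sum(vapply(structs, function(s)
    exp(-structure_energy(x, s, model) / model$RT), numeric(1)))
}

# pair/unpaired probability matrix by exhaustive enumeration
brute_bpp <- function(x, model) {
  n <- nchar(x)
  structs <- enumerate_structures(x, model)
  w <- vapply(structs, function(s)
    exp(-structure_energy(x, s, model) / model$RT), numeric(1))
  Q <- sum(w)
  b <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    s <- structs[[k]]
    paired <- rep(FALSE, n)
    if (nrow(s)) {
      for (r in seq_len(nrow(s))) {
        b[s[r, 1], s[r, 2]] <- b[s[r, 1], s[r, 2]] + w[k]
        b[s[r, 2], s[r, 1]] <- b[s[r, 2], s[r, 1]] + w[k]
        paired[s[r, ]] <- TRUE
      }
    }
    for (i in which(!paired)) b[i, i] <- b[i, i] + w[k]
  }
  b / Q
}

# minimum structure energy by exhaustive enumeration
brute_mfe <- function(x, model) {
  structs <- enumerate_structures(x, model)
  es <- vapply(structs, structure_energy, numeric(1), x = x, model = model)
  list(energy = min(es),
       min_pairs = min(vapply(structs[es <= min(es) + 1e-9], nrow,
                              integer(1))))
}

# expected partition function by full design-space enumeration
brute_epf <- function(D, model) {
  seqs <- enumerate_sequences(D$lattice, limit = 5000)
  sum(vapply(seqs, function(x)
    sequence_probability(D, x) * exp(partition_function(x, model)$logQ),
    numeric(1)))
}
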