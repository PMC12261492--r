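# The probabilistic lattice: per-node edge probabilities tau on the codon
# DFA, inducing a product distribution D(x) = prod_i tau(q_i, x_i) over the
# design space. tau is stored as a vector aligned with lattice$edges; the
# rows sharing (offset, from) form one node's distribution.

new_prob_lattice <- function(lattice, tau) {
  stopifnot(inherits(lattice, "codon_lattice"),
            length(tau) == nrow(lattice$edges))
  if (any(tau < -1e-12)) stop("tau must be nonnegative")
  tau <- pmax(tau, 0)
  sums <- tapply(tau, node_of(lattice), sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("tau must sum to 1 over each node's outgoing edges")
  structure(list(lattice = lattice, tau = as.numeric(tau)),
            class = "prob_lattice")
}

# node key (offset, from-state) per edge row, in edge order
node_of <- function(lattice) {
  e <- lattice$edges
  factor(paste(e$offset, e$from), levels = unique(paste(e$offset, e$from)))
}

# list of edge-row indices per node
node_groups <- function(lattice) {
  split(seq_len(nrow(lattice$edges)), node_of(lattice))
}

#' Uniform distribution over a codon lattice
#'
#' Every node's outgoing edges get equal probability. Note this is uniform
#' per *branch decision*, not uniform over sequences: codons reached through
#' a two-way branch carry half the mass of their siblings.
#'
#' @param lattice A [build_lattice()] object.
#' @return A `prob_lattice`.
#' @export
prob_uniform <- function(lattice) {
  grp <- node_groups(lattice)
  tau <- numeric(nrow(lattice$edges))
  for (ix in grp) tau[ix] <- 1 / length(ix)
  new_prob_lattice(lattice, tau)
}

#' Degenerate (one-hot) distribution at a given mRNA
#'
#' All probability mass on the accepting path of `x`, so `D(x) = 1`. Nodes
#' off the path keep a fixed valid (uniform) distribution.
#'
#' @param lattice A [build_lattice()] object.
#' @param x An mRNA accepted by the lattice.
#' @return A `prob_lattice`.
#' @export
prob_degenerate <- function(lattice, x) {
  w <- walk_path(lattice, x)
  if (!w$ok)
    stop(sprintf("sequence is not accepted by the lattice (position %d)",
                 w$position))
  grp <- node_groups(lattice)
  tau <- numeric(nrow(lattice$edges))
  for (ix in grp) tau[ix] <- 1 / length(ix)
  onpath <- node_of(lattice)[w$path]
  for (k in seq_along(w$path)) {
    ix <- grp[[as.character(onpath[k])]]
    tau[ix] <- 0
    tau[w$path[k]] <- 1
  }
  new_prob_lattice(lattice, tau)
}

#' Probability of a sequence under a probabilistic lattice
#'
#' `D(x)`: the product of edge probabilities along the accepting path of
#' `x`.
#'
#' @param D A `prob_lattice`.
#' @param x An mRNA accepted by the underlying lattice.
#' @return Numeric in `[0, 1]`.
#' @export
sequence_probability <- function(D, x) {
  stopifnot(inherits(D, "prob_lattice"))
  w <- walk_path(D$lattice, x)
  if (!w$ok)
    stop(sprintf("sequence is not accepted by the lattice (position %d)",
                 w$position))
  prod(D$tau[w$path])
}

#' Sample an mRNA sequence from a probabilistic lattice
#'
#' Draws a path edge by edge according to tau; reproducible given `seed`
#' (with `seed = NULL` the current RNG stream is used and advanced).
#'
#' @param D A `prob_lattice`.
#' @param seed Integer seed or `NULL`.
#' @return mRNA sequence (character scalar).
#' @export
sample_sequence <- function(D, seed = NULL) {
  stopifnot(inherits(D, "prob_lattice"))
  with_local_seed(seed, {
    e <- D$lattice$edges
    L <- D$lattice$length
    grp <- node_groups(D$lattice)
    out <- character(L)
    state <- 0L
    for (k in seq_len(L)) {
      ix <- grp[[paste(k - 1L, state)]]
      pick <- if (length(ix) == 1L) ix else {
        ix[sample.int(length(ix), 1L, prob = D$tau[ix])]
      }
      out[k] <- e$nuc[pick]
      state <- e$to[pick]
    }
    paste(out, collapse = "")
  })
}

#' Most-probable-edge decode of a probabilistic lattice
#'
#' Follows the highest-probability edge at every node along the induced
#' path (ties broken in nucleotide order `A < C < G < U`). This greedy
#' edge-wise decode is the integral extraction used after optimization; by
#' convergence the distribution is nearly one-hot, where it coincides with
#' the mode.
#'
#' @param D A `prob_lattice`.
#' @return mRNA sequence (character scalar).
#' @export
argmax_decode <- function(D) {
  stopifnot(inherits(D, "prob_lattice"))
  e <- D$lattice$edges
  L <- D$lattice$length
  grp <- node_groups(D$lattice)
  out <- character(L)
  state <- 0L
  for (k in seq_len(L)) {
    ix <- grp[[paste(k - 1L, state)]]
    pick <- ix[which.max(D$tau[ix])] # edges sorted A<C<G<U within node
    out[k] <- e$nuc[pick]
    state <- e$to[pick]
  }
  paste(out, collapse = "")
}

#' Soft-MFE initialization of the optimizer's distribution
#'
#' Blends, node by node, a seeded random distribution (flat Dirichlet per
#' node) with the degenerate distribution at the MFE design:
#' `tau = epsilon * tau_rand + (1 - epsilon) * tau_mfe`. `epsilon = 0`
#' reproduces the one-hot MFE start; `epsilon = 1` is a fully random start.
#' Mixing at the tau (node) level keeps the result inside the product
#' family representable by the lattice.
#'
#' @param lattice A [build_lattice()] object.
#' @param x_mfe The MFE design sequence (accepted by `lattice`).
#' @param epsilon Mixing fraction in `[0, 1]`.
#' @param seed Integer seed for the random component.
#' @return A `prob_lattice`.
#' @export
soft_mfe_init <- function(lattice, x_mfe, epsilon = 0.5, seed = 1L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      is.na(epsilon) || epsilon < 0 || epsilon > 1)
    stop("epsilon must be a single number in [0, 1]")
  mfe <- prob_degenerate(lattice, x_mfe)
  grp <- node_groups(lattice)
  tau_rand <- numeric(nrow(lattice$edges))
  with_local_seed(seed, {
    for (ix in grp) {
      g <- rgamma(length(ix), shape = 1)
      tau_rand[ix] <- g / sum(g)
    }
  })
  new_prob_lattice(lattice, epsilon * tau_rand + (1 - epsilon) * mfe$tau)
}

#' Per-node entropy of a probabilistic lattice
#'
#' `-sum_x tau(q, x) log2 tau(q, x)` in bits for every non-final state,
#' with `0 log 0 := 0`.
#'
#' @param D A `prob_lattice`.
#' @return Data frame with `offset`, `state`, `entropy` (bits).
#' @export
node_entropy <- function(D) {
  stopifnot(inherits(D, "prob_lattice"))
  grp <- node_groups(D$lattice)
  e <- D$lattice$edges
  ent <- vapply(grp, function(ix) {
    p <- D$tau[ix]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  first <- vapply(grp, `[`, integer(1), 1L)
  data.frame(offset = e$offset[first], state = e$from[first],
             entropy = as.numeric(ent))
}

#' Mean node entropy of a probabilistic lattice
#'
#' Arithmetic mean of [node_entropy()] over all non-final states; the
#' "softness" of the distribution that drives beam-pruning search error.
#'
#' @param D A `prob_lattice`.
#' @return Bits (scalar).
#' @export
mean_entropy <- function(D) {
  mean(node_entropy(D)$entropy)
}

#' Serialize tau to TSV
#'
#' @param D A `prob_lattice`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tau_tsv <- function(D, path) {
  e <- D$lattice$edges
  out <- data.frame(state = paste0(e$offset, ":", e$from),
                    nucleotide = e$nuc, probability = D$tau)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.prob_lattice <- function(x, ...) {
  cat(sprintf("<prob_lattice> %d nt, %d parameters, mean node entropy %.3f bits\n",
              x$lattice$length, length(x$tau), mean_entropy(x)))
  invisible(x)
}
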