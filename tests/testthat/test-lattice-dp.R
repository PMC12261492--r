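test_that("Viterbi lattice design finds the joint sequence-structure optimum", {
  m <- energy_model()
  expect_equal(design_mfe(build_lattice("M"), m),
               list(mrna = "AUG", energy = 0, structure = as_pm(NULL),
                    dot_bracket = "..."))
  d <- design_mfe(build_lattice("DN"), m)
  expect_equal(d$mrna, "GACAAC")
  expect_equal(d$energy, -3)
  expect_equal(d$structure, as_pm(cbind(1, 6)))
  set.seed(71)
  for (rep in 1:30) {
    lat <- build_lattice(rand_protein(sample(1:3, 1)))
    d <- design_mfe(lat, m)
    # brute force: fold every sequence in the design space
    seqs <- enumerate_sequences(lat, 2000)
    best <- min(vapply(seqs, function(x) fold_mfe(x, m)$energy, numeric(1)))
    expect_equal(d$energy, best)
    expect_true(d$mrna %in% seqs)
    expect_equal(structure_energy(d$mrna, d$structure, m), d$energy)
    expect_identical(design_mfe(lat, m), d) # deterministic
  }
})

test_that("the probabilistic inside engine reduces to Q on one-hot input", {
  m <- energy_model()
  lat <- build_lattice("MW")
  D <- prob_degenerate(lat, "AUGUGG")
  expect_equal(expected_partition_function(D, m),
               partition_function("AUGUGG", m)$logQ, tolerance = 1e-12)
  set.seed(81)
  for (rep in 1:50) {
    lat <- build_lattice(rand_protein(sample(1:6, 1)))
    x <- sample_sequence(prob_uniform(lat))
    D <- prob_degenerate(lat, x)
    lhs <- expected_partition_function(D, m)
    rhs <- partition_function(x, m)$logQ
    expect_true(abs(lhs - rhs) < 1e-10)
  }
})

test_that("the expected partition function equals its enumeration oracle", {
  m <- energy_model()
  # closed form for the uniform distribution over Asp-Asn
  lat <- build_lattice("DN")
  Du <- prob_uniform(lat)
  RT <- m$RT
  # Q depends only on x6: ..C ensembles {open, G1-C6}, ..U {open, G1-U6, A2-U6}
  want <- log(mean(c(1 + exp(3 / RT),                 # GACAAC
                     1 + exp(1 / RT) + exp(2 / RT),   # GACAAU
                     1 + exp(3 / RT),                 # GAUAAC
                     1 + exp(1 / RT) + exp(2 / RT)))) # GAUAAU
  expect_equal(expected_partition_function(Du, m), log(brute_epf(Du, m)),
               tolerance = 1e-12)
  expect_equal(expected_partition_function(Du, m), want, tolerance = 1e-9)
  expect_equal(expected_partition_function(prob_uniform(build_lattice("M")), m), 0)
  set.seed(91)
  for (rep in 1:50) {
    lat <- build_lattice(rand_protein(sample(1:4, 1)))
    D <- rand_tau(lat, seed = 1000 + rep)
    lhs <- expected_partition_function(D, m)
    rhs <- log(brute_epf(D, m))
    expect_true(abs(expm1(lhs - rhs)) < 1e-9) # relative error on Qtilde
  }
})

test_that("the Jensen surrogate bounds the expected ensemble free energy", {
  m <- energy_model()
  RT <- m$RT
  set.seed(101)
  for (rep in 1:50) {
    lat <- build_lattice(rand_protein(sample(2:4, 1)))
    D <- rand_tau(lat, seed = 2000 + rep)
    surrogate <- -RT * expected_partition_function(D, m)
    seqs <- enumerate_sequences(lat, 2000)
    probs <- vapply(seqs, sequence_probability, numeric(1), D = D)
    efes <- vapply(seqs, function(x) partition_function(x, m)$efe, numeric(1))
    expected_efe <- sum(probs * efes)
    expect_true(surrogate <= expected_efe + 1e-9)
    # strict unless the distribution is (near) degenerate and Q varies
    if (mean_entropy(D) > 0.05 && stats::sd(efes) > 1e-6)
      expect_true(surrogate < expected_efe)
    Dd <- prob_degenerate(lat, seqs[1])
    expect_equal(-RT * expected_partition_function(Dd, m),
                 partition_function(seqs[1], m)$efe, tolerance = 1e-9)
  }
})

test_that("inside-outside gradients match central finite differences", {
  m <- energy_model()
  fd_gradient <- function(lat, tau, eps = 1e-6) {
    mat <- efedesign:::lattice_matrix(lat)
    pm <- efedesign:::pair_matrix(m)
    q <- function(tv) exp(efedesign:::lattice_inside_cpp(
      lat$length, lat$nstates, mat, log(tv), pm, m$hairpin, m$RT, 0L))
    vapply(seq_along(tau), function(e) {
      up <- tau; up[e] <- up[e] + eps
      dn <- tau; dn[e] <- max(dn[e] - eps, 0)
      (q(up) - q(dn)) / (up[e] - dn[e])
    }, numeric(1))
  }
  set.seed(111)
  for (rep in 1:8) {
    lat <- build_lattice(rand_protein(sample(2:3, 1)))
    D <- if (rep %% 2 == 0) rand_tau(lat, seed = rep)
         else prob_degenerate(lat, sample_sequence(prob_uniform(lat)))
    g <- epf_gradient(D, m)
    got <- exp(g$log_magnitude)
    want <- fd_gradient(lat, D$tau)
    expect_equal(got, want, tolerance = 1e-4)
    expect_true(all(got >= 0))
    expect_equal(attr(g, "logQ"), expected_partition_function(D, m))
  }
  # single-codon protein: Qtilde is the product of the three edge parameters
  lat <- build_lattice("M")
  D <- prob_uniform(lat)
  g <- epf_gradient(D, m)
  expect_equal(g$log_magnitude, rep(0, 3)) # dQ/dtheta = Qtilde / theta = 1
})

test_that("beam pruning is exact at infinite width and errs on soft input", {
  m <- energy_model()
  set.seed(121)
  lat <- build_lattice(rand_protein(10))
  Du <- prob_uniform(lat)
  probe <- beam_error_probe(Du, m, beams = c(Inf, 1, 2, 8))
  expect_equal(probe$rel_error[1], 0)
  expect_true(all(probe$rel_error >= 0))
  # a one-hot distribution keeps its single path at any beam width
  Dd <- prob_degenerate(lat, design_mfe(lat, m)$mrna)
  probe_d <- beam_error_probe(Dd, m, beams = c(1, 2, 8))
  expect_equal(probe_d$rel_error, rep(0, 3), tolerance = 1e-12)
  # search error grows with distribution entropy at a fixed beam
  expect_true(probe$mean_entropy[1] > probe_d$mean_entropy[1])
  expect_true(all(probe$rel_error[probe$beam == 2] >=
                  probe_d$rel_error[probe_d$beam == 2]))
})
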