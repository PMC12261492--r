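test_that("degenerate distributions put all mass on one sequence", {
  lat <- build_lattice("MW")
  D <- prob_degenerate(lat, "AUGUGG")
  expect_equal(sequence_probability(D, "AUGUGG"), 1)
  lat2 <- build_lattice("DN")
  D2 <- prob_degenerate(lat2, "GACAAC")
  expect_equal(sequence_probability(D2, "GACAAC"), 1)
  expect_equal(sequence_probability(D2, "GAUAAU"), 0)
  expect_error(prob_degenerate(lat, "AUGUGA"), "position 6")
})

test_that("uniform distributions split branch probabilities evenly", {
  latM <- build_lattice("M")
  expect_true(all(prob_uniform(latM)$tau == 1))
  latL <- build_lattice("L")
  DL <- prob_uniform(latL)
  first <- DL$lattice$edges$offset == 0
  expect_equal(DL$tau[first], c(0.5, 0.5)) # branches C and U for Leu
  # per-branch sequence masses: 4-codon branch 1/8 each, 2-codon branch 1/4
  seqs <- enumerate_sequences(latL)
  p <- vapply(seqs, sequence_probability, numeric(1), D = DL)
  expect_equal(sum(p), 1)
  expect_setequal(round(unique(p), 10), round(c(1 / 8, 1 / 4), 10))
})

test_that("sequence probabilities are path products summing to one", {
  lat <- build_lattice("DN")
  D <- prob_uniform(lat)
  expect_equal(sequence_probability(D, "GAUAAC"), 0.25)
  set.seed(11)
  for (rep in 1:10) {
    lat <- build_lattice(rand_protein(sample(1:4, 1)))
    D <- rand_tau(lat, seed = rep)
    p <- vapply(enumerate_sequences(lat, 2000), sequence_probability,
                numeric(1), D = D)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("sampling follows the distribution and is seed-reproducible", {
  lat <- build_lattice("DN")
  D <- prob_uniform(lat)
  expect_identical(sample_sequence(D, seed = 99), sample_sequence(D, seed = 99))
  Dd <- prob_degenerate(lat, "GACAAU")
  expect_identical(sample_sequence(Dd, seed = 1), "GACAAU")
  expect_identical(sample_sequence(Dd, seed = 2), "GACAAU")
  n <- 10000
  draws <- withr::with_seed(123, vapply(seq_len(n), function(i)
    sample_sequence(D), character(1)))
  freq <- table(factor(draws, levels = enumerate_sequences(lat))) / n
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 3 * sigma + 1e-12))
})

test_that("argmax decoding picks maximal edges with A<C<G<U ties", {
  lat <- build_lattice("DN")
  expect_equal(argmax_decode(prob_uniform(lat)), "GACAAC") # all ties
  expect_equal(argmax_decode(prob_degenerate(lat, "GAUAAU")), "GAUAAU")
  # tilt the third-position choice toward U
  D <- prob_uniform(lat)
  ix <- which(lat$edges$offset == 2)
  D$tau[ix] <- ifelse(lat$edges$nuc[ix] == "U", 0.9, 0.1)
  expect_equal(argmax_decode(D), "GAUAAC")
})

test_that("soft-MFE initialization interpolates between one-hot and random", {
  lat <- build_lattice("DNS")
  x <- design_mfe(lat)$mrna
  D0 <- soft_mfe_init(lat, x, epsilon = 0, seed = 5)
  expect_identical(D0$tau, prob_degenerate(lat, x)$tau)
  # epsilon = 1 ignores the anchor sequence
  seqs <- enumerate_sequences(lat)
  D1a <- soft_mfe_init(lat, seqs[1], epsilon = 1, seed = 5)
  D1b <- soft_mfe_init(lat, seqs[5], epsilon = 1, seed = 5)
  expect_identical(D1a$tau, D1b$tau)
  # convex combination arithmetic at one node
  lat2 <- build_lattice("L")
  xm <- enumerate_sequences(lat2)[1] # CUA: branch C at the first node
  Dr <- soft_mfe_init(lat2, xm, epsilon = 1, seed = 3)
  Dh <- soft_mfe_init(lat2, xm, epsilon = 0.5, seed = 3)
  first <- lat2$edges$offset == 0
  expect_equal(Dh$tau[first],
               0.5 * Dr$tau[first] + 0.5 * c(1, 0))
  # invariants across the (epsilon, seed) grid
  for (eps in c(0, 0.25, 0.5, 1)) for (sd in 1:3) {
    D <- soft_mfe_init(lat, x, eps, sd)
    sums <- tapply(D$tau, paste(lat$edges$offset, lat$edges$from), sum)
    expect_true(all(abs(sums - 1) < 1e-9) && all(D$tau >= 0))
  }
  expect_error(soft_mfe_init(lat, x, epsilon = 1.2), "\\[0, 1\\]")
})

test_that("node and mean entropies follow the distribution", {
  lat <- build_lattice("D")
  expect_equal(mean_entropy(prob_degenerate(lat, "GAU")), 0)
  expect_equal(mean_entropy(prob_uniform(build_lattice("M"))), 0)
  expect_equal(mean_entropy(prob_uniform(lat)), 1 / 3) # one binary node of 3
  # a four-way node carries 2 bits (Val third position)
  latV <- build_lattice("V")
  ne <- node_entropy(prob_uniform(latV))
  expect_equal(ne$entropy[ne$offset == 2], 2)
})

test_that("tau serializes to TSV", {
  lat <- build_lattice("DN")
  D <- prob_uniform(lat)
  tsv <- tempfile(fileext = ".tsv")
  write_tau_tsv(D, tsv)
  got <- read.delim(tsv)
  expect_equal(nrow(got), length(D$tau))
  expect_equal(sum(got$probability), sum(D$tau))
})
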