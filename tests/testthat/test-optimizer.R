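test_that("simplex projection is exact, feasible and idempotent", {
  expect_equal(project_simplex(c(0.5, 0.7)), c(0.4, 0.6))
  expect_equal(project_simplex(c(2, 0)), c(1, 0))
  expect_equal(project_simplex(c(1)), 1)
  expect_error(project_simplex(numeric(0)), "empty")
  expect_error(project_simplex(c(1, NA)), "finite")
  set.seed(131)
  for (rep in 1:40) {
    v <- stats::rnorm(sample(2:6, 1), sd = 2)
    w <- project_simplex(v)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(project_simplex(w), w, tolerance = 1e-12)
  }
  # dense grid-search oracle over the 4-point simplex
  grid <- as.matrix(expand.grid(i = 0:50, j = 0:50, k = 0:50))
  grid <- grid[rowSums(grid) <= 50, ]
  grid <- cbind(grid, 50 - rowSums(grid)) / 50
  for (rep in 1:5) {
    v <- stats::rnorm(4, sd = 1.5)
    w <- project_simplex(v)
    best <- min(colSums((t(grid) - v)^2))
    expect_true(sum((w - v)^2) <= best + 1e-3)
  }
})

test_that("optimizer settings are validated", {
  expect_error(design_control(alpha = 0), "alpha")
  expect_error(design_control(epsilon = -0.1), "epsilon")
  expect_error(design_control(max_steps = 0), "max_steps")
  expect_error(design_control(runs = 0), "runs")
  ctrl <- design_control()
  expect_equal(ctrl$epsilon, 0.5)
  expect_equal(ctrl$max_steps, 30L)
})

test_that("a vanishing step from the one-hot MFE start returns the MFE design", {
  lat <- build_lattice("DNS")
  mfe <- design_mfe(lat)
  fit <- ensemble_design(lat, control = design_control(
    alpha = 1e-30, max_steps = 1, epsilon = 0, runs = 1,
    candidates_per_run = 1), seed = 4)
  expect_equal(fit$mrna, mfe$mrna)
  expect_equal(fit$codon_change, 0)
})

test_that("singleton design spaces are returned unchanged", {
  fit <- ensemble_design("M", control = design_control(runs = 2,
                                                       candidates_per_run = 2))
  expect_equal(fit$mrna, "AUG")
  expect_equal(fit$efe, 0)
})

test_that("the ensemble design attains the enumerated EFE optimum on Asp-Asn", {
  m <- energy_model()
  lat <- build_lattice("DN")
  fit <- ensemble_design(lat, m, design_control(runs = 3), seed = 2)
  efes <- vapply(enumerate_sequences(lat), function(x)
    partition_function(x, m)$efe, numeric(1))
  expect_equal(fit$efe, min(efes))
  expect_true(fit$efe <= partition_function(design_mfe(lat, m)$mrna, m)$efe)
})

test_that("optimization traces ascend and parameters stay feasible", {
  set.seed(141)
  lat <- build_lattice(rand_protein(10))
  fit <- ensemble_design(lat, control = design_control(runs = 2,
                                                       candidates_per_run = 3),
                         seed = 9)
  for (z in fit$runs) {
    expect_true(all(diff(z$trace$log_epf) >= 0))
    expect_true(z$trace$log_epf[nrow(z$trace)] >= z$trace$log_epf[1])
    sums <- tapply(z$tau, paste(lat$edges$offset, lat$edges$from), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  # the fitted object recomputes its own EFE exactly
  expect_equal(fit$efe, partition_function(fit$mrna)$efe)
  expect_equal(translate_mrna(fit$mrna), lat$protein)
})

test_that("model methods expose the fit the standard way", {
  set.seed(151)
  lat <- build_lattice(rand_protein(6))
  fit <- ensemble_design(lat, control = design_control(runs = 2,
                                                       candidates_per_run = 2),
                         seed = 3)
  expect_output(print(fit), "mrna_design:ensemble")
  s <- summary(fit)
  expect_s3_class(s, "summary.ensemble_design")
  expect_equal(nrow(s$runs), 2)
  tau <- coef(fit)
  expect_equal(nrow(tau), nrow(lat$edges))
  sums <- tapply(tau$tau, paste(tau$offset, tau$state), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  sims <- simulate(fit, nsim = 5, seed = 11)
  expect_true(all(vapply(sims, translate_mrna, character(1)) == lat$protein))
  expect_identical(sims, simulate(fit, nsim = 5, seed = 11))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  jl <- tempfile(fileext = ".jsonl")
  write_trace_jsonl(fit, jl)
  lines <- readLines(jl)
  expect_equal(length(lines), sum(vapply(fit$runs, function(z)
    nrow(z$trace), integer(1))))
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$iter, 0)
  expect_true(is.numeric(rec$log_epf))
})

test_that("the random walk only ever improves and is reproducible", {
  m <- energy_model()
  lat <- build_lattice("DN")
  rw0 <- random_walk_design(lat, m, start = "GACAAC", steps = 0, seed = 1)
  expect_equal(rw0$mrna, "GACAAC")
  # no strictly better sequence exists among the four
  rw <- random_walk_design(lat, m, start = "GACAAC", steps = 100, seed = 5)
  expect_equal(rw$mrna, "GACAAC")
  set.seed(161)
  lat <- build_lattice(rand_protein(12))
  start <- design_mfe(lat, m)$mrna
  a <- random_walk_design(lat, m, start = start, steps = 40, seed = 8)
  b <- random_walk_design(lat, m, start = start, steps = 40, seed = 8)
  expect_identical(a$mrna, b$mrna)
  expect_true(a$efe <= partition_function(start, m)$efe)
  expect_true(all(diff(a$accepted$efe) < 0)) # strict improvements only
  expect_equal(translate_mrna(a$mrna), lat$protein)
})

test_that("codon change fractions count differing triplets", {
  expect_equal(codon_change_fraction("GACAAC", "GACAAC"), 0)
  expect_equal(codon_change_fraction("GACAAC", "GACAAU"), 0.5)
  expect_equal(codon_change_fraction("GAUAAU", "GACAAC"), 1)
  expect_error(codon_change_fraction("GACAAC", "AUG"), "length")
  expect_error(codon_change_fraction("GACAAC", "AAUGAU"), "different proteins")
})
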