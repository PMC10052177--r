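test_that("build_toy_system assembles the requested composition", {
  sys <- build_toy_system(4, monomer_counts = c(3, 3, 3, 3), seed = 1)
  expect_equal(sys$N, 12)
  expect_equal(length(sys$chains), 0)
  expect_equal(unname(sys$composition), rep(3L, 4))
  expect_equal(sys$units$site, 0:11)

  sys2 <- build_toy_system(4, chain_specs = list(list(seq = "ACGU",
                                                      copies = 3)), seed = 1)
  expect_equal(sys2$N, 12)
  expect_equal(length(sys2$chains), 3)
  expect_true(all(vapply(sys2$chains, paste, "", collapse = "") == "ACGU"))
  # chains occupy consecutive sites
  for (id in 1:3) {
    s <- sys2$units$site[sys2$units$chain_id == id]
    expect_equal(s, seq(min(s), min(s) + 3))
  }
  expect_error(build_toy_system(2, chain_specs = list(list(seq = "ACGU"))),
               "alphabet")
  expect_error(build_toy_system(4, monomer_counts = c(1, 1)), "monomer_counts")
})

test_that("seeds change the arrangement but not the composition", {
  spec <- list(list(seq = "ACGU", copies = 2))
  a <- build_toy_system(4, monomer_counts = c(1, 1, 1, 1),
                        chain_specs = spec, seed = 1)
  b <- build_toy_system(4, monomer_counts = c(1, 1, 1, 1),
                        chain_specs = spec, seed = 2)
  expect_equal(a$composition, b$composition)
  expect_false(identical(a$units, b$units))
  # and the same seed reproduces the arrangement exactly
  expect_identical(a, build_toy_system(4, monomer_counts = c(1, 1, 1, 1),
                                       chain_specs = spec, seed = 1))
})

test_that("sample_walk follows nearest-unvisited with low-site tie-break", {
  # single chain: walk from the left end reads the chain in order
  sys <- build_toy_system(4, chain_specs = list(list(seq = "ACGU")), seed = 1)
  w <- sample_walk(sys, start = 0)
  expect_equal(w$sites, 0:3)
  expect_identical(w$types, "ACGU")
  # start at site 1: tie between sites 0 and 2 breaks to the lower index,
  # then nearest-unvisited skips over the visited stretch
  w2 <- sample_walk(sys, start = 1)
  expect_equal(w2$sites, c(1, 0, 2, 3))
  expect_identical(w2$types, "CAGU")
  # any walk visits every site exactly once
  sys3 <- build_toy_system(3, monomer_counts = c(2, 2, 2), seed = 5)
  for (st in sys3$units$site)
    expect_setequal(sample_walk(sys3, st)$sites, sys3$units$site)
  expect_error(sample_walk(sys, start = 99), "start")
})

test_that("walk ensemble: crystal-like systems have one sequence", {
  systems <- lapply(1:5, function(s)
    build_toy_system(1, chain_specs = list(list(seq = "AAAA", copies = 2)),
                     seed = s))
  expect_identical(walk_ensemble_log_weight(systems), 0)
  # set semantics: duplicated arrangements add nothing
  expect_identical(walk_ensemble_log_weight(c(systems, systems)), 0)
  sysA <- build_toy_system(2, monomer_counts = c(2, 2), seed = 1)
  expect_identical(walk_ensemble_log_weight(list(sysA, sysA)),
                   walk_ensemble_log_weight(list(sysA)))
})

test_that("walk ensemble orders the four canonical states as the closed
           forms do", {
  seeds <- 7:31
  ln_crystal <- walk_ensemble_log_weight(lapply(seeds, function(s)
    build_toy_system(2, chain_specs = list(list(seq = "AAAA"),
                                           list(seq = "BBBB")), seed = s)))
  ln_defined <- walk_ensemble_log_weight(lapply(seeds, function(s)
    build_toy_system(2, chain_specs = list(list(seq = "ABBA", copies = 2)),
                     seed = s)))
  ln_monomer <- walk_ensemble_log_weight(lapply(seeds, function(s)
    build_toy_system(2, monomer_counts = c(4, 4), seed = s)))
  ln_random <- walk_ensemble_log_weight(lapply(seeds, function(s)
    build_toy_system(2, chain_specs = list(list(length = 4, copies = 2,
                                                random = TRUE)), seed = s)))
  expect_lt(max(ln_crystal, ln_defined), ln_monomer)
  expect_lt(ln_monomer, ln_random)
})

test_that("multinomial mixing entropy is exact and Stirling-consistent", {
  expect_equal(multinomial_mixing_entropy(c(1, 1)), log(2))
  expect_identical(multinomial_mixing_entropy(c(7, 0, 0, 0)), 0)
  expect_equal(multinomial_mixing_entropy(c(2, 1)), log(3))
  # brute-force cross-check at tiny size: enumerate distinct orderings
  perm_strings <- function(v) {
    if (length(v) == 1) return(v)
    unlist(lapply(seq_along(v),
                  function(i) paste0(v[i], perm_strings(v[-i]))))
  }
  expect_equal(multinomial_mixing_entropy(c(2, 1, 1)),
               log(length(unique(perm_strings(c("A", "A", "B", "C"))))))
  # Stirling convergence at N = 1e4
  exact <- multinomial_mixing_entropy(rep(2500, 4))
  expect_lt(abs(exact - 1e4 * log(4)) / (1e4 * log(4)), 0.01)
})

test_that("explicit encodings fall within a factor 2 of min(c1, c2)", {
  fixtures <- list(
    list(sys = build_toy_system(4, chain_specs = list(list(seq = "ACGU",
                                                           copies = 3)),
                                seed = 7), L = 4),
    list(sys = build_toy_system(2, chain_specs = list(list(length = 2,
                                                           copies = 8,
                                                           random = TRUE)),
                                seed = 7), L = 2),
    list(sys = build_toy_system(4, chain_specs = list(list(length = 3,
                                                           copies = 4,
                                                           random = TRUE)),
                                seed = 8), L = 3))
  for (fx in fixtures) {
    oracle <- explicit_encoding_length(fx$sys)
    formula <- min(c1_random(fx$sys$n, fx$L, fx$sys$N),
                   c2_explicit(fx$sys$N, fx$sys$n))
    expect_lte(oracle, 2 * formula)
    expect_lte(formula, 2 * oracle)
  }
  # single free unit costs one symbol
  expect_identical(explicit_encoding_length(
    build_toy_system(4, monomer_counts = c(1, 0, 0, 0))), 2)
})

test_that("run_oracle_suite reports all checks green", {
  res <- run_oracle_suite()
  expect_true(all(res$pass))
  expect_gte(nrow(res), 6)
})
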