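test_that("entropy_general matches the term-by-term high-precision oracle", {
  st <- system_state(4, N = 120, L = 6, M = 2, p = 0.5,
                     r = c(0.4, 0.3, 0.2, 0.1),
                     pk = c(0.7, 0.1, 0.1, 0.1),
                     a = rep(1 / 6, 6))
  ent <- entropy_general(st)
  expect_equal(ent$term_mixing, frozen$general_mix_k, tolerance = 1e-12)
  expect_equal(ent$term_contact, frozen$general_contact_k, tolerance = 1e-12)
  expect_equal(ent$term_sequence, frozen$general_seq_k, tolerance = 1e-12)
  expect_equal(ent$S_r_k, frozen$general_total_k, tolerance = 1e-12)
})

test_that("fully defined chains carry no sequence entropy (0 ln(1/0) = 0)", {
  st <- system_state(4, N = 100, L = 4, M = 0, pk = c(1, 0, 0, 0))
  ent <- entropy_general(st)
  expect_identical(ent$term_sequence, 0)
  # §3 case-4 shape: S_r/k = (2N/L) ln L
  expect_equal(ent$S_r_k, (2 * 100 / 4) * log(4), tolerance = 1e-12)
})

test_that("fully random pk reduces entropy_general to entropy_uniform(p=1)", {
  st <- system_state(4, N = 500, L = 8, M = 3, pk = rep(0.25, 4))
  expect_equal(entropy_general(st)$S_r_k,
               entropy_uniform(4, 500, 8, 3, 1)$S_r_k, tolerance = 1e-12)
})

test_that("entropy_general without pk directs to the reductions", {
  st <- make_uniform_state(4, N = 10, L = 2, M = 1, p = 0.5)
  expect_error(entropy_general(st), "entropy_two_level")
})

test_that("entropy_two_level endpoints and frozen mid-point value", {
  st <- make_uniform_state(4, N = 1000, L = 20, M = 10, p = 0)
  expect_identical(entropy_two_level(st)$term_sequence, 0)
  expect_equal(entropy_two_level(st, p = 1)$S_r_k,
               entropy_uniform(4, 1000, 20, 10, 1)$S_r_k, tolerance = 1e-12)
  expect_equal(entropy_uniform(4, 1000, 20, 10, 0.5)$S_r_k,
               frozen$two_level_k, tolerance = 1e-12)
})

test_that("reduction chain holds on randomized grids (property)", {
  set.seed(7)
  for (i in 1:40) {
    ps <- draw_params()
    # explicit uniform profiles must equal the uniform-flagged path
    st_exp <- system_state(ps$n, N = ps$N, L = ps$L, M = ps$M, p = ps$p,
                           r = rep(1 / ps$n, ps$n),
                           a = rep(1 / ceiling(ps$L), ceiling(ps$L)))
    st_uni <- make_uniform_state(ps$n, N = ps$N, L = ps$L, M = ps$M, p = ps$p)
    e_exp <- entropy_two_level(st_exp)
    e_uni <- entropy_two_level(st_uni)
    expect_equal(e_exp$term_mixing, e_uni$term_mixing, tolerance = 1e-12)
    expect_equal(e_exp$term_sequence, e_uni$term_sequence, tolerance = 1e-12)
    # contact term: profile sum over ceiling(L) slots vs ln L agree only at
    # integer L, where the uniform reduction is exact
    if (ps$L == round(ps$L))
      expect_equal(e_exp$term_contact, e_uni$term_contact, tolerance = 1e-12)
    # uniform convenience form equals the two-level path
    expect_equal(e_uni$S_r_k,
                 entropy_uniform(ps$n, ps$N, ps$L, ps$M, ps$p)$S_r_k,
                 tolerance = 1e-12)
    # breakdown invariants
    expect_true(all(c(e_uni$term_mixing, e_uni$term_contact,
                      e_uni$term_sequence) >= 0))
    expect_equal(e_uni$S_r_k,
                 e_uni$term_mixing + e_uni$term_contact + e_uni$term_sequence,
                 tolerance = 1e-9)
    if (e_uni$S_r_k > 0)
      expect_equal(e_uni$order_KJ * e_uni$S_r_JK, 1, tolerance = 1e-12)
  }
})

test_that("uniform closed form reproduces the four limiting cases", {
  N <- moles_to_units(1)
  # case 1: L=1, p=1 -> kN ln n, independently of M (algebraic identity)
  for (M in c(0, 10)) {
    e <- entropy_uniform(4, N, 1, M, 1)
    expect_equal(e$S_r_k, N * log(4), tolerance = 1e-12)
    expect_equal(e$S_r_JK, frozen$pure_monomer_JK, tolerance = 1e-12)
  }
  # cases 2/4: M=0, p=0 -> k(2N/L) ln L
  e4 <- entropy_uniform(4, N, 20, 0, 0)
  expect_equal(e4$S_r_k, (2 * N / 20) * log(20), tolerance = 1e-12)
  expect_equal(e4$S_r_JK, frozen$defined_L20_JK, tolerance = 1e-12)
  # case 3: M=0, p=1 -> k(2N/L) ln L + kN ln n
  e3 <- entropy_uniform(4, N, 20, 0, 1)
  expect_equal(e3$S_r_k, (2 * N / 20) * log(20) + N * log(4),
               tolerance = 1e-12)
  # single-letter monomer system has a single microstate
  expect_identical(entropy_uniform(1, 10, 1, 0, 1)$S_r_k, 0)
})

test_that("limiting_case_entropy returns the printed closed forms", {
  N <- moles_to_units(1)
  expect_equal(limiting_case_entropy("pure_monomer", n = 4, N = N) * kB,
               frozen$pure_monomer_JK, tolerance = 1e-12)
  expect_equal(limiting_case_entropy("crystals", n = 1, N = 100, L = 100),
               2 * log(100), tolerance = 1e-12)
  expect_equal(limiting_case_entropy("random_chains", n = 4, N = 100, L = 10),
               frozen$random_chains_100, tolerance = 1e-12)
  expect_equal(limiting_case_entropy("defined_chains", n = 4, N = 100, L = 10),
               20 * log(10), tolerance = 1e-12)
  expect_error(limiting_case_entropy("melted", n = 4, N = 1))
  expect_error(limiting_case_entropy("crystals", n = 4, N = 1), "`L`")
})

test_that("order_parameter is the guarded reciprocal", {
  expect_equal(order_parameter(frozen$pure_monomer_JK), frozen$order_pure_KJ,
               tolerance = 1e-12)
  expect_identical(order_parameter(1), 1)
  expect_error(order_parameter(0), "single microstate")
  expect_error(order_parameter(-1), "S_r_JK")
})

test_that("living/dead gap equals kN ln n and the case difference", {
  N <- moles_to_units(1)
  expect_equal(living_dead_gap(4, N) * kB, frozen$pure_monomer_JK,
               tolerance = 1e-12)
  expect_identical(living_dead_gap(1, 123), 0)
  # equals random - defined at matched L, both via limiting cases and Eq. (3)
  expect_equal(living_dead_gap(4, 100),
               limiting_case_entropy("random_chains", 4, 100, 10) -
                 limiting_case_entropy("defined_chains", 4, 100, 10))
  expect_equal(living_dead_gap(4, 100),
               entropy_uniform(4, 100, 10, 0, 1)$S_r_k -
                 entropy_uniform(4, 100, 10, 0, 0)$S_r_k, tolerance = 1e-12)
})

test_that("S_r is strictly increasing in p; order strictly decreasing", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:6, 1); N <- runif(1, 10, 1e4)
    L <- runif(1, 1.5, 30); M <- runif(1, 0, 20)
    p <- sort(runif(5))
    s <- vapply(p, function(pp) entropy_uniform(n, N, L, M, pp)$S_r_k, 0)
    expect_true(all(diff(s) > 0))
    expect_true(all(diff(1 / s) < 0))
  }
})

test_that("mixing term converges to the exact multinomial count", {
  counts <- rep(2500, 4)
  exact <- multinomial_mixing_entropy(counts)
  stirling <- 1e4 * log(4)
  expect_lt(abs(exact - stirling) / stirling, 0.01)
})
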