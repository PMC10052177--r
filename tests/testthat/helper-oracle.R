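# Independent oracles and frozen expected values.
#
# The frozen constants below were computed with 50-digit arithmetic (mpmath)
# from the closed-form expressions, term by term, independently of the
# package implementation.  Double precision reproduces them to ~1e-15
# relative, so tests assert at 1e-12.

kB <- 1.380649e-23
N_AVOGADRO <- 6.02214076e23

frozen <- list(
  # k * N_A * ln 4, J/K for one mole of units (pure-monomer limit)
  pure_monomer_JK   = 11.526292643287959,
  # 50 * (10 ln4 + ln20 + 5 ln4): uniform form at n=4,N=1000,L=20,M=10,p=.5
  two_level_k       = 1189.5073845176175,
  # k * N_A * (2/20) * ln 20: defined chains at L=20, one mole
  defined_L20_JK    = 2.4907904002459874,
  # general form at n=4,N=120,L=6,M=2,r=(.4,.3,.2,.1),a unif,pk=(.7,.1,.1,.1)
  general_mix_k     = 61.433002840016038,
  general_contact_k = 43.002227261473320,
  general_seq_k     = 67.712255183183499,
  general_total_k   = 172.14748528467286,
  # 4^20 * log2(N_A / 20)
  c1_random_mol     = 82103495898992.32,
  # 40 + 4^20 * log2(N_A / 30)
  c1_mixed_p1_mol   = 81460322827676.49,
  # 40 + 20 * (0.5 N_A / 30) * 2
  c2_mixed_half_mol = 4.0147605066666667e23,
  # N_A * 2
  c2_explicit_mol   = 1.204428152e24,
  # 2 + 4 * log2(0.5 N_A / 11): L = 1 endpoint of the chain-length sweep
  c1_L1_sweep       = 300.14076397367570,
  # 1 / (k N_A ln 4)
  order_pure_KJ     = 0.086758165088088785,
  # 20 ln 10 + 100 ln 4: random chains at n=4, N=100, L=10, units of k
  random_chains_100 = 184.68113797186998
)

# Straight transcription of the uniform closed form, kept deliberately
# separate from the package's construction path.
oracle_uniform_k <- function(n, N, L, M, p) {
  W <- N / (M + L / 2)
  W * (M * log(n) + log(L) + p * (L / 2) * log(n))
}

# Random parameter draws satisfying the state invariants.
draw_params <- function() {
  list(n = sample(2:6, 1),
       N = runif(1, 10, 1e5),
       L = runif(1, 1, 40),
       M = runif(1, 0, 30),
       p = runif(1))
}
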