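# shared fixtures: default elasticity models and a cached short baseline

el_ds <- ds_dna_elasticity()
el_ds_inext <- ds_dna_elasticity(stretch_modulus = Inf)
el_ss <- ss_dna_elasticity()

# nM per nm^-3, used by analytic J-factor oracles
NM3_TO_NM <- 1e24 / 6.02214076e23 * 1e9

# small cached unzipping baseline (1 kb, 50% GC)
fixture_baseline <- local({
  seqc <- random_dna_sequence(1000, gc = 0.5, seed = 424)
  equilibrium_unzip_baseline(seqc)
})

# fast MC settings for unit-level sampling checks
fast_mc <- function(seed = 1, n_prod = 5e4) {
  mc_settings(n_equil = 1e4, n_prod = n_prod, seed = seed)
}
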