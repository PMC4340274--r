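# Shared fixtures: parameter sets and models used across test files.

grx1_params <- function() {
  grx_params(k1 = 0.073, k2_wt = 4.23e-6, k2p_mut = 0.01, k_hed = 0.073,
             grx_tot = 0.24)
}

wt_core_grx1 <- function(pssg = 70, gsh = 998) {
  build_wildtype_core(grx1_params(), pssg = pssg, gsh = gsh)
}

hed_model_grx1 <- function() {
  prof <- grx_profile("grx1")
  build_hed_assay(prof$params, prof$species)
}

ecoli_model <- function(reversible = FALSE, gsh = 1000, pssg = 5) {
  build_ecoli_system(ecoli_default_params(), reversible = reversible,
                     clamped = c(NADPH = 250, NADP = 1, GSH = gsh,
                                 PSSG = pssg, PSH = 1))
}

# log-uniform parameter draws over `decades` decades centred on `centre`
draw_log_uniform <- function(n, centre, decades = 4) {
  centre * 10^stats::runif(n, -decades / 2, decades / 2)
}
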