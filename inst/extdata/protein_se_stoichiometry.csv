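species,n_se_atoms,molar_mass_gmol,stoichiometric,note
GPx,1,27362,TRUE,molar mass back-derived from the bundled cohort mean (fixture; GPx isoforms differ in subunit mass)
SMT,NA,NA,FALSE,heterogeneous low-molecular-weight selenometabolites with no single molar mass
SELENOP,13,49985,TRUE,13 SeCys per molecule in chicken; molar mass back-derived from the bundled cohort mean (fixture)
SELENOW_plus_others,NA,NA,FALSE,fraction may contain several Se species; measured Se cannot be attributed to SELENOW alone
SeAlb,NA,NA,FALSE,Se bound nonspecifically to albumin; no fixed Se:protein stoichiometry
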