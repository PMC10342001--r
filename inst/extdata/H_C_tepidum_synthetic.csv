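# species: C_tepidum
# units: cm^-1
# content: eight-site excitonic Hamiltonian of one FMO monomer (site basis,
#   BChls 1-8), real symmetric; diagonal = site energies, off-diagonal =
#   excitonic couplings.
# provenance: SYNTHETIC STAND-IN compiled from published excitonic models of
#   the C. tepidum FMO monomer (seven-site spectroscopy-fitted core extended
#   by the structure-based eighth site). Site energies carry an arbitrary
#   global offset (a uniform diagonal shift leaves populations and all
#   measures invariant). See the package vignette for details and caveats.
12410.0,-87.7,5.5,-5.9,6.7,-13.7,-9.9,37.5
-87.7,12530.0,30.8,8.2,0.7,11.8,4.3,7.9
5.5,30.8,12210.0,-53.5,-2.2,-9.6,6.0,1.5
-5.9,8.2,-53.5,12320.0,-70.7,-17.0,-63.3,-1.7
6.7,0.7,-2.2,-70.7,12480.0,81.1,-1.3,4.5
-13.7,11.8,-9.6,-17.0,81.1,12630.0,39.7,-9.7
-9.9,4.3,6.0,-63.3,-1.3,39.7,12440.0,3.2
37.5,7.9,1.5,-1.7,4.5,-9.7,3.2,12505.0
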