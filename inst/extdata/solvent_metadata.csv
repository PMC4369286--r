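# Solvent metadata: Kamlet-Taft hydrogen-bond basicity (beta, Marcus
# solvatochromic compilation), density at 298 K (g/cm3) and molar mass
# (g/mol). beta drives the monomer/dimer classification; density and
# molar mass serve mole-/mass-fraction unit conversions.
name,beta,density_g_per_cm3,molar_mass
water,0.47,0.997,18.02
methanol,0.66,0.791,32.04
ethanol,0.75,0.789,46.07
propan-1-ol,0.90,0.803,60.10
propan-2-ol,0.84,0.785,60.10
butan-1-ol,0.84,0.810,74.12
butan-2-ol,0.80,0.806,74.12
pentan-1-ol,0.86,0.814,88.15
pentan-2-ol,0.84,0.809,88.15
octan-1-ol,0.81,0.824,130.23
"octan-1-ol, wet",0.81,0.824,130.23
diethyl ether,0.47,0.713,74.12
"diethyl ether, wet",0.47,0.713,74.12
tetrahydrofuran,0.55,0.889,72.11
ethyl acetate,0.45,0.902,88.11
propyl acetate,0.40,0.888,102.13
propanone,0.43,0.791,58.08
acetonitrile,0.40,0.786,41.05
dimethyl sulfoxide,0.76,1.100,78.13
trichloromethane,0.10,1.489,119.38
tetrachloromethane,0.10,1.594,153.82
cyclohexane,0.00,0.779,84.16
benzene,0.10,0.876,78.11
toluene,0.11,0.867,92.14
p-xylene,0.12,0.861,106.17
chlorobenzene,0.07,1.106,112.56
nitrobenzene,0.30,1.204,123.11
trifluoroethanol,0.00,1.383,100.04
tetrachloroethylene,0.00,1.622,165.83
trichloroethylene,0.05,1.464,131.39
pentachloroethane,0.00,1.680,202.29
tetrachloroethane,0.00,1.595,167.85
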