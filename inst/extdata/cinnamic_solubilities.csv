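# Averaged saturation solubilities of trans-cinnamic acid at 298.15 K
# (mol/L), from Open Notebook Science Challenge data plus literature
# values, already temperature-corrected and replicate-averaged.
# Solvent names are canonicalized; the solubility table's "m-xylene"
# is recorded as p-xylene to match the partition-coefficient fixtures,
# and "chloroform"/"carbon tetrachloride" as trichloromethane /
# tetrachloromethane.
solvent,kind,value,unit,temperature_C,source
water,solubility,0.004,molarity,25,ons_challenge
cyclohexane,solubility,0.027,molarity,25,ons_challenge
tetrachloromethane,solubility,0.167,molarity,25,ons_challenge
trifluoroethanol,solubility,0.168,molarity,25,ons_challenge
p-xylene,solubility,0.201,molarity,25,ons_challenge
toluene,solubility,0.253,molarity,25,ons_challenge
acetonitrile,solubility,0.263,molarity,25,ons_challenge
tetrachloroethylene,solubility,0.277,molarity,25,ons_challenge
benzene,solubility,0.303,molarity,25,ons_challenge
chlorobenzene,solubility,0.314,molarity,25,ons_challenge
nitrobenzene,solubility,0.429,molarity,25,ons_challenge
octan-1-ol,solubility,0.537,molarity,25,ons_challenge
diethyl ether,solubility,0.575,molarity,25,ons_challenge
trichloroethylene,solubility,0.59,molarity,25,ons_challenge
propyl acetate,solubility,0.609,molarity,25,ons_challenge
pentachloroethane,solubility,0.617,molarity,25,ons_challenge
butan-2-ol,solubility,0.705,molarity,25,ons_challenge
pentan-1-ol,solubility,0.725,molarity,25,ons_challenge
butan-1-ol,solubility,0.735,molarity,25,ons_challenge
ethyl acetate,solubility,0.775,molarity,25,ons_challenge
pentan-2-ol,solubility,0.922,molarity,25,ons_challenge
propan-1-ol,solubility,0.934,molarity,25,ons_challenge
propan-2-ol,solubility,0.967,molarity,25,ons_challenge
trichloromethane,solubility,1.034,molarity,25,ons_challenge
tetrachloroethane,solubility,1.149,molarity,25,ons_challenge
ethanol,solubility,1.167,molarity,25,ons_challenge
propanone,solubility,1.337,molarity,25,ons_challenge
methanol,solubility,1.384,molarity,25,ons_challenge
tetrahydrofuran,solubility,2.367,molarity,25,ons_challenge
dimethyl sulfoxide,solubility,8.423,molarity,25,ons_challenge
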