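compound,smiles,logkp,kp_cm_s,source,layer,donor,temperature_c,ph,reference
paracetamol,CC(=O)Nc1ccc(O)cc1,-6.1,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
ethanol,CCO,-6.9,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
phenol,Oc1ccccc1,-5.8,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
benzene,c1ccccc1,-5.2,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
phenol,Oc1ccccc1,-7.0,,thigh,epidermis,diluted,33,7.2,synthetic fixture
aspirin,CC(=O)Oc1ccccc1C(=O)O,-6.3,,abdomen,epidermis + dermis,saturated,33,7.4,synthetic fixture
aspirin,CC(=O)Oc1ccccc1C(=O)O,-6.5,,abdomen,epidermis + dermis,saturated,33,7.4,synthetic fixture
fluorobenzene,Fc1ccccc1,-5.9,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
nitrobenzene,O=[N+]([O-])c1ccccc1,-6.0,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
ethanol,CCO,-7.3,,breast,epidermis,diluted,38,7.2,synthetic fixture
toluene,Cc1ccccc1,-5.6,,breast,epidermis,diluted,38,7.2,synthetic fixture
anisole,COc1ccccc1,-6.2,,breast,epidermis,diluted,38,7.2,synthetic fixture
propanol,CCCO,-6.7,,abdomen,epidermis,diluted,33,6.0,synthetic fixture
benzyl alcohol,OCc1ccccc1,,1e-7,abdomen,dermis,diluted,28,7.2,synthetic fixture
acetone,CC(C)=O,-7.2,,abdomen,dermis,diluted,28,7.2,synthetic fixture
chlorobenzene,Clc1ccccc1,-5.4,,abdomen,epidermis,diluted,thirty,7.2,synthetic fixture
aniline,Nc1ccccc1,,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
hexanol,CCCCCCO,-6.6,,forearm,epidermis,diluted,33,7.2,synthetic fixture
glycerol,OCC(O)CO,-7.8,,abdomen,stratum corneum,diluted,33,7.2,synthetic fixture
naphthalene,c1ccc2ccccc2c1,-5.0,,thigh,epidermis + dermis,diluted,22,7.2,synthetic fixture
bromobenzene,Brc1ccccc1,-5.7,,breast,epidermis + dermis,saturated,38,7.2,synthetic fixture
acetophenone,CC(=O)c1ccccc1,-6.8,,abdomen,epidermis,saturated,22,7.2,synthetic fixture
benzamide,NC(=O)c1ccccc1,-7.4,,abdomen,epidermis,diluted,33,7.5,synthetic fixture
p-cresol,Cc1ccc(O)cc1,-6.05,,abdomen,epidermis,diluted,33,,synthetic fixture
thiophenol,Sc1ccccc1,-5.5,,abdomen,epidermis,diluted,33,7.2,synthetic fixture
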