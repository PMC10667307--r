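name: eq1
type: fragment
provenance: global equation, 180 compounds; training n=144 R2=0.5002 RMSE=0.76; test n=36 R2=0.4003 RMSE=0.96
intercept: -5.622
aromatic: 0.186
amide: -0.369
amine: -0.374
bromine: 0.329
carboxylic_acid: -0.757
chlorine: 0.182
ether: -0.272
ester: -0.245
hydroxyl: -0.349
ketone: -0.313

name: eq2
type: fragment
source: abdomen
layer: epidermis
donor: diluted
temp_bin: 31-35
provenance: selected scenario equation (abdomen/epidermis/diluted/31-35), training n=29 R2=0.7125 RMSE=0.71; test n=7 R2=0.8931 RMSE=0.49
intercept: -4.916
aromatic: 0.168
amide: -0.176
amine: -1.143
bromine: 0
carboxylic_acid: -1.521
chlorine: 0.616
ether: 0.601
ester: 0.145
hydroxyl: -0.512
ketone: -0.131

name: dermwin
type: comparator
provenance: DERMWIN screening equation, log10 cm/h scale
intercept: -2.80
logkow_coeff: 0.66
mw_coeff: -0.0056

name: scenario_01
type: scenario
source: breast
layer: epidermis
donor: diluted
temp_bin: 36-40
n: 9
r_squared: 0.9639
intercept: -8.572
aromatic: 0.399
ester: 2.426
ether: -0.474
hydroxyl: -2.071

name: scenario_02
type: scenario
source: breast
layer: epidermis+dermis
donor: saturated
temp_bin: 36-40
n: 6
r_squared: 0.7874
intercept: -6.618
bromine: 0.217
chlorine: 0.123

name: scenario_03
type: scenario
source: breast
layer: epidermis+dermis
donor: diluted
temp_bin: 20-25
n: 4
r_squared: 0.9703
intercept: -4.226
chlorine: -0.040

name: scenario_04
type: scenario
source: breast
layer: epidermis+dermis
donor: diluted
temp_bin: 31-35
n: 20
r_squared: 0.5810
intercept: -6.878
aromatic: -0.739
amide: 0.548
amine: 0.651
carboxylic_acid: 1.451
ether: -0.325
hydroxyl: 1.030
ketone: -1.037

name: scenario_05
type: scenario
source: breast
layer: epidermis+dermis
donor: diluted
temp_bin: 36-40
n: 5
r_squared: 1.0000
intercept: -5.243
chlorine: -0.253
ester: 0.441
ether: 0
hydroxyl: -1.187
ketone: 0.826

name: scenario_06
type: scenario
source: abdomen
layer: epidermis
donor: saturated
temp_bin: 20-25
n: 10
intercept: -7.850

name: scenario_07
type: scenario
source: abdomen
layer: epidermis
donor: saturated
temp_bin: 26-30
n: 8
r_squared: 0.6325
intercept: -5.645
ester: -0.046
ether: -0.958

name: scenario_08
type: scenario
source: abdomen
layer: epidermis
donor: diluted
temp_bin: 20-25
n: 36
r_squared: 0.6757
intercept: -4.840
aromatic: 0.392
amide: -1.654
amine: -0.095
bromine: 0.424
chlorine: 0.266
ester: -0.173
hydroxyl: -0.975
ketone: -0.243

name: scenario_09
type: scenario
source: abdomen
layer: epidermis
donor: diluted
temp_bin: 26-30
n: 2
intercept: -6.351

name: scenario_10
type: scenario
source: abdomen
layer: epidermis
donor: diluted
temp_bin: 31-35
n: 36
r_squared: 0.7466
intercept: -4.925
aromatic: 0.245
amide: -0.054
amine: -1.184
carboxylic_acid: -1.582
chlorine: 0.589
ester: 0.089
ether: 0.537
hydroxyl: -0.509
ketone: -0.019

name: scenario_11
type: scenario
source: abdomen
layer: epidermis
donor: diluted
temp_bin: 36-40
n: 43
r_squared: 0.5094
intercept: -6.618
aromatic: 0.484
amide: 0.966
amine: -0.041
carboxylic_acid: -0.252
chlorine: 0.850
ester: -0.010
ether: -0.665
hydroxyl: -0.197
ketone: -1.195

name: scenario_12
type: scenario
source: abdomen
layer: dermis
donor: saturated
temp_bin: 20-25
n: 8
intercept: -6.674

name: scenario_13
type: scenario
source: abdomen
layer: dermis
donor: diluted
temp_bin: 20-25
n: 16
r_squared: 0.8849
intercept: -4.625
ester: 1.796
ether: 0.021
hydroxyl: -0.291
ketone: -1.542

name: scenario_14
type: scenario
source: abdomen
layer: dermis
donor: diluted
temp_bin: 31-35
n: 6
r_squared: 0.4186
intercept: -5.528
aromatic: -0.283

name: scenario_15
type: scenario
source: abdomen
layer: epidermis+dermis
donor: saturated
temp_bin: 26-30
n: 4
intercept: -8.632

name: scenario_16
type: scenario
source: abdomen
layer: epidermis+dermis
donor: diluted
temp_bin: 20-25
n: 4
intercept: -6.063
note: printed as "-6.063 (Hydroxyl)"; ambiguous, stored as a constant model

name: scenario_17
type: scenario
source: abdomen
layer: epidermis+dermis
donor: diluted
temp_bin: 26-30
n: 8
r_squared: 0.8446
intercept: -5.672
aromatic: 0.093
amide: -0.660
amine: 0.155
carboxylic_acid: 0.422
hydroxyl: -0.603

name: scenario_18
type: scenario
source: abdomen
layer: epidermis+dermis
donor: diluted
temp_bin: 31-35
n: 45
r_squared: 0.2794
intercept: -6.271
aromatic: -0.529
amide: -0.148
amine: -0.176
carboxylic_acid: 1.136
chlorine: 0.221
ester: -2.561
ether: 0.426
hydroxyl: -0.203
ketone: -0.665

name: scenario_19
type: scenario
source: abdomen
layer: epidermis+dermis
donor: diluted
temp_bin: 36-40
n: 14
r_squared: 0.9661
intercept: -5.007
ester: 0.478
hydroxyl: -1.423
ketone: 0.925

name: scenario_20
type: scenario
source: abdomen
layer: stratum_corneum
donor: diluted
temp_bin: 26-30
n: 3
r_squared: 0.2500
intercept: -5.562
amide: -0.395

name: scenario_21
type: scenario
source: abdomen
layer: stratum_corneum
donor: diluted
temp_bin: 31-35
n: 3
r_squared: 1.0000
intercept: -6.201
amide: -0.687
hydroxyl: 0.357

name: scenario_22
type: scenario
source: thigh
layer: epidermis
donor: diluted
temp_bin: 31-35
n: 3
r_squared: 1.0000
intercept: -8.667
aromatic: 0.394
amide: 0.488

name: scenario_23
type: scenario
source: thigh
layer: epidermis
donor: diluted
temp_bin: 36-40
n: 3
r_squared: 1.0000
intercept: -5.503
ether: 0.129
hydroxyl: -1.989

name: scenario_24
type: scenario
source: thigh
layer: epidermis+dermis
donor: diluted
temp_bin: 20-25
n: 5
intercept: -4.896

name: scenario_25
type: scenario
source: thigh
layer: epidermis+dermis
donor: diluted
temp_bin: 26-30
n: 17
r_squared: 0.8838
intercept: -5.260
aromatic: -0.080
amide: 0.240
amine: -0.376
chlorine: -0.181
ester: -2.674
ether: 0.119
hydroxyl: -0.245

name: scenario_26
type: scenario
source: thigh
layer: epidermis+dermis
donor: diluted
temp_bin: 31-35
n: 3
r_squared: 0.5127
intercept: -7.490
hydroxyl: 0.097

name: scenario_27
type: scenario
source: thigh
layer: epidermis+dermis
donor: diluted
temp_bin: 36-40
n: 21
r_squared: 0.3755
intercept: -3.997
aromatic: -0.094
amine: -1.469
ester: 0.576
hydroxyl: -1.052
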