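name,submodel
MinL,Phenology
Lincr,Phenology
Ldecr,Phenology
P,Phenology
Pincr,Phenology
SLDL,Phenology
PFLLAnth,Phenology
VAI,Phenology
VBEE,Phenology
AreaPL,Leaf layer expansion
PlagLL,Leaf layer expansion
PsenLL,Leaf layer expansion
RatioFLPL,Leaf layer expansion
aSheath,Leaf layer expansion
NLL,Leaf layer expansion
Kl,Light interception and use efficiency
TauSLN,Light interception and use efficiency
SlopeFR,Light interception and use efficiency
RUE,Light interception and use efficiency
Topt,Light interception and use efficiency
Dcd,Grain
Dgf,Grain
Kcd,Grain
FracBEAR,DM allocation
CritSLN,N allocation
MaxSLN,N allocation
StrucLeafN,N allocation
MaxStemN,N allocation
StrucStemN,N allocation
AlphaSSN,N allocation
AlphaNNI,N allocation
BetaKn,N allocation
BetaSSN,N allocation
MaxRWU,Root growth and N uptake
MaxNuptake,Root growth and N uptake
BetaRWU,Root growth and N uptake
MaxDSF,Soil drought factors
UpperFTSWexp,Soil drought factors
UpperFTSWgs,Soil drought factors
UpperFTSWrue,Soil drought factors
UpperFTSWsen,Soil drought factors
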