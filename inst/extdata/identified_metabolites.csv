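compound,family,differential,direction
glucose,sugar,TRUE,postembryonic
fructose,sugar,TRUE,postembryonic
DIMBOA,benzoxazinoid,TRUE,postembryonic
DIMBOA-Glc,benzoxazinoid,TRUE,postembryonic
DIM2BOA-Glc,benzoxazinoid,TRUE,postembryonic
leucine,amino acid,TRUE,postembryonic
tryptophan,amino acid,TRUE,postembryonic
phenylalanine,amino acid,TRUE,postembryonic
chlorogenic acid,phenolic acid,TRUE,postembryonic
HDMBOA-Glc,benzoxazinoid,TRUE,embryonic
HMBOA,benzoxazinoid,TRUE,embryonic
ferulic acid,phenolic acid,TRUE,embryonic
p-coumaric acid,phenolic acid,TRUE,embryonic
caffeic acid,phenolic acid,TRUE,embryonic
vanillic acid,phenolic acid,TRUE,embryonic
rutin,flavonoid,TRUE,embryonic
quercetin-3-glucoside,flavonoid,TRUE,embryonic
MBOA,benzoxazinoid,FALSE,NA
HMBOA-Glc,benzoxazinoid,FALSE,NA
HDM2BOA-Glc,benzoxazinoid,FALSE,NA
valine,amino acid,FALSE,NA
isoleucine,amino acid,FALSE,NA
proline,amino acid,FALSE,NA
asparagine,amino acid,FALSE,NA
tyrosine,amino acid,FALSE,NA
luteolin-7-glucoside,flavonoid,FALSE,NA
apigenin-7-glucoside,flavonoid,FALSE,NA
syringic acid,phenolic acid,FALSE,NA
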