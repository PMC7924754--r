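name,canonical
DIMBOA-glucoside,DIMBOA-Glc
DIMBOA glucoside,DIMBOA-Glc
HDMBOA-glucoside,HDMBOA-Glc
DIM2BOA-glucoside,DIM2BOA-Glc
HMBOA-glucoside,HMBOA-Glc
D-glucose,glucose
D-fructose,fructose
6-MBOA,MBOA
quercetin-3-O-glucoside,quercetin-3-glucoside
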