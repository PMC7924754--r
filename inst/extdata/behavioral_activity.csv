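compound,activity,source_tag
glucose,feeding stimulant,main text (monosaccharide feeding stimulant)
fructose,feeding stimulant,main text (monosaccharide feeding stimulant)
DIMBOA,host-recognition cue,main text (iron-complex short-distance cue)
DIMBOA-Glc,host-recognition cue,main text (iron-complex short-distance cue)
sucrose,feeding stimulant,literature (disaccharide feeding stimulant)
MBOA,attractant,literature (benzoxazinone attractant)
oleic acid,feeding stimulant,placeholder (supplementary table not redistributable)
linoleic acid,feeding stimulant,placeholder (supplementary table not redistributable)
stearic acid,feeding stimulant,placeholder (supplementary table not redistributable)
palmitic acid,feeding stimulant,placeholder (supplementary table not redistributable)
beta-caryophyllene,attractant,placeholder (supplementary table not redistributable)
ethylene,attractant,placeholder (supplementary table not redistributable)
(E)-beta-farnesene,attractant,placeholder (supplementary table not redistributable)
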