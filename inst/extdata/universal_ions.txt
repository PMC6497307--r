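# Universal inorganic ions found across published biomass objective
# functions (compartment-free BiGG-style identifiers). This file is data,
# not code: replace it to use a different ion inventory.
ca2
cl
cobalt2
cu2
fe2
fe3
k
mg2
mn2
mobd
na1
nh4
ni2
pi
so4
zn2
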