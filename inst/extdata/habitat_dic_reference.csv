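grouping,precision_mode,angiosperm,grass,leaf_litter,moss,rock,water,wood,cover,bare_ground
null,shared,49.7,111.1,193.8,352.6,352.0,111.2,592.4,198.6,352.8
lizard,shared,-17.1,72.1,190.7,346.9,352.4,105.6,479.2,184.8,354.5
lizard,variable,-39.4,74.7,186.2,346.3,345.1,112.5,481.2,187.1,344.7
sex,shared,-16.4,75.5,193.5,350.6,356.5,110.2,477.0,188.0,350.1
sex,variable,-37.5,76.9,187.0,350.7,348.0,118.5,480.5,190.5,339.3
parity,shared,-32.0,73.5,194.6,341.7,356.2,101.6,479.9,175.3,355.6
parity,variable,-54.0,75.1,189.1,342.0,347.8,168.5,482.1,177.2,345.2
parity_sex,shared,-32.4,72.9,194.4,342.4,356.7,102.9,479.7,175.8,355.2
parity_sex,variable,-53.0,75.5,189.0,341.9,347.9,110.2,482.3,177.4,345.7
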