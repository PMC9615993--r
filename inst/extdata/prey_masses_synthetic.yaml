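# Illustrative mean prey body masses (kg) for worked examples and tests.
# These are round literature-style values for the Himalayan prey community,
# NOT measurements from any particular study; relative-biomass output depends
# on them, so substitute your own masses for real analyses.
bharal: 55
livestock: 120
marmot: 5
bird: 1
small_prey: 0.5
musk_deer: 12
himalayan_tahr: 70
himalayan_langur: 15
goral: 30
serow: 90
sambar: 180
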