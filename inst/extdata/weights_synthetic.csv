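# SYNTHETIC weight scheme: plausible proportions of known species per group,
# for examples and tests. Only two entries are published estimates
# (Palearctic terrestrial: realm share 0.106 of terrestrial vertebrates;
# birds 0.433 of terrestrial Palearctic vertebrates); all other values are
# invented. Weights are renormalized per parent on read.
level,system,realm,taxon,weight,known_species
system,terrestrial,,,1,
system,freshwater,,,1,
system,marine,,,1,
realm,terrestrial,Afrotropical,,0.231,
realm,terrestrial,Indo-Pacific,,0.300,
realm,terrestrial,Nearctic,,0.080,
realm,terrestrial,Neotropical,,0.283,
realm,terrestrial,Palearctic,,0.106,
realm,freshwater,Afrotropical,,0.220,
realm,freshwater,Indo-Pacific,,0.280,
realm,freshwater,Nearctic,,0.100,
realm,freshwater,Neotropical,,0.300,
realm,freshwater,Palearctic,,0.100,
realm,marine,Arctic,,0.030,
realm,marine,Atlantic north temperate,,0.120,
realm,marine,Atlantic tropical and subtropical,,0.200,
realm,marine,Pacific north temperate,,0.120,
realm,marine,Tropical and subtropical Indo-Pacific,,0.400,
realm,marine,South temperate and Antarctic,,0.130,
taxon,terrestrial,Afrotropical,Birds,0.350,2200
taxon,terrestrial,Afrotropical,Mammals,0.250,1550
taxon,terrestrial,Afrotropical,Herps,0.400,2480
taxon,terrestrial,Indo-Pacific,Birds,0.380,3100
taxon,terrestrial,Indo-Pacific,Mammals,0.220,1800
taxon,terrestrial,Indo-Pacific,Herps,0.400,3300
taxon,terrestrial,Nearctic,Birds,0.460,725
taxon,terrestrial,Nearctic,Mammals,0.280,440
taxon,terrestrial,Nearctic,Herps,0.260,410
taxon,terrestrial,Neotropical,Birds,0.370,3800
taxon,terrestrial,Neotropical,Mammals,0.160,1640
taxon,terrestrial,Neotropical,Herps,0.470,4800
taxon,terrestrial,Palearctic,Birds,0.433,1330
taxon,terrestrial,Palearctic,Mammals,0.250,770
taxon,terrestrial,Palearctic,Herps,0.317,970
taxon,freshwater,Afrotropical,Birds,0.080,240
taxon,freshwater,Afrotropical,Mammals,0.020,60
taxon,freshwater,Afrotropical,Herps,0.250,740
taxon,freshwater,Afrotropical,Fish,0.650,1940
taxon,freshwater,Indo-Pacific,Birds,0.090,280
taxon,freshwater,Indo-Pacific,Mammals,0.020,70
taxon,freshwater,Indo-Pacific,Herps,0.240,760
taxon,freshwater,Indo-Pacific,Fish,0.650,2050
taxon,freshwater,Nearctic,Birds,0.120,130
taxon,freshwater,Nearctic,Mammals,0.030,30
taxon,freshwater,Nearctic,Herps,0.280,310
taxon,freshwater,Nearctic,Fish,0.570,620
taxon,freshwater,Neotropical,Birds,0.060,280
taxon,freshwater,Neotropical,Mammals,0.010,50
taxon,freshwater,Neotropical,Herps,0.200,920
taxon,freshwater,Neotropical,Fish,0.730,3400
taxon,freshwater,Palearctic,Birds,0.140,180
taxon,freshwater,Palearctic,Mammals,0.030,40
taxon,freshwater,Palearctic,Herps,0.190,240
taxon,freshwater,Palearctic,Fish,0.640,820
taxon,marine,Arctic,Birds,0.130,60
taxon,marine,Arctic,Mammals,0.060,30
taxon,marine,Arctic,Fish,0.810,390
taxon,marine,Atlantic north temperate,Birds,0.070,120
taxon,marine,Atlantic north temperate,Mammals,0.030,50
taxon,marine,Atlantic north temperate,Herps,0.005,6
taxon,marine,Atlantic north temperate,Fish,0.895,1600
taxon,marine,Atlantic tropical and subtropical,Birds,0.040,110
taxon,marine,Atlantic tropical and subtropical,Mammals,0.020,60
taxon,marine,Atlantic tropical and subtropical,Herps,0.003,7
taxon,marine,Atlantic tropical and subtropical,Fish,0.937,2600
taxon,marine,Pacific north temperate,Birds,0.070,140
taxon,marine,Pacific north temperate,Mammals,0.030,60
taxon,marine,Pacific north temperate,Herps,0.001,2
taxon,marine,Pacific north temperate,Fish,0.899,1800
taxon,marine,Tropical and subtropical Indo-Pacific,Birds,0.030,180
taxon,marine,Tropical and subtropical Indo-Pacific,Mammals,0.010,70
taxon,marine,Tropical and subtropical Indo-Pacific,Herps,0.002,12
taxon,marine,Tropical and subtropical Indo-Pacific,Fish,0.958,5600
taxon,marine,South temperate and Antarctic,Birds,0.080,160
taxon,marine,South temperate and Antarctic,Mammals,0.030,60
taxon,marine,South temperate and Antarctic,Herps,0.001,3
taxon,marine,South temperate and Antarctic,Fish,0.889,1900
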