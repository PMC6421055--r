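cultivar	condition	trait	mean	stderr
Hermes	stress	plant_height_cm	60.6	0.9
Hermes	control	plant_height_cm	70.5	0.9
Hermes	stress	fiber_mass_mg	115.6	5.6
Hermes	control	fiber_mass_mg	135.6	8.2
Hermes	stress	seed_pod_count	2.9	0.4
Hermes	control	seed_pod_count	2.8	0.4
TMP1919	stress	plant_height_cm	69.4	1.6
TMP1919	control	plant_height_cm	73.7	1.7
TMP1919	stress	fiber_mass_mg	93.7	3.8
TMP1919	control	fiber_mass_mg	108.9	5.4
TMP1919	stress	seed_pod_count	3.5	0.3
TMP1919	control	seed_pod_count	4.3	0.5
Lira	stress	plant_height_cm	56.2	1.2
Lira	control	plant_height_cm	74.6	1.5
Lira	stress	fiber_mass_mg	54.4	5.8
Lira	control	fiber_mass_mg	131.8	7.4
Lira	stress	seed_pod_count	2.5	0.3
Lira	control	seed_pod_count	4.4	0.3
Orshanskiy	stress	plant_height_cm	61.2	1.4
Orshanskiy	control	plant_height_cm	71.0	0.6
Orshanskiy	stress	fiber_mass_mg	52.8	4.4
Orshanskiy	control	fiber_mass_mg	83.7	8.3
Orshanskiy	stress	seed_pod_count	3.2	0.3
Orshanskiy	control	seed_pod_count	5.4	0.4
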