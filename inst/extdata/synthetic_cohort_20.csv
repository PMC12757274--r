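patient_id,Age,HR,PaO2,dead30,death_day,discharge_day,left_early
MH001,62,72,88,0,,12,0
MH002,81,96,55,0,,25,0
MH003,88,104,38,1,5,,0
MH004,57,68,92,0,,9,0
MH005,74,84,60,0,,14,0
MH006,69,90,,0,,11,0
MH007,79,78,71,0,,18,0
MH008,66,82,83,0,,10,0
MH009,91,110,42,1,12,,0
MH010,48,64,95,0,,7,0
MH011,72,88,67,0,,16,1
MH012,85,95,58,0,,29,0
MH013,63,76,79,0,,13,0
MH014,77,92,,0,,21,0
MH015,70,73,86,0,,8,0
MH016,83,89,52,0,,,0
MH017,95,118,36,1,28,,0
MH018,54,70,90,0,,6,0
MH019,75,85,59,0,,19,0
MH020,68,80,74,0,,15,0
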