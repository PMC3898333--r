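islet_id,d1_um,d2_um,d3_um,d4_um
islet_01,62,,,
islet_02,75,81,,
islet_03,88,,,
islet_04,104,96,100,
islet_05,118,,,
islet_06,131,139,,
islet_07,150,,,
islet_08,163,171,167,
islet_09,188,,,
islet_10,205,215,,
islet_11,238,,,
islet_12,262,270,,
islet_13,301,,,
islet_14,322,330,326,318
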