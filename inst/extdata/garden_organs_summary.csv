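element,site_id,organ,mean_mg_kg,sd_mg_kg
Cd,no.1,fibrous_root,0.62,0.04
Cd,no.1,taproot,0.30,0.01
Cd,no.1,main_stem,0.33,0.01
Cd,no.1,lateral_stem,0.29,0.01
Cd,no.1,old_leaf,0.05,0.00
Cd,no.1,young_leaf,0.02,0.00
Cd,no.2,fibrous_root,1.95,0.07
Cd,no.2,taproot,0.34,0.03
Cd,no.2,main_stem,0.27,0.02
Cd,no.2,lateral_stem,0.20,0.01
Cd,no.2,old_leaf,0.05,0.00
Cd,no.2,young_leaf,0.02,0.00
Cd,no.3,fibrous_root,1.97,0.06
Cd,no.3,taproot,0.19,0.01
Cd,no.3,main_stem,0.41,0.02
Cd,no.3,lateral_stem,0.21,0.01
Cd,no.3,old_leaf,0.07,0.00
Cd,no.3,young_leaf,0.02,0.00
Cd,no.4,fibrous_root,0.80,0.01
Cd,no.4,taproot,0.29,0.00
Cd,no.4,main_stem,0.40,0.00
Cd,no.4,lateral_stem,0.28,0.01
Cd,no.4,old_leaf,0.06,0.00
Cd,no.4,young_leaf,0.01,0.00
Cd,no.5,fibrous_root,1.06,0.02
Cd,no.5,taproot,0.32,0.01
Cd,no.5,main_stem,0.20,0.01
Cd,no.5,lateral_stem,0.17,0.01
Cd,no.5,old_leaf,0.06,0.00
Cd,no.5,young_leaf,0.02,0.00
Cd,no.6,fibrous_root,0.94,0.03
Cd,no.6,taproot,0.18,0.00
Cd,no.6,main_stem,0.22,0.00
Cd,no.6,lateral_stem,0.39,0.01
Cd,no.6,old_leaf,0.09,0.01
Cd,no.6,young_leaf,0.04,0.00
Cd,no.7,fibrous_root,1.29,0.02
Cd,no.7,taproot,0.40,0.01
Cd,no.7,main_stem,0.20,0.02
Cd,no.7,lateral_stem,0.35,0.02
Cd,no.7,old_leaf,0.10,0.00
Cd,no.7,young_leaf,0.02,0.00
Cd,no.8,fibrous_root,1.51,0.06
Cd,no.8,taproot,0.24,0.01
Cd,no.8,main_stem,0.20,0.01
Cd,no.8,lateral_stem,0.39,0.00
Cd,no.8,old_leaf,0.09,0.00
Cd,no.8,young_leaf,0.02,0.00
Cd,no.9,fibrous_root,1.36,0.03
Cd,no.9,taproot,0.31,0.01
Cd,no.9,main_stem,0.31,0.01
Cd,no.9,lateral_stem,0.30,0.02
Cd,no.9,old_leaf,0.08,0.00
Cd,no.9,young_leaf,0.02,0.00
Cd,no.10,fibrous_root,1.22,0.05
Cd,no.10,taproot,0.39,0.03
Cd,no.10,main_stem,0.30,0.04
Cd,no.10,lateral_stem,0.28,0.01
Cd,no.10,old_leaf,0.05,0.00
Cd,no.10,young_leaf,0.02,0.00
Cd,no.11,fibrous_root,0.76,0.01
Cd,no.11,taproot,0.36,0.02
Cd,no.11,main_stem,0.22,0.02
Cd,no.11,lateral_stem,0.18,0.01
Cd,no.11,old_leaf,0.07,0.00
Cd,no.11,young_leaf,0.01,0.00
Cd,no.12,fibrous_root,0.51,0.04
Cd,no.12,taproot,0.18,0.00
Cd,no.12,main_stem,0.13,0.02
Cd,no.12,lateral_stem,0.26,0.01
Cd,no.12,old_leaf,0.06,0.00
Cd,no.12,young_leaf,0.01,0.00
Se,no.1,fibrous_root,0.69,0.18
Se,no.1,taproot,0.40,0.04
Se,no.1,main_stem,0.57,0.09
Se,no.1,lateral_stem,0.22,0.01
Se,no.1,old_leaf,0.41,0.03
Se,no.1,young_leaf,0.45,0.04
Se,no.2,fibrous_root,1.14,0.12
Se,no.2,taproot,0.36,0.01
Se,no.2,main_stem,0.45,0.02
Se,no.2,lateral_stem,0.13,0.02
Se,no.2,old_leaf,0.72,0.02
Se,no.2,young_leaf,0.11,0.00
Se,no.3,fibrous_root,1.00,0.14
Se,no.3,taproot,0.81,0.03
Se,no.3,main_stem,0.60,0.02
Se,no.3,lateral_stem,0.21,0.00
Se,no.3,old_leaf,0.46,0.04
Se,no.3,young_leaf,0.10,0.01
Se,no.4,fibrous_root,2.26,0.02
Se,no.4,taproot,1.68,0.05
Se,no.4,main_stem,1.04,0.06
Se,no.4,lateral_stem,0.22,0.00
Se,no.4,old_leaf,0.55,0.09
Se,no.4,young_leaf,0.10,0.01
Se,no.5,fibrous_root,0.87,0.05
Se,no.5,taproot,0.48,0.01
Se,no.5,main_stem,0.62,0.03
Se,no.5,lateral_stem,0.31,0.02
Se,no.5,old_leaf,0.33,0.04
Se,no.5,young_leaf,0.14,0.02
Se,no.6,fibrous_root,3.85,0.07
Se,no.6,taproot,2.29,0.18
Se,no.6,main_stem,0.63,0.04
Se,no.6,lateral_stem,0.81,0.10
Se,no.6,old_leaf,2.46,0.26
Se,no.6,young_leaf,1.38,0.08
Se,no.7,fibrous_root,2.65,0.08
Se,no.7,taproot,1.13,0.06
Se,no.7,main_stem,0.77,0.04
Se,no.7,lateral_stem,0.59,0.03
Se,no.7,old_leaf,1.28,0.11
Se,no.7,young_leaf,0.99,0.07
Se,no.8,fibrous_root,1.39,0.10
Se,no.8,taproot,0.64,0.02
Se,no.8,main_stem,0.46,0.04
Se,no.8,lateral_stem,0.59,0.04
Se,no.8,old_leaf,1.06,0.15
Se,no.8,young_leaf,0.14,0.06
Se,no.9,fibrous_root,2.64,0.18
Se,no.9,taproot,1.20,0.10
Se,no.9,main_stem,0.78,0.04
Se,no.9,lateral_stem,0.51,0.03
Se,no.9,old_leaf,0.59,0.06
Se,no.9,young_leaf,0.69,0.04
Se,no.10,fibrous_root,1.99,0.09
Se,no.10,taproot,0.66,0.02
Se,no.10,main_stem,0.45,0.02
Se,no.10,lateral_stem,0.48,0.07
Se,no.10,old_leaf,0.59,0.05
Se,no.10,young_leaf,0.20,0.02
Se,no.11,fibrous_root,0.67,0.15
Se,no.11,taproot,0.42,0.05
Se,no.11,main_stem,0.55,0.03
Se,no.11,lateral_stem,0.14,0.03
Se,no.11,old_leaf,0.48,0.03
Se,no.11,young_leaf,0.23,0.01
Se,no.12,fibrous_root,1.33,0.20
Se,no.12,taproot,0.52,0.05
Se,no.12,main_stem,0.68,0.05
Se,no.12,lateral_stem,0.62,0.06
Se,no.12,old_leaf,0.72,0.01
Se,no.12,young_leaf,0.09,0.00
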