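"species","family","suborder","population_id","male_mass_g","female_mass_g","male_scl_cm","female_scl_cm","basis","captive","source_id"
"sp_001","fam_01","Cryptodira","sp_001_p01",3574,578.9,30.06,15.02,"mean",FALSE,"synthetic"
"sp_002","fam_02","Cryptodira","sp_002_p01",57740,6169,71.76,33.36,"mean",FALSE,"synthetic"
"sp_002","fam_02","Cryptodira","sp_002_p02",66280,6103,74.56,36.76,"mean",FALSE,"synthetic"
"sp_002","fam_02","Cryptodira","sp_002_p03",70660,5565,84.34,36.45,"mean",FALSE,"synthetic"
"sp_003","fam_01","Cryptodira","sp_003_p01",3478,685.3,27.26,17.9,"mean",FALSE,"synthetic"
"sp_004","fam_03","Cryptodira","sp_004_p01",2985,655.1,27.86,16.62,"mean",FALSE,"synthetic"
"sp_004","fam_03","Cryptodira","sp_004_p02",2784,666,31.64,16.62,"mean",FALSE,"synthetic"
"sp_004","fam_03","Cryptodira","sp_004_p03",2809,612.4,29.16,16.21,"mean",FALSE,"synthetic"
"sp_005","fam_01","Cryptodira","sp_005_p01",3093,475.4,29.27,16.83,"mean",FALSE,"synthetic"
"sp_005","fam_01","Cryptodira","sp_005_p02",2773,514.1,27.92,17.95,"mean",FALSE,"synthetic"
"sp_005","fam_01","Cryptodira","sp_005_p03",2932,455.3,25.32,15.3,"mean",FALSE,"synthetic"
"sp_006","fam_03","Cryptodira","sp_006_p01",1289,241.8,19.81,12.13,"mean",FALSE,"synthetic"
"sp_007","fam_04","Cryptodira","sp_007_p01",8442,1301,39.12,19.95,"mean",FALSE,"synthetic"
"sp_007","fam_04","Cryptodira","sp_007_p02",8722,1223,37.14,23.92,"mean",FALSE,"synthetic"
"sp_008","fam_02","Cryptodira","sp_008_p01",86190,6897,88.64,40.61,"mean",FALSE,"synthetic"
"sp_009","fam_05","Pleurodira","sp_009_p01",1132,468.3,22.17,15.18,"mean",FALSE,"synthetic"
"sp_009","fam_05","Pleurodira","sp_009_p02",1407,474.2,21.28,15.65,"mean",FALSE,"synthetic"
"sp_009","fam_05","Pleurodira","sp_009_p03",1428,563.3,24.01,14.79,"mean",FALSE,"synthetic"
"sp_010","fam_02","Cryptodira","sp_010_p01",39130,3953,75.37,29.58,"mean",FALSE,"synthetic"
"sp_011","fam_01","Cryptodira","sp_011_p01",3691,520.9,28.76,14.23,"mean",FALSE,"synthetic"
"sp_012","fam_06","Cryptodira","sp_012_p01",33700,2894,66.98,27.75,"mean",FALSE,"synthetic"
"sp_012","fam_06","Cryptodira","sp_012_p02",32130,2756,64.17,27.03,"mean",FALSE,"synthetic"
"sp_012","fam_06","Cryptodira","sp_012_p03",30300,2489,62.87,28.52,"mean",FALSE,"synthetic"
"sp_013","fam_06","Cryptodira","sp_013_p01",24450,2317,68.2,25.17,"mean",FALSE,"synthetic"
"sp_013","fam_06","Cryptodira","sp_013_p02",25130,2238,52.38,24.73,"mean",FALSE,"synthetic"
"sp_014","fam_02","Cryptodira","sp_014_p01",25430,2998,54.37,28.85,"mean",FALSE,"synthetic"
"sp_014","fam_02","Cryptodira","sp_014_p02",27370,3001,64,26.92,"mean",FALSE,"synthetic"
"sp_015","fam_03","Cryptodira","sp_015_p01",2827,462,28.35,14.96,"mean",FALSE,"synthetic"
"sp_015","fam_03","Cryptodira","sp_015_p02",3579,452.1,28.19,15.83,"mean",FALSE,"synthetic"
"sp_015","fam_03","Cryptodira","sp_015_p03",3111,418.9,27.37,15.24,"mean",FALSE,"synthetic"
"sp_016","fam_02","Cryptodira","sp_016_p01",32320,2831,58.51,26.09,"mean",FALSE,"synthetic"
"sp_016","fam_02","Cryptodira","sp_016_p02",30010,2691,59.86,29.23,"mean",FALSE,"synthetic"
"sp_017","fam_01","Cryptodira","sp_017_p01",3260,664.2,30.22,17,"mean",FALSE,"synthetic"
"sp_018","fam_01","Cryptodira","sp_018_p01",2565,627.9,27.19,16.74,"mean",FALSE,"synthetic"
"sp_018","fam_01","Cryptodira","sp_018_p02",2840,580.1,28.99,18.03,"mean",FALSE,"synthetic"
"sp_019","fam_05","Pleurodira","sp_019_p01",2763,905.7,30.3,21.23,"mean",FALSE,"synthetic"
"sp_019","fam_05","Pleurodira","sp_019_p02",2656,662.5,25.02,16.73,"mean",FALSE,"synthetic"
"sp_020","fam_03","Cryptodira","sp_020_p01",5918,1416,34.28,21.31,"mean",FALSE,"synthetic"
"sp_021","fam_05","Pleurodira","sp_021_p01",6694,1819,34.89,25.29,"mean",FALSE,"synthetic"
"sp_021","fam_05","Pleurodira","sp_021_p02",6112,1514,34.25,24.68,"mean",FALSE,"synthetic"
"sp_022","fam_03","Cryptodira","sp_022_p01",5571,1519,36,21.9,"mean",FALSE,"synthetic"
"sp_022","fam_03","Cryptodira","sp_022_p02",5571,1512,35.5,22.68,"mean",FALSE,"synthetic"
"sp_022","fam_03","Cryptodira","sp_022_p03",5982,1463,38.46,25.07,"mean",FALSE,"synthetic"
"sp_023","fam_02","Cryptodira","sp_023_p01",87240,5859,85.51,37.4,"mean",FALSE,"synthetic"
"sp_023","fam_02","Cryptodira","sp_023_p02",80450,6086,90.96,39.69,"mean",FALSE,"synthetic"
"sp_024","fam_03","Cryptodira","sp_024_p01",2708,458,27.72,15.11,"mean",FALSE,"synthetic"
"sp_024","fam_03","Cryptodira","sp_024_p02",2796,547.2,28.67,16.54,"mean",FALSE,"synthetic"
"sp_024","fam_03","Cryptodira","sp_024_p03",2610,473.8,23.36,14.23,"mean",FALSE,"synthetic"
"sp_025","fam_05","Pleurodira","sp_025_p01",5944,2077,37.03,24.26,"mean",FALSE,"synthetic"
"sp_025","fam_05","Pleurodira","sp_025_p02",7426,1971,37,25.7,"mean",FALSE,"synthetic"
"sp_025","fam_05","Pleurodira","sp_025_p03",7632,2114,39.7,24.76,"mean",FALSE,"synthetic"
"sp_026","fam_06","Cryptodira","sp_026_p01",34540,2207,67.11,24.48,"mean",FALSE,"synthetic"
"sp_026","fam_06","Cryptodira","sp_026_p02",31680,2616,57.52,27.9,"mean",FALSE,"synthetic"
"sp_027","fam_01","Cryptodira","sp_027_p01",3446,843.4,29.37,18.72,"mean",FALSE,"synthetic"
"sp_027","fam_01","Cryptodira","sp_027_p02",3773,703.7,35.78,18.87,"mean",FALSE,"synthetic"
"sp_027","fam_01","Cryptodira","sp_027_p03",4532,730.1,30.75,16.38,"mean",FALSE,"synthetic"
"sp_028","fam_01","Cryptodira","sp_028_p01",2797,421.5,26.58,14.53,"mean",FALSE,"synthetic"
"sp_028","fam_01","Cryptodira","sp_028_p02",3104,496.3,27.35,15.92,"mean",FALSE,"synthetic"
"sp_029","fam_03","Cryptodira","sp_029_p01",2490,628.1,29.63,17.79,"mean",FALSE,"synthetic"
"sp_030","fam_04","Cryptodira","sp_030_p01",66710,5985,70.96,39.73,"mean",FALSE,"synthetic"
"sp_031","fam_03","Cryptodira","sp_031_p01",2948,735,25.91,18.01,"mean",FALSE,"synthetic"
"sp_031","fam_03","Cryptodira","sp_031_p02",3010,667.6,28.9,16.22,"mean",FALSE,"synthetic"
"sp_031","fam_03","Cryptodira","sp_031_p03",2967,617.4,28.57,16.65,"mean",FALSE,"synthetic"
"sp_032","fam_02","Cryptodira","sp_032_p01",28680,3241,55.88,28.31,"mean",FALSE,"synthetic"
"sp_032","fam_02","Cryptodira","sp_032_p02",32930,3026,69.26,29.31,"mean",FALSE,"synthetic"
"sp_032","fam_02","Cryptodira","sp_032_p03",34830,2551,59.25,28.04,"mean",FALSE,"synthetic"
"sp_033","fam_03","Cryptodira","sp_033_p01",541.2,144.4,15.02,10.62,"mean",FALSE,"synthetic"
"sp_033","fam_03","Cryptodira","sp_033_p02",631.5,148.7,18.88,9.674,"mean",FALSE,"synthetic"
"sp_033","fam_03","Cryptodira","sp_033_p03",616,183.3,17.1,11.19,"mean",FALSE,"synthetic"
"sp_034","fam_02","Cryptodira","sp_034_p01",64400,5265,77.88,38.43,"mean",FALSE,"synthetic"
"sp_035","fam_05","Pleurodira","sp_035_p01",7201,1941,43.58,24.32,"mean",FALSE,"synthetic"
"sp_035","fam_05","Pleurodira","sp_035_p02",7545,1766,36.23,23.99,"mean",FALSE,"synthetic"
"sp_035","fam_05","Pleurodira","sp_035_p03",6469,1911,36.99,26.42,"mean",FALSE,"synthetic"
"sp_036","fam_01","Cryptodira","sp_036_p01",3685,469.2,29.46,14.27,"mean",FALSE,"synthetic"
"sp_036","fam_01","Cryptodira","sp_036_p02",3040,480.3,31.48,14.76,"mean",FALSE,"synthetic"
"sp_037","fam_05","Pleurodira","sp_037_p01",4958,1328,33.2,24.79,"mean",FALSE,"synthetic"
"sp_038","fam_01","Cryptodira","sp_038_p01",1548,271.9,23.12,12.29,"mean",FALSE,"synthetic"
"sp_038","fam_01","Cryptodira","sp_038_p02",1603,303.3,21.61,12.64,"mean",FALSE,"synthetic"
"sp_038","fam_01","Cryptodira","sp_038_p03",1600,293.7,23.55,13.44,"mean",FALSE,"synthetic"
"sp_039","fam_02","Cryptodira","sp_039_p01",4750,830.5,31.26,19.64,"mean",FALSE,"synthetic"
"sp_039","fam_02","Cryptodira","sp_039_p02",4738,787.8,37.28,17.95,"mean",FALSE,"synthetic"
"sp_040","fam_01","Cryptodira","sp_040_p01",1278,242.8,20.76,12.1,"mean",FALSE,"synthetic"
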