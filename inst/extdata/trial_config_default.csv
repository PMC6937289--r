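# Default synthetic-trial configuration: cell means and standard errors
# (over 4 replicate plots) for a 2-variety x 2-N-management split-plot
# rice trial. Edit freely; empty cells mean the measurement is not taken
# for that internode.
variety,treatment,internode,mean_length_cm,se_length_cm,mean_diameter_mm,se_diameter_mm,mean_wall_mm,se_wall_mm,mean_dry_mg,se_dry_mg,mean_break_N,se_break_N,mean_E_GPa,se_E_GPa,mean_BM_gfcm,se_BM_gfcm,mean_plant_height_cm,se_plant_height_cm
YJRZ,FFP,1,3.4,0.1,5.89,0.14,0.93,0.04,65.6,2.9,,,,,,,104.0,0.9
YJRZ,FFP,2,8.1,0.2,5.45,0.14,0.67,0.03,93.2,3.6,9.1,0.8,0.57,0.09,1155.3,102.7,104.0,0.9
YJRZ,FFP,3,16.9,0.4,4.85,0.14,0.54,0.02,126.1,6.7,6.0,0.6,1.9,0.14,760.0,76.2,104.0,0.9
YJRZ,FFP,4,18.4,0.5,,,,,,,,,,,,,104.0,0.9
YJRZ,FFP,5,36.8,0.1,,,,,,,,,,,,,104.0,0.9
YJRZ,OPT,1,2.8,0.2,6.18,0.18,1.04,0.02,69.4,4.5,,,,,,,110.1,3.3
YJRZ,OPT,2,6.8,0.5,6.10,0.19,0.80,0.02,110.5,7.6,11.7,0.8,0.33,0.04,1490.3,101.5,110.1,3.3
YJRZ,OPT,3,13.2,0.6,5.49,0.15,0.67,0.03,145.6,5.9,9.3,0.3,1.26,0.05,1186.5,32.0,110.1,3.3
YJRZ,OPT,4,19.8,0.6,,,,,,,,,,,,,110.1,3.3
YJRZ,OPT,5,39.6,0.6,,,,,,,,,,,,,110.1,3.3
YZ889,FFP,1,3.6,0.3,5.55,0.10,0.92,0.01,55.9,4.6,,,,,,,102.9,1.9
YZ889,FFP,2,8.7,0.3,5.21,0.12,0.65,0.02,103.8,7.6,7.9,0.6,0.64,0.04,1005.0,70.6,102.9,1.9
YZ889,FFP,3,17.8,0.4,4.68,0.16,0.50,0.01,126.3,9.4,5.7,0.5,2.31,0.32,728.8,58.0,102.9,1.9
YZ889,FFP,4,16.3,0.5,,,,,,,,,,,,,102.9,1.9
YZ889,FFP,5,34.6,0.1,,,,,,,,,,,,,102.9,1.9
YZ889,OPT,1,3.4,0.2,5.93,0.06,1.03,0.02,70.3,6.5,,,,,,,108.8,2.1
YZ889,OPT,2,7.1,0.5,5.84,0.08,0.79,0.02,114.4,10.2,12.1,0.4,0.56,0.11,1548.4,54.2,108.8,2.1
YZ889,OPT,3,14.2,0.5,5.56,0.07,0.61,0.01,164.1,8.0,9.3,0.3,1.48,0.16,1184.3,36.6,108.8,2.1
YZ889,OPT,4,18.0,0.7,,,,,,,,,,,,,108.8,2.1
YZ889,OPT,5,38.9,0.4,,,,,,,,,,,,,108.8,2.1
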