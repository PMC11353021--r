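sex,age_band,pct_cases,quantity,median,p25,p75,min,max
M,21-30,12,CED_mSv,185.75,NA,NA,156.70,214.80
M,21-30,12,bladder,26.60,24.17,29.02,NA,NA
M,21-30,12,colon,38.29,30.94,45.63,NA,NA
M,21-30,12,liver,45.11,34.57,55.64,NA,NA
M,21-30,12,lung,6.05,4.50,7.59,NA,NA
M,21-30,12,stomach,29.41,22.59,36.23,NA,NA
M,21-30,12,thyroid,0.80,0.67,1.08,NA,NA
M,21-30,12,prostate,29.56,26.91,32.20,NA,NA
M,31-40,24,CED_mSv,119.20,NA,NA,102.90,149.90
M,31-40,24,bladder,30.05,7.57,37.13,NA,NA
M,31-40,24,colon,15.93,8.64,47.35,NA,NA
M,31-40,24,liver,16.24,9.48,49.36,NA,NA
M,31-40,24,lung,3.37,2.37,7.89,NA,NA
M,31-40,24,stomach,10.69,6.51,32.40,NA,NA
M,31-40,24,thyroid,1.14,0.37,22.90,NA,NA
M,31-40,24,prostate,16.34,8.45,37.34,NA,NA
M,41-50,12,CED_mSv,180.55,NA,NA,129.40,231.70
M,41-50,12,bladder,68.43,51.12,85.74,NA,NA
M,41-50,12,colon,75.38,56.33,94.42,NA,NA
M,41-50,12,liver,77.02,57.71,96.33,NA,NA
M,41-50,12,lung,10.51,8.65,12.36,NA,NA
M,41-50,12,stomach,50.91,38.35,63.48,NA,NA
M,41-50,12,thyroid,3.64,2.91,4.36,NA,NA
M,41-50,12,prostate,75.66,56.30,95.01,NA,NA
M,51-60,18,CED_mSv,164.90,NA,NA,103.30,223.00
M,51-60,18,bladder,10.74,3.36,19.51,NA,NA
M,51-60,18,colon,18.19,5.33,21.05,NA,NA
M,51-60,18,liver,21.45,7.03,35.06,NA,NA
M,51-60,18,lung,5.37,2.87,25.67,NA,NA
M,51-60,18,stomach,14.12,5.80,29.60,NA,NA
M,51-60,18,thyroid,3.48,1.26,4.28,NA,NA
M,51-60,18,prostate,8.45,2.96,21.87,NA,NA
M,61-70,18,CED_mSv,132.00,NA,NA,112.30,142.90
M,61-70,18,bladder,36.87,20.83,41.06,NA,NA
M,61-70,18,colon,68.80,25.32,85.69,NA,NA
M,61-70,18,liver,98.88,27.30,134.73,NA,NA
M,61-70,18,lung,73.55,3.32,102.95,NA,NA
M,61-70,18,stomach,81.39,17.92,110.54,NA,NA
M,61-70,18,thyroid,11.46,0.50,13.80,NA,NA
M,61-70,18,prostate,22.21,21.21,34.39,NA,NA
M,71-80,12,CED_mSv,161.40,NA,NA,101.90,220.90
M,71-80,12,bladder,24.95,21.58,28.33,NA,NA
M,71-80,12,colon,33.83,26.88,40.77,NA,NA
M,71-80,12,liver,47.01,34.05,59.96,NA,NA
M,71-80,12,lung,24.36,14.00,37.41,NA,NA
M,71-80,12,stomach,35.48,24.63,46.34,NA,NA
M,71-80,12,thyroid,11.44,11.32,11.57,NA,NA
M,71-80,12,prostate,25.10,23.02,27.17,NA,NA
M,81-90,6,CED_mSv,121.90,NA,NA,NA,NA
M,81-90,6,bladder,36.43,NA,NA,NA,NA
M,81-90,6,colon,49.99,NA,NA,NA,NA
M,81-90,6,liver,52.73,NA,NA,NA,NA
M,81-90,6,lung,6.65,NA,NA,NA,NA
M,81-90,6,stomach,34.69,NA,NA,NA,NA
M,81-90,6,thyroid,2.57,NA,NA,NA,NA
M,81-90,6,prostate,36.94,NA,NA,NA,NA
F,21-30,20,CED_mSv,122.50,NA,NA,NA,NA
F,21-30,20,bladder,31.38,NA,NA,NA,NA
F,21-30,20,breast,0.81,NA,NA,NA,NA
F,21-30,20,colon,16.91,NA,NA,NA,NA
F,21-30,20,liver,5.59,NA,NA,NA,NA
F,21-30,20,lung,1.02,NA,NA,NA,NA
F,21-30,20,stomach,3.87,NA,NA,NA,NA
F,21-30,20,thyroid,0.28,NA,NA,NA,NA
F,21-30,20,uterus,35.83,NA,NA,NA,NA
F,31-40,20,CED_mSv,108.10,NA,NA,NA,NA
F,31-40,20,bladder,21.10,NA,NA,NA,NA
F,31-40,20,breast,1.54,NA,NA,NA,NA
F,31-40,20,colon,24.87,NA,NA,NA,NA
F,31-40,20,liver,25.54,NA,NA,NA,NA
F,31-40,20,lung,3.21,NA,NA,NA,NA
F,31-40,20,stomach,17.57,NA,NA,NA,NA
F,31-40,20,thyroid,0.53,NA,NA,NA,NA
F,31-40,20,uterus,18.75,NA,NA,NA,NA
F,51-60,20,CED_mSv,103.30,NA,NA,NA,NA
F,51-60,20,bladder,189.20,NA,NA,NA,NA
F,51-60,20,breast,13.72,NA,NA,NA,NA
F,51-60,20,colon,222.48,NA,NA,NA,NA
F,51-60,20,liver,232.44,NA,NA,NA,NA
F,51-60,20,lung,28.92,NA,NA,NA,NA
F,51-60,20,stomach,158.56,NA,NA,NA,NA
F,51-60,20,thyroid,4.56,NA,NA,NA,NA
F,51-60,20,uterus,164.62,NA,NA,NA,NA
F,61-70,20,CED_mSv,190.10,NA,NA,NA,NA
F,61-70,20,bladder,24.44,NA,NA,NA,NA
F,61-70,20,breast,19.31,NA,NA,NA,NA
F,61-70,20,colon,37.26,NA,NA,NA,NA
F,61-70,20,liver,47.78,NA,NA,NA,NA
F,61-70,20,lung,22.61,NA,NA,NA,NA
F,61-70,20,stomach,36.41,NA,NA,NA,NA
F,61-70,20,thyroid,10.42,NA,NA,NA,NA
F,61-70,20,uterus,25.95,NA,NA,NA,NA
F,71-80,20,CED_mSv,112.30,NA,NA,NA,NA
F,71-80,20,bladder,26.39,NA,NA,NA,NA
F,71-80,20,breast,57.58,NA,NA,NA,NA
F,71-80,20,colon,56.23,NA,NA,NA,NA
F,71-80,20,liver,72.89,NA,NA,NA,NA
F,71-80,20,lung,62.61,NA,NA,NA,NA
F,71-80,20,stomach,63.88,NA,NA,NA,NA
F,71-80,20,thyroid,9.87,NA,NA,NA,NA
F,71-80,20,uterus,41.73,NA,NA,NA,NA
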