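block,variable,cn_mean,cn_sd,mci_mean,mci_sd,t_printed,significant
demographics,Age,72.17,5.72,74.13,6.27,-2.747,TRUE
demographics,EDUYR,10.58,4.37,9.40,4.78,2.165,TRUE
neuropsych,MMSE,27.62,1.91,26.04,2.54,6.192,TRUE
neuropsych,Attention,9.49,2.21,8.38,1.90,4.292,TRUE
neuropsych,Language,0.21,0.25,-0.13,0.49,8.251,TRUE
neuropsych,Visuospatial,0.52,0.37,0.00,0.88,7.541,TRUE
neuropsych,Memory,0.32,0.59,-0.55,0.67,11.621,TRUE
neuropsych,Frontal,0.22,0.55,-0.42,0.71,8.940,TRUE
erp,FAL,390.88,53.42,392.21,49.52,-0.21,FALSE
erp,AUC,245.88,297.27,321.52,281.66,-2.13,TRUE
erp,AMP,6.58,7.12,7.99,6.80,-1.65,FALSE
erp,LAT,388.35,62.41,393.35,63.52,-0.66,FALSE
erp,T1,247.21,101.51,218.32,96.81,2.38,TRUE
erp,T2,484.75,98.34,503.66,91.35,-1.62,FALSE
erp,FALT1,143.67,79.94,173.89,82.99,-3.08,TRUE
erp,T2FAL,93.87,65.18,111.45,62.10,-2.25,TRUE
erp,T2T1,237.54,119.41,285.35,119.62,-3.30,TRUE
behavioral,NI,1.52,2.19,2.71,3.96,-3.49,TRUE
behavioral,ER,0.04,0.05,0.09,0.12,-5.82,TRUE
behavioral,ACC,98.80,2.23,96.30,7.02,4.92,TRUE
behavioral,WER,0.01,0.01,0.02,0.04,-5.47,TRUE
behavioral,RT,347.80,64.15,348.80,75.60,-0.12,FALSE
behavioral,RTSD,92.76,39.96,106.89,40.72,-2.90,TRUE
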