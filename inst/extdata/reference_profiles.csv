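component,unit,mean,sd,cv_percent,p5,p10,p25,p50,p75,p90,p95,variance_ratio,pct_zero,spearman_r,spearman_sig
energy,kcal,1631.76,468.63,28.72,1028.69,1121.7,1332.3,1562.52,1881.97,2181.79,2450.58,1.35,0,NA,NA
protein,g,68.48,22.07,32.23,40.19,45.21,53.8,64.65,79.36,94.01,105.74,1.43,0,NA,NA
fat,g,38.86,16.87,43.42,15.46,19.35,26.04,37.15,48.69,59.78,69.16,1.98,0,NA,NA
cho,g,252.91,93.94,37.14,140.73,154.93,186.27,231.04,300.47,383.04,431.23,0.92,0,NA,NA
cholesterol,mg,383.49,189.64,49.45,117.42,167.05,266.38,363.28,483.74,607.24,687.07,3.09,8.99,0.3,FALSE
calcium,mg,439.03,181.43,41.32,229.35,263.68,323.06,412.32,512.41,639.56,747.78,2.09,0,NA,NA
iron,mg,20.15,6.17,30.63,12.2,13.62,16.01,19.1,23.32,27.51,31.01,2.44,0,NA,NA
vitamin_a,ugRAE,424.09,211.53,49.88,198.04,232.12,288.46,378.39,509.77,679.63,774.51,4.26,0.07,NA,NA
vitamin_e,mg,11.99,4.06,33.87,6.75,7.54,9.14,11.41,13.99,17.17,19.39,3.62,0,NA,NA
vitamin_b2,mg,0.83,0.26,31.58,0.49,0.55,0.67,0.81,0.96,1.11,1.24,1.76,0,NA,NA
rice,g,69.18,54.26,78.44,15.49,21.78,34.15,56.47,90.63,125.89,159.97,1.25,26.22,-0.37,FALSE
eggs,g,43.66,21.96,50.29,13.26,18.7,29.63,41.66,55.53,68.28,78.43,3.94,41.82,0.12,FALSE
beans,g,51.37,31.65,61.6,9.21,14.84,27.58,48.01,70.02,92.29,105.86,4.67,30.16,0.61,TRUE
vegetables,g,225.69,102.43,45.39,95.64,117.25,151.59,207.51,278.14,349.35,416.25,2.33,3.98,NA,NA
meats,g,147.44,131.04,88.88,4.18,9.18,37.8,120.87,229.26,313.97,381.25,0.83,26.57,0.89,TRUE
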