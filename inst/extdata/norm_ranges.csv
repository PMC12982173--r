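parameter,M,sigma,extreme_low,extreme_high,level2_group,level3_block,source
"Amplitude P-wave (μV) (lead II)",150,50,-100,450,"P wave","Myocardial condition","literature"
"Amplitude Q-wave (μV) (lead II)",-80,40,-450,100,"QRS complex","Myocardial condition","literature"
"Amplitude R-wave (μV) (lead II)",1000,300,100,3000,"QRS complex","Myocardial condition","literature"
"Amplitude S-wave (μV) (lead II)",-150,80,-900,100,"QRS complex","Myocardial condition","literature"
"Amplitude T-wave (μV) (lead II)",300,100,-250,950,"Repolarisation","Myocardial condition","literature"
"J-point dislocation (μV) (lead II)",0,25,-220,220,"Repolarisation","Myocardial condition","literature"
"Duration of P-wave (sec)",0.1,0.02,0.02,0.24,"ECG intervals","Myocardial condition","literature"
"Duration PQ (sec)",0.16,0.02,0.07,0.32,"ECG intervals","Myocardial condition","literature"
"QRS duration (sec)",0.09,0.015,0.03,0.2,"ECG intervals","Myocardial condition","literature"
"QTcF duration (sec)",0.4,0.03,0.28,0.56,"ECG intervals","Myocardial condition","literature"
"Macruz index P/(PQ-P)",1.6,0.5,0.05,4.8,"ECG intervals","Myocardial condition","literature"
"SDNN, ms",50,20,2,220,"HRV time domain","Regulation","normative-database"
"RMSSD, ms",42,18,2,200,"HRV time domain","Regulation","normative-database"
"SDSD, ms",42,18,2,200,"HRV time domain","Regulation","normative-database"
"PNN50, %",20,12,-5,85,"HRV time domain","Regulation","normative-database"
"LF",1170,600,15,5200,"HRV frequency domain","Regulation","normative-database"
"HF",975,500,8,5100,"HRV frequency domain","Regulation","normative-database"
"LF/HF ratio",1.5,0.8,0.04,11,"HRV frequency domain","Regulation","normative-database"
"Mean RR (ms)",900,150,280,2100,"Rhythm regularity","Arrhythmia","normative-database"
"Heart rate (bpm)",68,10,24,225,"Rhythm regularity","Arrhythmia","normative-database"
"Baevsky stress index",120,60,2,950,"Stress indices","Psycho-emotional status","normative-database"
"McCraty psycho-emotional index",1.0,0.5,0.005,8.5,"Coherence indices","Psycho-emotional status","normative-database"
"Mashin psycho-emotional index",0.4,0.25,-1.2,1.1,"Coherence indices","Psycho-emotional status","normative-database"
"Detrended Fluctuation Analysis (DFA) of HRV",1.0,0.15,0.1,2.0,"Fractal dynamics","Psycho-emotional status","normative-database"
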