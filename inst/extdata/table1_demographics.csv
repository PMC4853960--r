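# table1_demographics VERSION 1.0
# Demographics and disease history of the 17 STN-DBS patients with left
# hemibody symptom onset and their 17 age-matched controls, transcribed from
# the source study's clinical table. Units: age years, LED mg/day, durations
# years, UPDRS-III points, asymmetry % left-sided symptoms, voltages V.
# Missing entries are empty fields (pre-op UPDRS unavailable for 3 patients;
# ventral-contact voltages unavailable for patients 2, 10, 15).
id,age,gender,led_mg,pd_duration_yr,dbs_duration_yr,updrs_preop_dopa_off,updrs_preop_dopa_on,updrs_postop_dbs_off,updrs_postop_dbs_on,recorded_in_dopa_off,asymmetry_pct,stim_right,stim_left,volt_veR,volt_veL,control_age,control_gender
1,32,M,631,2.0,0.8,44.0,25.0,13.0,6.0,No cond,73.3,"-10/+11, 60, 130, 2.5 V","-2/+C, 60, 130, 2.3 V",2.8,1.5,30,m
2,42,M,567,7.5,2.1,40.0,24.0,47.0,21.5,No cond,54.9,"-9/-10/+C, 60, 180, 2.0 V","-1/-2/+C, 60, 180, 2.1 V",,,40,m
3,45,M,1249,7.5,0.3,,,39.5,10.0,No cond,61.4,"-10/+C, 60, 130, 2.7 V","-2/+C, 60, 130, 2.3 V",2.6,4.0,51,f
4,48,F,1082,12.0,0.8,34.0,19.0,34.0,14.0,No cond,66.7,"-9/+C, 60, 130, 3.8 V","-2/+C, 60, 130, 2.8 V",2.4,2.0,51,m
5,49,M,809,9.0,2.3,26.0,7.0,32.0,7.5,"veR, veL",77.8,"-10/+C, 60, 90, 3.2 V","-2/+C, 60, 90, 2.0 V",2.4,5.0,53,f
6,53,M,624,0.0,0.3,50.0,17.0,48.0,35.0,"veR, veL",53.1,"-10/+C, 60, 130, 2.7 V","-2/+C, 60, 130, 2.7 V",1.4,2.8,53,m
7,58,F,1341,12.0,2.0,67.0,10.0,14.5,14.5,No cond,93.8,"-10/+C, 60, 150, 2.6 V","-2/+C, 60, 150, 2.5 V",0.8,1.6,54,m
8,58,M,1203,20.5,3.0,54.0,10.0,22.5,18.5,No cond,45.2,"-9/-10/+C, 60, 130, 3.0 V","-1/-2/+C, 60, 130, 3.3 V",3.4,4.3,54,f
9,60,M,1027,19.8,3.8,57.0,17.0,45.5,24.5,All cond,60.9,"-8/+C, 60, 160, 2.0 V","-1/+C, 60, 160, 2.4 V",2.5,2.9,56,f
10,60,F,967,22.5,5.8,,,46.5,46.5,All cond,47.2,"-10/+C, 90, 130, 3.9 V","-1/+C, 60, 130, 3.6 V",,,56,m
11,60,F,1038,8.5,1.8,39.0,6.0,42.0,42.0,No cond,65.4,"-10/+9, 90, 130, 3.2 V","-2/+C, 60, 130, 2.0 V",2.8,1.4,57,f
12,60,M,550,10.0,3.2,,,55.0,27.0,"veR, veL",55.3,"-9/+C, 60, 180, 4.0 V","-1/+C, 60, 180, 4.5 V",3.2,2.4,61,m
13,62,M,926,11.5,1.3,51.0,44.0,52.0,23.0,No cond,53.9,"-10/+C, 60, 160, 3.7 V","-2/+C, 60, 160, 3.5 V",1.6,3.2,63,m
14,65,M,566,16.7,3.0,15.0,9.0,25.0,9.5,No cond,75.6,"-10/-9/+C, 60, 130, 3.9 V","-1/+C, 60, 130, 1.5 V",3.2,3.2,68,f
15,69,F,508,15.2,0.8,31.0,17.0,26.0,23.5,No cond,89.5,"-10/+9, 60, 180, 2.5 V","-2/+C, 60, 180, 2.8 V",,,68,f
16,72,m,1111,12.2,2.0,29.0,11.0,27.5,15.5,No cond,64.3,"-10/+9, 60, 130, 4.0 V","-2/+1, 60, 130, 3.5 V",3.6,4.0,76,f
17,73,m,537,20.5,7.5,31.0,12.0,31.0,24.0,No cond,63.0,"-10/+C, 60, 130, 3.1 V","-2/+C, 60, 130, 3.1 V",4.0,5.6,76,m
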