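# table2_electrodes VERSION 1.0
# MNI positions (mm, world space) of the ventral-most stimulation contacts
# used in the unilateral conditions, with per-side outcomes, transcribed from
# the source study's electrode table. One row per patient x side; 14 patients
# (imaging excluded for the remaining three). Patient 17's coordinates could
# not be reconstructed (distorted CT) and are empty. side_effects codes:
# PAR paresthesia, DYS dysarthria, TC/TMC (tetanic) muscle contraction,
# DA dizziness, MO mouth drawn, AUT autonomic. pct_right is the percentage of
# exploration time on the right hemifield during that side's unilateral
# condition, init_bias the median horizontal first-fixation position (deg),
# delta_sac the mean rightward-minus-leftward saccade length (deg).
id,side,x,y,z,side_effects,pct_right,init_bias,delta_sac
1,left,-11.9,-13.4,-7.1,"TC, DYS",36.8,-1.01,1.1
1,right,10.4,-14.0,-7.1,"PAR, DYS",44.3,-0.08,0.0
3,left,-11.9,-14.9,-6.9,"TMC, DA",85.3,0.62,0.0
3,right,11.8,-14.6,-7.2,TMC,26.9,-1.32,0.2
4,left,-10.0,-13.5,-9.5,"DYS, TC, MO",51.9,-1.19,0.2
4,right,10.3,-13.6,-6.4,"PAR, DA",56.8,-0.52,0.2
5,left,-9.4,-14.4,-7.3,PAR,71.0,2.42,-0.3
5,right,10.6,-15.8,-7.1,PAR,58.6,1.97,-0.5
6,left,-11.1,-14.1,-6.9,PAR,47.5,0.14,0.2
6,right,11.7,-12.2,-8.1,PAR,60.6,0.88,-0.2
7,left,-8.4,-14.2,-11.0,"PAR, DA",59.6,2.97,-0.6
7,right,11.0,-13.6,-6.7,DA,56.2,3.91,-0.2
8,left,-11.9,-12.2,-8.1,"DYS, AUT",54.3,-0.50,-0.2
8,right,12.1,-14.0,-7.6,"PAR, AUT",51.0,1.32,-0.1
9,left,-10.8,-13.8,-11.3,,49.6,-1.25,0.8
9,right,9.4,-16.6,-8.4,,50.0,-1.24,1.1
11,left,-10.2,-15.3,-8.4,"TC, PAR, DYS",42.7,-1.61,0.3
11,right,12.7,-13.3,-7.8,"MO, TMC",40.3,-2.96,-0.7
12,left,-6.0,-15.6,-12.6,PAR,80.4,3.60,0.5
12,right,11.0,-10.6,-5.9,PAR,76.7,2.36,0.2
13,left,-10.9,-12.8,-6.7,"TMC, DYS, PAR, DA",40.7,-2.95,1.0
13,right,10.6,-14.5,-6.4,"TC, DA, PAR",85.0,1.34,3.4
14,left,-9.0,-16.3,-7.7,"PAR, DA",79.6,5.64,0.5
14,right,11.9,-14.6,-5.2,"PAR, DA",69.0,1.60,1.1
16,left,-8.5,-15.6,-6.1,"AUT, PAR",73.0,1.14,0.2
16,right,9.8,-15.1,-4.6,"AUT, PAR",40.6,0.21,-0.5
17,left,,,,,57.1,-0.64,-0.8
17,right,,,,,55.1,-0.42,-1.1
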