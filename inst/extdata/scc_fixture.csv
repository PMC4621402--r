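subject_id,unit_id,group_id,occasion,week,sccs,ks2,kon
S001,U1,G1,1,0,33.66,167,38.1
S001,U1,G1,2,2,42.8,NA,NA
S001,U1,G1,3,4,36.9,NA,NA
S001,U1,G1,4,6,31.11,NA,NA
S001,U1,G1,5,8,31.57,134.9,NA
S002,U1,G1,1,0,45.3,228.9,21
S002,U1,G1,2,2,54.06,NA,NA
S002,U1,G1,3,4,48.23,NA,NA
S002,U1,G1,4,6,42.2,NA,NA
S002,U1,G1,5,8,43.15,255.7,NA
S003,U2,G4,1,0,42.26,161.4,13.5
S003,U2,G4,2,2,35.5,NA,NA
S003,U2,G4,3,4,34.68,NA,NA
S003,U2,G4,4,6,33.28,NA,NA
S003,U2,G4,5,8,32.39,188,NA
S004,U1,G2,1,0,54.47,282.6,13.8
S004,U1,G2,2,2,47.52,NA,NA
S004,U1,G2,3,4,46.44,NA,NA
S004,U1,G2,4,6,45.11,NA,NA
S004,U1,G2,5,8,44.05,312.9,NA
S005,U3,G7,1,0,44.04,38.1,15.2
S005,U3,G7,2,2,36.72,NA,NA
S005,U3,G7,3,4,35.68,NA,NA
S005,U3,G7,4,6,34.63,NA,NA
S005,U3,G7,5,8,33.36,97.1,NA
S006,U3,G6,1,0,52.19,206.5,26.2
S006,U3,G6,2,2,52.99,NA,NA
S006,U3,G6,3,4,46,NA,NA
S006,U3,G6,4,6,54.27,NA,NA
S006,U3,G6,5,8,55.25,331.5,NA
S007,U1,G3,1,0,44.53,318.4,27.6
S007,U1,G3,2,2,45.06,NA,NA
S007,U1,G3,3,4,38.34,NA,NA
S007,U1,G3,4,6,46.53,NA,NA
S007,U1,G3,5,8,46.9,154.4,NA
S008,U2,G5,1,0,45.19,34.4,64.1
S008,U2,G5,2,2,46.12,NA,NA
S008,U2,G5,3,4,39.04,NA,NA
S008,U2,G5,4,6,47.43,NA,NA
S008,U2,G5,5,8,48.57,0,NA
S009,U3,G7,1,0,39.88,335.1,60.9
S009,U3,G7,2,2,39.84,NA,NA
S009,U3,G7,3,4,39.33,NA,NA
S009,U3,G7,4,6,40.04,NA,NA
S009,U3,G7,5,8,39.41,407,NA
S010,U1,G3,1,0,43.44,215.8,39.8
S010,U1,G3,2,2,43.3,NA,NA
S010,U1,G3,3,4,43.38,NA,NA
S010,U1,G3,4,6,43.46,NA,NA
S010,U1,G3,5,8,43.44,339.2,NA
S011,U3,G6,1,0,27.71,279.2,44.4
S011,U3,G6,2,2,36.74,NA,NA
S011,U3,G6,3,4,30.6,NA,NA
S011,U3,G6,4,6,24.59,NA,NA
S011,U3,G6,5,8,25.3,234.7,NA
S012,U1,G3,1,0,45.73,351.6,54.5
S012,U1,G3,2,2,54.7,NA,NA
S012,U1,G3,3,4,49.5,NA,NA
S012,U1,G3,4,6,42.49,NA,NA
S012,U1,G3,5,8,43.86,359.4,NA
S013,U1,G1,1,0,20.31,339.2,22.9
S013,U1,G1,2,2,29.31,NA,NA
S013,U1,G1,3,4,23.71,NA,NA
S013,U1,G1,4,6,17.43,NA,NA
S013,U1,G1,5,8,18.68,290.2,NA
S014,U2,G4,1,0,25.45,277.3,39.3
S014,U2,G4,2,2,26.4,NA,NA
S014,U2,G4,3,4,19.05,NA,NA
S014,U2,G4,4,6,27.25,NA,NA
S014,U2,G4,5,8,28.6,286.9,NA
S015,U3,G6,1,0,32.1,186,25.3
S015,U3,G6,2,2,24.84,NA,NA
S015,U3,G6,3,4,23.96,NA,NA
S015,U3,G6,4,6,23.24,NA,NA
S015,U3,G6,5,8,22.32,293.7,NA
S016,U1,G1,1,0,28.58,124.1,20.1
S016,U1,G1,2,2,28.82,NA,NA
S016,U1,G1,3,4,29.15,NA,NA
S016,U1,G1,4,6,28.73,NA,NA
S016,U1,G1,5,8,28.84,65.2,NA
S017,U1,G1,1,0,27.06,121.3,28.6
S017,U1,G1,2,2,19.86,NA,NA
S017,U1,G1,3,4,18.97,NA,NA
S017,U1,G1,4,6,18.07,NA,NA
S017,U1,G1,5,8,16.98,154.1,NA
S018,U2,G5,1,0,27.79,208.2,10.2
S018,U2,G5,2,2,36.39,NA,NA
S018,U2,G5,3,4,30.41,NA,NA
S018,U2,G5,4,6,24.69,NA,NA
S018,U2,G5,5,8,25.25,127.5,NA
S019,U3,G6,1,0,17.23,375.2,50.9
S019,U3,G6,2,2,25.85,NA,NA
S019,U3,G6,3,4,20.53,NA,NA
S019,U3,G6,4,6,14.17,NA,NA
S019,U3,G6,5,8,15.12,177.7,NA
S020,U3,G7,1,0,35.37,48,74.2
S020,U3,G7,2,2,44.68,NA,NA
S020,U3,G7,3,4,38.48,NA,NA
S020,U3,G7,4,6,32.55,NA,NA
S020,U3,G7,5,8,34.01,10.8,NA
S021,U1,G1,1,0,25.11,270.8,67.6
S021,U1,G1,2,2,25.89,NA,NA
S021,U1,G1,3,4,19.2,NA,NA
S021,U1,G1,4,6,27.07,NA,NA
S021,U1,G1,5,8,28.31,341.9,NA
S022,U2,G5,1,0,34.98,464.2,49.4
S022,U2,G5,2,2,43.37,NA,NA
S022,U2,G5,3,4,37.74,NA,NA
S022,U2,G5,4,6,31.64,NA,NA
S022,U2,G5,5,8,32.85,407.5,NA
S023,U1,G1,1,0,32.02,459.7,34.2
S023,U1,G1,2,2,39.29,NA,NA
S023,U1,G1,3,4,39.64,NA,NA
S023,U1,G1,4,6,41.5,NA,NA
S023,U1,G1,5,8,42.3,275.1,NA
S024,U1,G1,1,0,27.77,391.3,43.8
S024,U1,G1,2,2,20.44,NA,NA
S024,U1,G1,3,4,19.97,NA,NA
S024,U1,G1,4,6,18.93,NA,NA
S024,U1,G1,5,8,17.8,333,NA
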