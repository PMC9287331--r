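"station_id","latitude","longitude","altitude","tmin_01","tmin_02","tmin_03","tmin_04","tmin_05","tmin_06","tmin_07","tmin_08","tmin_09","tmin_10","tmin_11","tmin_12","tmax_01","tmax_02","tmax_03","tmax_04","tmax_05","tmax_06","tmax_07","tmax_08","tmax_09","tmax_10","tmax_11","tmax_12","rh_01","rh_02","rh_03","rh_04","rh_05","rh_06","rh_07","rh_08","rh_09","rh_10","rh_11","rh_12","wind_01","wind_02","wind_03","wind_04","wind_05","wind_06","wind_07","wind_08","wind_09","wind_10","wind_11","wind_12","srad_01","srad_02","srad_03","srad_04","srad_05","srad_06","srad_07","srad_08","srad_09","srad_10","srad_11","srad_12","prec_01","prec_02","prec_03","prec_04","prec_05","prec_06","prec_07","prec_08","prec_09","prec_10","prec_11","prec_12","et0_01","et0_02","et0_03","et0_04","et0_05","et0_06","et0_07","et0_08","et0_09","et0_10","et0_11","et0_12"
"SYN001",39.25,5.25,365.93,-18.666,-16.558,-10.797,-2.929,4.94,10.701,12.809,10.701,4.94,-2.929,-10.797,-16.558,-8.666,-6.558,-0.797,7.071,14.94,20.701,22.809,20.701,14.94,7.071,-0.797,-6.558,49.519,50.045,51.423,53.176,54.789,55.89,56.276,55.89,54.789,53.176,51.423,50.045,4.347,4.347,4.347,4.347,4.347,4.347,4.347,4.347,4.347,4.347,4.347,4.347,7.1,9.546,12.89,16.187,18.352,19.194,18.648,16.798,13.751,10.385,7.665,6.434,14.005,15.881,21.007,28.009,35.012,40.138,42.014,40.138,35.012,28.009,21.007,15.881,22.639,25.74,45.08,72.837,112.863,137.99,150.411,132.866,94.519,61.655,35.778,25.085
"SYN002",39.75,6.75,375.742,-19.205,-17.073,-11.249,-3.292,4.664,10.488,12.62,10.488,4.664,-3.292,-11.249,-17.073,-9.205,-7.073,-1.249,6.708,14.664,20.488,22.62,20.488,14.664,6.708,-1.249,-7.073,33.806,34.172,35.131,36.349,37.47,38.234,38.502,38.234,37.47,36.349,35.131,34.172,1.934,1.934,1.934,1.934,1.934,1.934,1.934,1.934,1.934,1.934,1.934,1.934,7.337,9.926,13.483,17.006,19.334,20.244,19.656,17.666,14.403,10.82,7.936,6.634,14.026,15.905,21.039,28.052,35.066,40.2,42.079,40.2,35.066,28.052,21.039,15.905,19.581,23.629,43.663,72.3,111.375,133.903,143.725,125.466,87.787,55.611,30.974,21.2
"SYN003",40.25,5.25,400.027,-19.838,-17.682,-11.794,-3.75,4.294,10.182,12.337,10.182,4.294,-3.75,-11.794,-17.682,-9.838,-7.682,-1.794,6.25,14.294,20.182,22.337,20.182,14.294,6.25,-1.794,-7.682,41.928,42.392,43.605,45.146,46.562,47.526,47.864,47.526,46.562,45.146,43.605,42.392,1.009,1.009,1.009,1.009,1.009,1.009,1.009,1.009,1.009,1.009,1.009,1.009,4.548,6.193,8.462,10.721,12.223,12.813,12.433,11.148,9.053,6.763,4.929,4.103,14.021,15.9,21.032,28.043,35.053,40.185,42.064,40.185,35.053,28.043,21.032,15.9,12.672,15.578,29.195,48.387,73.72,87.478,93.149,81.276,57.073,36.194,20.026,13.619
"SYN004",38.75,5.25,328.83,-17.95,-15.865,-10.169,-2.387,5.394,11.09,13.175,11.09,5.394,-2.387,-10.169,-15.865,-7.95,-5.865,-0.169,7.613,15.394,21.09,23.175,21.09,15.394,7.613,-0.169,-5.865,27.864,28.153,28.912,29.877,30.767,31.375,31.588,31.375,30.767,29.877,28.912,28.153,4.006,4.006,4.006,4.006,4.006,4.006,4.006,4.006,4.006,4.006,4.006,4.006,5.848,7.814,10.492,13.117,14.832,15.495,15.063,13.6,11.176,8.486,6.302,5.311,13.956,15.826,20.935,27.913,34.891,39.999,41.869,39.999,34.891,27.913,20.935,15.826,31.597,34.75,58.617,91.59,138.789,167.895,183.687,165.506,122.083,83.124,49.964,35.493
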