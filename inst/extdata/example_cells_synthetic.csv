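cell_id,x,y,compartment,CD8,PD1,TOX,FOXP3,PDL1,PAX8
EX1_c00001,194.99,150.1,tumor,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
EX1_c00002,108.56,92.53,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00003,208.67,104.57,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00004,237.12,144.44,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00005,160.76,132.39,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00006,131.56,184.95,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00007,151.87,99.65,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00008,184.99,102.12,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00009,200.78,153.33,tumor,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
EX1_c00010,225.6,176.65,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00011,236.05,155.96,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00012,199.78,177.18,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00013,140.83,122.08,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00014,61.75,86.81,tumor,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
EX1_c00015,184.21,223.42,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00016,200.47,100.42,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00017,61.9,92.57,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00018,64.65,185.14,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00019,68.92,128.05,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00020,138.63,141.26,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00021,29.7,160.88,tumor,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
EX1_c00022,136.68,156.89,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00023,58.19,83.32,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00024,162.23,145.73,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00025,46.89,169.52,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00026,59.6,140.01,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00027,29.87,91.4,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00028,36.49,109.3,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00029,82.08,110.47,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00030,151.04,172.86,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00031,197.61,176.06,tumor,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
EX1_c00032,126.51,180.23,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00033,130.17,140.37,tumor,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
EX1_c00034,67.19,89.42,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
EX1_c00035,240.08,169.62,tumor,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00036,157.93,41,stroma,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00037,49.57,202.69,stroma,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE
EX1_c00038,65.23,56.78,tumor,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE
EX1_c00039,171.41,138.86,tumor,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00040,241.43,164.82,tumor,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00041,9.25,88.45,stroma,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00042,8.1,152.52,stroma,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00043,112.44,129.24,tumor,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00044,184.87,40.32,stroma,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00045,233.82,184.23,tumor,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00046,220.52,161.26,tumor,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE
EX1_c00047,150.1,10.97,stroma,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00048,107.37,236.68,stroma,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00049,195.79,126.96,tumor,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00050,24.8,126.8,tumor,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00051,106.53,95.64,tumor,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EX1_c00052,82.33,158.63,tumor,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
EX1_c00053,214.19,158.73,tumor,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
EX1_c00054,180.68,246.83,stroma,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
EX1_c00055,138.4,81.64,tumor,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
EX1_c00056,32.08,164.4,tumor,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
EX1_c00057,73.06,129.37,tumor,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
EX1_c00058,82.61,150.64,tumor,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
EX1_c00059,78.7,96.15,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00060,166.87,173.07,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00061,131.68,37.13,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00062,21.97,157.67,stroma,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
EX1_c00063,176.59,27.53,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00064,218.96,76.41,stroma,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
EX1_c00065,20.09,76.62,stroma,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
EX1_c00066,205.35,88.86,stroma,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
EX1_c00067,194.52,63.84,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00068,81.71,233.58,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00069,236.32,225.73,stroma,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
EX1_c00070,245.2,120.05,stroma,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
EX1_c00071,45.58,67.67,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00072,105.23,229.12,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00073,110.47,20.18,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00074,32.36,168.31,stroma,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
EX1_c00075,28.26,122.71,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00076,24.39,109.87,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00077,245.96,227.71,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00078,223.15,150.57,tumor,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00079,29.11,10.29,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
EX1_c00080,238.74,13.39,stroma,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
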