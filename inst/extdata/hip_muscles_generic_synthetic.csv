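name,group,segment_origin,ox,oy,oz,via_segment,vx,vy,vz,segment_insertion,ix,iy,iz,f_iso_max,l_opt,l_ts,k_pe,eps0
glut_max1,extensor,pelvis,-0.08,0.01,-0.05,NA,NA,NA,NA,femur,-0.05,0.03,0.07,56.64631452837795,0.12037304164149097,0.030093260410372732,4,0.6
glut_max2,extensor,pelvis,-0.08,0,-0.03,NA,NA,NA,NA,femur,-0.04,0.02,0.08,93.86483507482416,0.11842799494428982,0.02960699873607245,4,0.6
glut_max3,extensor,pelvis,-0.09,-0.01,0.01,NA,NA,NA,NA,femur,-0.03,0.01,0.1,34.808512016457314,0.1224248467977501,0.030606211699437516,4,0.6
glut_med1,abductor,pelvis,-0.01,0.05,-0.07,NA,NA,NA,NA,femur,-0.01,0.05,0.01,550,0.050911670015713735,0.033941113343809164,4,0.6
glut_med2,abductor,pelvis,-0.03,0.04,-0.07,NA,NA,NA,NA,femur,-0.01,0.05,0.02,380,0.05941468998178063,0.03960979332118709,4,0.6
glut_med3,abductor,pelvis,-0.05,0.03,-0.06,NA,NA,NA,NA,femur,-0.02,0.05,0.02,435,0.06495015649506156,0.04330010433004104,4,0.6
glut_min1,abductor,pelvis,0,0.04,-0.05,NA,NA,NA,NA,femur,0,0.05,0.01,180,0.03649657518178932,0.024331050121192882,4,0.6
glut_min2,abductor,pelvis,-0.02,0.04,-0.05,NA,NA,NA,NA,femur,-0.01,0.05,0.015,190,0.043542712895563516,0.029028475263709014,4,0.6
glut_min3,abductor,pelvis,-0.04,0.03,-0.05,NA,NA,NA,NA,femur,-0.015,0.045,0.02,215,0.05417124270733242,0.03611416180488829,4,0.6
iliacus,flexor,pelvis,0.01,0.02,-0.07,pelvis,0.03,0.01,-0.01,femur,-0.01,-0.01,0.06,430,0.04751534813676419,0.08203995183994364,4,0.6
psoas,flexor,pelvis,-0.01,-0.03,-0.12,pelvis,0.03,0,-0.01,femur,-0.01,-0.015,0.055,370,0.053673758721348705,0.12512264365627956,4,0.6
add_long,adductor,pelvis,0.04,-0.05,0.02,NA,NA,NA,NA,femur,0,-0.01,0.22,420,0.09495126856999911,0.0992423214749667,4,0.6
add_brev,adductor,pelvis,0.03,-0.06,0.03,NA,NA,NA,NA,femur,0,-0.01,0.12,285,0.06434283176858165,0.042895221179054435,4,0.6
add_mag1,adductor,pelvis,0.02,-0.06,0.05,NA,NA,NA,NA,femur,-0.01,-0.015,0.15,52.62245112579571,0.09095053600721659,0.022737634001804133,4,0.6
add_mag2,extensor,pelvis,-0.05,-0.04,0.07,NA,NA,NA,NA,femur,0,-0.02,0.38,66.49520939827447,0.2829868672782316,0.07074671681955785,4,0.6
pect,adductor,pelvis,0.04,-0.04,0,NA,NA,NA,NA,femur,-0.01,-0.01,0.09,88.81024980728088,0.07324346139323033,0.018310865348307573,4,0.6
gracilis,adductor,pelvis,0.03,-0.06,0.04,NA,NA,NA,NA,tibia,0.01,-0.02,0.07,110,0.04147740795574133,0.4026332940498889,4,0.6
tfl,flexor,pelvis,0.03,0.06,-0.04,femur,0.01,0.06,0.05,tibia,0.02,0.03,0.05,155,0.049620716677469555,0.4499937780795889,4,0.6
rect_fem,flexor,pelvis,0.05,0.02,-0.04,femur,0.035,0,0.4,tibia,0.035,0,0.05,780,0.08609112086270523,0.4077934758370084,4,0.6
sartorius,flexor,pelvis,0.04,0.06,-0.03,NA,NA,NA,NA,tibia,0.02,-0.02,0.08,105,0.0597527391821169,0.4568909942645225,4,0.6
semimem,extensor,pelvis,-0.06,-0.03,0.06,NA,NA,NA,NA,tibia,-0.03,-0.02,0.04,1030,0.24474312894338582,0.17460251991495326,4,0.6
semiten,extensor,pelvis,-0.06,-0.03,0.07,NA,NA,NA,NA,tibia,-0.02,-0.02,0.06,330,0.21642488918447378,0.22014273569094867,4,0.6
bflh,extensor,pelvis,-0.06,-0.02,0.07,NA,NA,NA,NA,tibia,-0.03,0.03,0.04,681.1191797785558,0.3284007541648266,0.08210018854120665,4,0.6
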