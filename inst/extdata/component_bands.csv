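component,class,center_cm1,fwhm_cm1,height
cellulose,cellulose,1033,40,1.00
cellulose,cellulose,1160,30,0.45
cellulose,cellulose,898,25,0.30
hemicellulose_xylan,hemicellulose,1043,35,0.50
hemicellulose_xylan,hemicellulose,1735,30,0.35
hemicellulose_xylan,hemicellulose,1245,35,0.40
lignin_G,lignin,1510,25,0.90
lignin_G,lignin,1268,30,0.60
lignin_G,lignin,855,25,0.25
lignin_S,lignin,1595,30,0.90
lignin_S,lignin,1326,30,0.60
lignin_S,lignin,1123,30,0.40
pectin,pectin,1745,25,0.60
pectin,pectin,1608,45,0.50
pectin,pectin,955,30,0.30
protein,protein,1652,35,1.00
protein,protein,1545,35,0.70
lipid,lipid,1465,20,0.70
lipid,lipid,1378,20,0.35
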