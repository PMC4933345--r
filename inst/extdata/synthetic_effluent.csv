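"run_id","cell_type","injected_dose","minute","flow_ml_min","conc_cells_ml","replicate"
"heart1","BMMNC",8e+06,1,17,326789.897281289,1
"heart1","BMMNC",8e+06,1,17,362200.288947591,2
"heart1","BMMNC",8e+06,1,17,351220.956422931,3
"heart1","BMMNC",8e+06,2,14,18237.1513466546,1
"heart1","BMMNC",8e+06,2,14,18112.2606389987,2
"heart1","BMMNC",8e+06,2,14,16719.2591505634,3
"heart1","BMMNC",8e+06,3,14,341.534481807457,1
"heart1","BMMNC",8e+06,3,14,293.721405701638,2
"heart1","BMMNC",8e+06,3,14,338.745553571606,3
"heart1","BMMNC",8e+06,4,14,5.91312628294984,1
"heart1","BMMNC",8e+06,4,14,5.82028335060073,2
"heart1","BMMNC",8e+06,4,14,5.57360284475387,3
"heart1","BMMNC",8e+06,5,14,0,1
"heart1","BMMNC",8e+06,5,14,0,2
"heart1","BMMNC",8e+06,5,14,0,3
"heart1","BMMNC",8e+06,6,14,0,1
"heart1","BMMNC",8e+06,6,14,0,2
"heart1","BMMNC",8e+06,6,14,0,3
"heart1","BMMNC",8e+06,7,14,0,1
"heart1","BMMNC",8e+06,7,14,0,2
"heart1","BMMNC",8e+06,7,14,0,3
"heart1","BMMNC",8e+06,8,14,0,1
"heart1","BMMNC",8e+06,8,14,0,2
"heart1","BMMNC",8e+06,8,14,0,3
"heart1","BMMNC",8e+06,9,14,0,1
"heart1","BMMNC",8e+06,9,14,0,2
"heart1","BMMNC",8e+06,9,14,0,3
"heart1","BMMNC",8e+06,10,14,0,1
"heart1","BMMNC",8e+06,10,14,0,2
"heart1","BMMNC",8e+06,10,14,0,3
"heart2","BMMNC",8e+06,1,17,367322.46526706,1
"heart2","BMMNC",8e+06,1,17,373352.767962717,2
"heart2","BMMNC",8e+06,1,17,346561.709815619,3
"heart2","BMMNC",8e+06,2,14,16523.480413125,1
"heart2","BMMNC",8e+06,2,14,19683.7681450068,2
"heart2","BMMNC",8e+06,2,14,16348.1906271619,3
"heart2","BMMNC",8e+06,3,14,317.006677372865,1
"heart2","BMMNC",8e+06,3,14,305.488274414785,2
"heart2","BMMNC",8e+06,3,14,351.135042275089,3
"heart2","BMMNC",8e+06,4,14,6.15051122793557,1
"heart2","BMMNC",8e+06,4,14,6.08374813658934,2
"heart2","BMMNC",8e+06,4,14,6.46255810416287,3
"heart2","BMMNC",8e+06,5,14,0,1
"heart2","BMMNC",8e+06,5,14,0,2
"heart2","BMMNC",8e+06,5,14,0,3
"heart2","BMMNC",8e+06,6,14,0,1
"heart2","BMMNC",8e+06,6,14,0,2
"heart2","BMMNC",8e+06,6,14,0,3
"heart2","BMMNC",8e+06,7,14,0,1
"heart2","BMMNC",8e+06,7,14,0,2
"heart2","BMMNC",8e+06,7,14,0,3
"heart2","BMMNC",8e+06,8,14,0,1
"heart2","BMMNC",8e+06,8,14,0,2
"heart2","BMMNC",8e+06,8,14,0,3
"heart2","BMMNC",8e+06,9,14,0,1
"heart2","BMMNC",8e+06,9,14,0,2
"heart2","BMMNC",8e+06,9,14,0,3
"heart2","BMMNC",8e+06,10,14,0,1
"heart2","BMMNC",8e+06,10,14,0,2
"heart2","BMMNC",8e+06,10,14,0,3
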