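liver_id,mppgl_mg_per_g,CYP1A2,CYP2D25,CYP2E1,CYP3A29,phenacetin_rate_pmol_min_mg,midazolam_rate_pmol_min_mg
liver1,10.9,21.6,68.5,143,16.8,3800,2300
liver2,14.6,28.3,50.3,139,48.5,6000,4000
liver3,11.4,19.9,66.2,133,34.1,1600,1000
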