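site_class,variant_id,stapled,staple,index_a,register_a,index_b,register_b,counterpart,tm_obs,tm_obs_se,tm_sim,tm_sim_se,ddg_obs,ddg_obs_se,ddg_sim,ddg_sim_se,cb310,cb310_se,cb450,cb450_se,d450,d450_se
nsb_eg,6e/8g'-z4x,FALSE,z4x,6,e,8,g,,39.5,0.2,81.8,0.1,,,,,10.5,0.1,59.5,0.2,,
nsb_eg,s6e/8g'-z4x,TRUE,z4x,6,e,8,g,6e/8g'-z4x,69.1,0.2,101.8,0.3,-2.53,0.04,-2.00,0.06,10.09,0.01,14.40,0.01,-45.1,0.2
nsb_eg,13e/15g'-z4x,FALSE,z4x,13,e,15,g,,42.1,0.1,83.6,0.1,,,,,10.18,0.04,50.0,0.3,,
nsb_eg,s13e/15g'-z4x,TRUE,z4x,13,e,15,g,13e/15g'-z4x,57.7,0.1,92.8,0.2,-1.33,0.02,-1.10,0.04,10.32,0.01,14.65,0.01,-35.3,0.3
nsb_eg,20e/22g'-z4x,FALSE,z4x,20,e,22,g,,41.8,0.2,82.9,0.1,,,,,10.45,0.10,38.8,0.1,,
nsb_eg,s20e/22g'-z4x,TRUE,z4x,20,e,22,g,20e/22g'-z4x,54.3,0.1,89.0,0.1,-1.09,0.02,-0.84,0.02,10.41,0.01,14.07,0.02,-24.8,0.1
nsb_eg,27e/29g'-z4x,FALSE,z4x,27,e,29,g,,41.1,0.2,85.4,0.1,,,,,11.6,0.2,23.22,0.04,,
nsb_eg,s27e/29g'-z4x,TRUE,z4x,27,e,29,g,27e/29g'-z4x,48.2,0.1,87.5,0.1,-0.65,0.02,-0.27,0.02,10.58,0.01,13.55,0.02,-9.68,0.04
nsb_eg,27e/29g'-xx,FALSE,x4x,27,e,29,g,,39.8,0.2,87.4,0.1,,,,,11.5,0.1,22.07,0.03,,
nsb_eg,s27e/29g'-x4x,TRUE,x4x,27,e,29,g,27e/29g'-xx,52.9,0.2,90.5,0.1,-1.08,0.03,-0.48,0.02,10.55,0.02,13.62,0.02,-8.45,0.04
sb_eg,6e/1g'-xx,FALSE,x4x,6,e,1,g,,48.7,0.1,87.4,0.1,,,,,10.66,0.05,62.5,0.4,,
sb_eg,s6e/1g'-x4x,TRUE,x4x,6,e,1,g,6e/1g'-xx,77.5,0.1,103.6,0.1,-2.96,0.04,-2.03,0.03,9.74,0.02,13.61,0.02,-48.9,0.4
sb_eg,13e/8g'-xx,FALSE,x4x,13,e,8,g,,41.8,0.2,82.9,0.1,,,,,10.01,0.04,53.9,0.3,,
sb_eg,s13e/8g'-x4x,TRUE,x4x,13,e,8,g,13e/8g'-xx,75.6,0.1,101.7,0.4,-3.13,0.05,-1.76,0.08,9.52,0.01,15.08,0.02,-38.8,0.3
sb_eg,20e/15g'-xx,FALSE,x4x,20,e,15,g,,43.2,0.1,83.8,0.1,,,,,9.45,0.01,44.3,0.2,,
sb_eg,s20e/15g'-x4x,TRUE,x4x,20,e,15,g,20e/15g'-xx,74.4,0.1,93.5,0.2,-3.13,0.04,-0.80,0.03,9.71,0.01,14.85,0.02,-29.4,0.2
sb_eg,27e/22g'-z4x,FALSE,z4x,27,e,22,g,,43.2,0.1,84.6,0.1,,,,,9.46,0.02,32.26,0.07,,
sb_eg,s27e/22g'-z4x,TRUE,z4x,27,e,22,g,27e/22g'-z4x,63.6,0.1,91.1,0.2,-2.01,0.03,-0.79,0.03,9.62,0.02,14.33,0.01,-17.93,0.07
sb_eg,27e/22g'-xx,FALSE,x4x,27,e,22,g,,42.5,0.2,85.7,0.1,,,,,9.58,0.02,31.3,0.1,,
sb_eg,s27e/22g'-x4x,TRUE,x4x,27,e,22,g,27e/22g'-xx,63.7,0.1,92.0,0.1,-2.07,0.01,-0.72,0.02,9.45,0.01,14.61,0.01,-16.7,0.1
sb_eg,34e/29g'-xx,FALSE,x4x,34,e,29,g,,51.8,0.1,89.3,0.1,,,,,10.02,0.08,14.98,0.02,,
sb_eg,s34e/29g'-x4x,TRUE,x4x,34,e,29,g,34e/29g'-xx,61.9,0.1,92.8,0.1,-1.07,0.01,-0.42,0.02,9.06,0.03,11.20,0.02,-3.78,0.03
fb,7f/10b'-xx,FALSE,x4x,7,f,10,b,,48.9,0.2,92.8,0.1,,,,,16.11,0.02,49.2,0.3,,
fb,s7f/10b'-x4x,TRUE,x4x,7,f,10,b,7f/10b'-xx,58.0,0.2,98.5,0.4,-0.64,0.01,-0.40,0.05,11.8,0.4,14.73,0.02,-34.5,0.3
fb,14f/17b'-xx,FALSE,x4x,14,f,17,b,,43.4,0.2,88.3,0.1,,,,,16.34,0.01,43.0,0.2,,
fb,s14f/17b'-x4x,TRUE,x4x,14,f,17,b,14f/17b'-xx,,,75.6,0.9,,,0.66,0.06,14.8,0.4,14.65,0.02,-28.4,0.2
fb,21f/24b'-xx,FALSE,x4x,21,f,24,b,,41.9,0.2,86.6,0.1,,,,,16.08,0.04,32.8,0.1,,
fb,s21f/24b'-x4x,TRUE,x4x,21,f,24,b,21f/24b'-xx,,,77.8,0.7,,,0.56,0.06,13.8,0.2,14.14,0.02,-18.6,0.1
fb,28f/31b'-xx,FALSE,x4x,28,f,31,b,,45.7,0.1,87.2,0.1,,,,,16.03,0.05,17.57,0.02,,
fb,s28f/31b'-x4x,TRUE,x4x,28,f,31,b,28f/31b'-xx,37.8,0.3,82.7,0.2,0.62,0.03,0.43,0.03,11.1,0.2,12.79,0.02,-4.78,0.03
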