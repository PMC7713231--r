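model,threshold,slide_code,depth_cm,total_images,unclassified_pct,det_Cdv,prec_Cdv,det_Cbc,prec_Cbc,det_Rad,prec_Rad,det_dtm,prec_dtm,det_oth,prec_oth
Cdv%v2,0.60,1,0.6,1228,9.6,60,26.7,76,44.7,627,89.8,52,57.7,295,96.6
Cdv%v2,0.60,13,14.5,1474,7.1,66,31.8,70,72.9,896,93.5,68,80.9,270,96.3
Cdv%v2,0.60,21,23.6,2787,8.4,192,60.4,93,24.7,1523,79.5,311,95.5,433,92.6
Cdv%v2,0.60,25,28.2,4005,8.0,371,77.6,78,28.2,1694,82.7,656,97.7,885,93.4
Cdv%v2,0.60,29,32.7,4527,7.9,418,78.7,74,23.0,1566,83.8,1348,97.0,763,91.5
Cdv%v2,0.95,1,0.6,1228,51.1,7,71.4,38,81.6,332,97.3,23,NA,200,NA
Cdv%v2,0.95,13,14.5,1474,45.5,11,90.9,42,69.0,536,95.7,41,NA,173,NA
Cdv%v2,0.95,21,23.6,2787,48.2,46,87.0,40,35.0,889,85.4,231,NA,237,NA
Cdv%v2,0.95,25,28.2,4005,47.9,117,93.2,34,44.1,858,90.7,515,NA,562,NA
Cdv%v2,0.95,29,32.7,4527,47.8,104,98.1,34,44.1,689,84.5,1078,NA,459,NA
Cdv%v2,0.95,33,37.3,4387,46.6,120,97.5,23,0.0,521,91.7,1529,NA,149,NA
Cdv%v2,0.95,37,41.8,4866,44.9,207,98.6,42,4.8,765,81.0,1462,NA,167,NA
Cdv%v2,0.95,41,46.3,3100,41.3,118,99.2,12,8.3,570,83.5,847,NA,270,NA
Cdv%v6R,0.95,1,0.6,2174,47.0,14,78.6,34,82.4,340,85.3,766,NA,88,NA
Cdv%v6R,0.95,13,14.5,2387,44.5,26,88.5,52,59.6,756,90.2,804,NA,12,NA
Cdv%v6R,0.95,21,23.6,5581,47.9,182,88.5,91,48.4,1428,83.0,508,NA,697,NA
Cdv%v6R,0.95,25,28.2,4458,48.3,253,96.1,61,32.8,1070,82.2,396,NA,527,NA
Cdv%v6R,0.95,29,32.7,6602,49.0,331,96.4,89,13.5,1596,62.4,901,NA,452,NA
Cdv%v6R,0.95,33,37.3,6030,48.8,357,97.8,125,3.2,1446,72.9,798,NA,364,NA
Cdv%v6R,0.95,37,41.8,6281,47.2,464,97.0,87,2.3,1466,78.9,835,NA,466,NA
Cdv%v6R,0.95,41,46.3,4539,48.1,223,96.9,42,2.4,984,72.6,634,NA,474,NA
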