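item,unit,price,source
surgeon_per_min,minute,2.40,staff bands (synthetic)
anaesthetist_per_min,minute,2.40,staff bands (synthetic)
nurse_band5_per_min,minute,0.73,staff bands (synthetic)
nurse_band4_per_min,minute,0.62,staff bands (synthetic)
theatre_per_min,minute,12.00,theatre (synthetic)
device_minisling,device,350.00,list price (synthetic)
device_standardsling,device,180.00,list price (synthetic)
anaesthesia_general,episode,30.00,medications (synthetic)
anaesthesia_spinal,episode,25.00,medications (synthetic)
anaesthesia_la_iv,episode,18.00,medications (synthetic)
anaesthesia_la_oral,episode,10.00,medications (synthetic)
anaesthesia_la_only,episode,8.00,medications (synthetic)
recovery_per_min,minute,1.00,theatre (synthetic)
ward_day,day,250.00,reference costs (synthetic)
catheter,item,5.50,catheters (synthetic)
return_to_theatre,episode,500.00,theatre (synthetic)
gp_visit,visit,39.00,primary care (synthetic)
nurse_visit,visit,11.00,primary care (synthetic)
physio_visit,visit,55.00,primary care (synthetic)
district_nurse_visit,visit,40.00,primary care (synthetic)
outpatient_visit,visit,125.00,reference costs (synthetic)
inpatient_day,day,350.00,reference costs (synthetic)
further_procedure,procedure,1400.00,reference costs (synthetic)
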