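"column","type","units","allowed","required","min","max"
"patient_id","id","","",TRUE,,
"site_id","id","","",TRUE,,
"age_years","numeric","years","",FALSE,0.0794520547945206,14
"sex","enum","","F|M",FALSE,,
"weight_kg","numeric","kg","",FALSE,0.5,150
"admission_spo2_pct","numeric","%","",FALSE,0,100
"muac_cm","numeric","cm","",FALSE,3,40
"waz","numeric","z-score","",FALSE,-10,10
"reported_malnutrition","logical","","",FALSE,,
"cyanotic_chd","logical","","",FALSE,,
"prior_pulmonary_disease","logical","","",FALSE,,
"lods_prostration_or_feed","logical","","",FALSE,,
"lods_coma","logical","","",FALSE,,
"lods_deep_breathing","logical","","",FALSE,,
"final_diagnoses","character","","",FALSE,,
"cxr_obtained","logical","","",FALSE,,
"cxr_opacity","logical","","",FALSE,,
"cxr_opacity_attributed_nonparenchymal","logical","","",FALSE,,
"sedation_gt4h","logical","","",FALSE,,
"vasoactives","logical","","",FALSE,,
"died","logical","","",FALSE,,
"died_in_ed","logical","","",FALSE,,
"ed_death_spo2_pct","numeric","%","",FALSE,0,100
"ed_death_on_oxygen","logical","","",FALSE,,
"admitted","logical","","",FALSE,,
"los_days","numeric","days","",FALSE,0,365
"d1_spo2_min","numeric","%","",FALSE,0,100
"d1_support","enum","","IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE",FALSE,,
"d1_interface","enum","","NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE",FALSE,,
"d1_fio2","numeric","fraction","",FALSE,0.21,1
"d1_flow_lpm","numeric","L/min","",FALSE,0,80
"d1_map_cmh2o","numeric","cmH2O","",FALSE,0.1,60
"d2_spo2_min","numeric","%","",FALSE,0,100
"d2_support","enum","","IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE",FALSE,,
"d2_interface","enum","","NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE",FALSE,,
"d2_fio2","numeric","fraction","",FALSE,0.21,1
"d2_flow_lpm","numeric","L/min","",FALSE,0,80
"d2_map_cmh2o","numeric","cmH2O","",FALSE,0.1,60
"d3_spo2_min","numeric","%","",FALSE,0,100
"d3_support","enum","","IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE",FALSE,,
"d3_interface","enum","","NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE",FALSE,,
"d3_fio2","numeric","fraction","",FALSE,0.21,1
"d3_flow_lpm","numeric","L/min","",FALSE,0,80
"d3_map_cmh2o","numeric","cmH2O","",FALSE,0.1,60
"d4_spo2_min","numeric","%","",FALSE,0,100
"d4_support","enum","","IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE",FALSE,,
"d4_interface","enum","","NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE",FALSE,,
"d4_fio2","numeric","fraction","",FALSE,0.21,1
"d4_flow_lpm","numeric","L/min","",FALSE,0,80
"d4_map_cmh2o","numeric","cmH2O","",FALSE,0.1,60
"d5_spo2_min","numeric","%","",FALSE,0,100
"d5_support","enum","","IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE",FALSE,,
"d5_interface","enum","","NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE",FALSE,,
"d5_fio2","numeric","fraction","",FALSE,0.21,1
"d5_flow_lpm","numeric","L/min","",FALSE,0,80
"d5_map_cmh2o","numeric","cmH2O","",FALSE,0.1,60
"d6_spo2_min","numeric","%","",FALSE,0,100
"d6_support","enum","","IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE",FALSE,,
"d6_interface","enum","","NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE",FALSE,,
"d6_fio2","numeric","fraction","",FALSE,0.21,1
"d6_flow_lpm","numeric","L/min","",FALSE,0,80
"d6_map_cmh2o","numeric","cmH2O","",FALSE,0.1,60
"d7_spo2_min","numeric","%","",FALSE,0,100
"d7_support","enum","","IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE",FALSE,,
"d7_interface","enum","","NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE",FALSE,,
"d7_fio2","numeric","fraction","",FALSE,0.21,1
"d7_flow_lpm","numeric","L/min","",FALSE,0,80
"d7_map_cmh2o","numeric","cmH2O","",FALSE,0.1,60
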