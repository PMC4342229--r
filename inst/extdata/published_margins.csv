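table,item,value
cohort,n_workers,25757
cohort,monitored_for_pu,7059
cohort,monitored_pct_printed,27.4
followup,migrants_censored_2003,4497
followup,migrated_2004_2008,132
followup,lost_before_2004,1264
followup,lost_total_printed,5893
followup,lost_pct_printed,22.9
hire,people_1948_53,9213
hire,people_1954_58,4221
hire,people_1959_63,4378
hire,people_1964_72,3675
hire,people_1973_82,4270
table6,stomach_male,374
table6,stomach_female,78
table6,colon_male,110
table6,colon_female,46
table6,rectum_male,103
table6,rectum_female,43
table6,pancreas_male,103
table6,pancreas_female,25
table6,breast_male,0
table6,breast_female,107
table6,prostate_male,80
table6,prostate_female,0
table6,kidney_male,61
table6,kidney_female,17
table6,melanoma_male,23
table6,melanoma_female,15
table6,larynx_male,66
table6,larynx_female,2
table6,esophagus_male,58
table6,esophagus_female,8
table6,brain_male,58
table6,brain_female,8
table6,bladder_male,62
table6,bladder_female,1
table6,ovary_male,0
table6,ovary_female,43
table6,uterus_male,0
table6,uterus_female,36
table6,other_male,236
table6,other_female,65
table6,group_total_male_printed,1334
table6,group_total_female_printed,491
table6,group_total_printed,1825
table6,pu_sites_male,849
table6,pu_sites_female,125
table6,hematopoietic_male,135
table6,hematopoietic_female,46
table6,all_cancer_male_printed,2318
table6,all_cancer_female_printed,662
table6,all_cancer_total_printed,2980
table4,deaths_cat1,246
table4,deaths_cat2,168
table4,deaths_cat3,213
table4,deaths_cat4,216
table4,deaths_cat5,342
table4,deaths_cat6,282
table4,deaths_cat7,271
table4,deaths_cat8,63
table4,deaths_cat9,24
table4,deaths_total_printed,1825
table4,py_cat1,277422
table4,py_cat2,140927
table4,py_cat3,98648
table4,py_cat4,106818
table4,py_cat5,141808
table4,py_cat6,93270
table4,py_cat7,72944
table4,py_cat8,15146
table4,py_cat9,3913
table4,py_total_printed,950894
table4,py_total_text,950896
table4,background_adjusted_total,1715.4
table4,excess_external_adjusted_total,96.9
table4,excess_internal_adjusted_total,12.7
table4,background_unadjusted_total,1697.1
table4,excess_unadjusted_total,127.9
table2,people_cat0,9293
table2,people_cat1,4891
table2,people_cat2,5931
table2,people_cat3,5329
table2,people_cat4,740
table2,people_cat5,573
table2,people_total_printed,25757
table8,err_male,0.30
table8,err_female,0.52
table8,weight_male,0.75
table8,err_total_printed,0.35
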