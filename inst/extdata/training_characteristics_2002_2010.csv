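variable,category,sex,group,count,pct
total,all,male,control,316574,
total,all,male,case,6713,
total,all,female,control,329016,
total,all,female,case,2186,
age,15-39,male,control,122712,38.76
age,15-39,male,case,1948,29.01
age,15-39,female,control,120116,36.50
age,15-39,female,case,612,27.99
age,40-59,male,control,108687,34.33
age,40-59,male,case,2998,44.65
age,40-59,female,control,108740,33.05
age,40-59,female,case,1043,47.71
age,>=60,male,control,85175,26.90
age,>=60,male,case,1767,26.32
age,>=60,female,control,100160,30.44
age,>=60,female,case,531,24.29
urbanicity,rural_town,male,control,62682,19.80
urbanicity,rural_town,male,case,1962,29.22
urbanicity,rural_town,female,control,60449,18.37
urbanicity,rural_town,female,case,478,21.86
social_deprivation,1,male,control,60096,18.98
social_deprivation,1,male,case,1167,17.38
social_deprivation,1,female,control,59127,17.97
social_deprivation,1,female,case,310,14.18
social_deprivation,2,male,control,60283,19.04
social_deprivation,2,male,case,1323,19.70
social_deprivation,2,female,control,60002,18.23
social_deprivation,2,female,case,339,15.50
social_deprivation,3,male,control,59937,18.93
social_deprivation,3,male,case,1223,18.21
social_deprivation,3,female,control,61491,18.68
social_deprivation,3,female,case,358,16.37
social_deprivation,4,male,control,58681,18.53
social_deprivation,4,male,case,1162,17.30
social_deprivation,4,female,control,62807,19.08
social_deprivation,4,female,case,427,19.53
social_deprivation,5,male,control,58620,18.51
social_deprivation,5,male,case,1427,21.25
social_deprivation,5,female,control,63683,19.35
social_deprivation,5,female,case,592,27.08
material_deprivation,1,male,control,58609,18.51
material_deprivation,1,male,case,875,13.03
material_deprivation,1,female,control,62815,19.09
material_deprivation,1,female,case,323,14.77
material_deprivation,2,male,control,58650,18.52
material_deprivation,2,male,case,1034,15.40
material_deprivation,2,female,control,61194,18.59
material_deprivation,2,female,case,365,16.69
material_deprivation,3,male,control,60167,19.00
material_deprivation,3,male,case,1274,18.97
material_deprivation,3,female,control,61428,18.67
material_deprivation,3,female,case,378,17.29
material_deprivation,4,male,control,60102,18.98
material_deprivation,4,male,case,1450,21.59
material_deprivation,4,female,control,61349,18.64
material_deprivation,4,female,case,449,20.53
material_deprivation,5,male,control,60089,18.98
material_deprivation,5,male,case,1669,24.86
material_deprivation,5,female,control,60324,18.33
material_deprivation,5,female,case,511,23.37
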