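"individual_id","sex","age_years","age_class","area","day1_date","day2_date","day1_holiday","day2_holiday"
"m_10-17_0001","male",16.4089769218117,"10-17","Centre",306,331,FALSE,FALSE
"m_10-17_0002","male",16.8830174040049,"10-17","Northeast",118,137,FALSE,FALSE
"m_18-64_0001","male",50.4398316876031,"18-64","Northwest",41,71,TRUE,FALSE
"m_18-64_0002","male",44.7544751586393,"18-64","Centre",90,124,FALSE,FALSE
"f_3-9_0001","female",4.14190690778196,"3-9","South and Islands",74,98,FALSE,FALSE
"f_3-9_0002","female",9.69000710151158,"3-9","Centre",178,204,FALSE,FALSE
"f_18-64_0001","female",36.5943431940395,"18-64","Northeast",226,253,FALSE,FALSE
"f_18-64_0002","female",42.4812898004893,"18-64","Northwest",48,81,FALSE,FALSE
"f_65-74_0001","female",71.9693564111367,"65-74","Northeast",200,235,TRUE,FALSE
"f_65-74_0002","female",65.9673983706161,"65-74","Northwest",125,148,FALSE,FALSE
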