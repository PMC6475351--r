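household_id,cluster_id,year,cig_expenditure,cig_quantity,quantity_unit,total_expenditure,hh_size,prop_adults,prop_males,educ_years_head,age_head,gender_head,work_head
h001,c01,2005,2000,1,pack,30000,5,0.6,0.5,7,42,male,employed
h002,c01,2005,3000,40,stick,41000,4,0.5,0.55,10,38,male,employed
h003,c01,2005,1500,20,stick,26000,6,0.45,0.5,4,55,male,not_employed
h004,c02,2005,2500,1.5,pack,52000,3,0.7,0.35,12,33,female,employed
h005,c02,2005,1800,24,stick,28000,7,0.5,0.6,0,47,male,employed
h006,c03,2005,1200,16,stick,22000,5,0.55,0.45,6,41,male,employed
h007,c03,2005,2600,1.2,pack,47000,4,0.6,0.5,9,36,male,employed
h008,c03,2005,900,12,stick,18500,8,0.4,0.55,3,60,male,not_employed
h009,c04,2005,0,,pack,25000,5,0.5,0.5,5,44,male,employed
h010,c04,2005,2200,1,pack,39000,6,0.55,0.5,8,39,female,employed
h011,c04,2005,1600,22,stick,27000,4,0.65,0.45,7,35,male,employed
h012,c05,2005,2400,,pack,43000,5,0.6,0.5,11,40,male,employed
h013,c05,2005,1400,18,stick,24500,6,0.5,0.55,2,52,male,employed
h014,c05,2005,2100,1.1,pack,36000,3,0.75,0.4,13,31,male,employed
h015,c05,2005,0,,pack,21000,7,0.45,0.5,4,49,male,not_employed
h016,c02,2005,1900,26,stick,33000,5,0.55,0.5,6,43,male,employed
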