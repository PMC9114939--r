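quantity,group,value,unit
n_vocal_clans,ETP,5,count
clan_size_individuals,ETP,10000,individuals
mean_social_unit_size,Regular,13.6,individuals
mean_social_unit_size,PlusOne,10.7,individuals
mean_group_size,ETP,30.4,individuals
displacement_3h,Regular,10.2,km
displacement_3h,PlusOne,10.7,km
displacement_6h,Regular,16.8,km
displacement_6h,PlusOne,19.4,km
daily_rms_displacement,ETP,50,km
yearly_displacement,ETP,1000,km
max_female_displacement,ETP,5000,km
range_span,ETP,1500,km
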