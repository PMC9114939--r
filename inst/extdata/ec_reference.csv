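quantity,group,value,unit
n_vocal_clans,EC,3,count
clan_size_individuals,EC,300,individuals
mean_social_unit_size,EC1,6.8,individuals
mean_social_unit_size,EC2,8.1,individuals
mean_group_size,EC,8,individuals
displacement_3h,EC1,8.0,km
displacement_3h,EC2,7.0,km
displacement_6h,EC1,13.7,km
displacement_6h,EC2,12.3,km
daily_rms_displacement,EC,15,km
yearly_displacement,EC,100,km
max_female_displacement,EC,350,km
range_span,EC,300,km
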