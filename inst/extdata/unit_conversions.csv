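variable,from_unit,to_unit,factor,offset,note
stress,ug/dL,nmol/L,27.59,0,cortisol molar-mass conversion (MW 362.46)
stress,nmol/L,ug/dL,0.036245,0,inverse cortisol conversion
sleep,minutes,hours,0.016667,0,60 minutes per hour
sleep,hours,minutes,60,0,
reaction_time,s,ms,1000,0,
reaction_time,ms,s,0.001,0,
executive_function,percent,proportion,0.01,0,
perceptuo_motor,percent,proportion,0.01,0,
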