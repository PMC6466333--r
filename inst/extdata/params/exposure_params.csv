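parameter,metal,value,unit,description
IR_p,,100,mg/day,adult soil ingestion rate
EF_a,,250,day/yr,exposure frequency
ED_a,,25,yr,exposure duration
BW,,56.8,kg,adult body weight
LT,,26280,day,averaging (lifetime) exposure time
EV,,1,1/day,dermal contact event frequency
SA,,1.614,m2,total skin surface area
mu,,0.18,fraction,fraction of skin exposed
eta,,0.2,mg/cm2,soil-to-skin adherence factor
omega,,0.15,mg/m3,suspended particulate concentration in air
IR_b,,14.5,m3/day,breathing rate
f_spod,,0.8,fraction,soil fraction of suspended particles outdoors
EFOD_a,,87.5,day/yr,outdoor exposure frequency
f_spid,,0.5,fraction,soil fraction of suspended particles indoors
EFID_a,,262.5,day/yr,indoor exposure frequency
beta,Cr,2.5e-2,fraction,gastrointestinal absorption coefficient
beta,Ni,1.6e-2,fraction,gastrointestinal absorption coefficient
beta,Cu,1.0,fraction,gastrointestinal absorption coefficient
beta,Zn,1.0,fraction,gastrointestinal absorption coefficient
beta,As,1.0,fraction,gastrointestinal absorption coefficient
beta,Cd,5.0e-2,fraction,gastrointestinal absorption coefficient
beta,Pb,1.0,fraction,gastrointestinal absorption coefficient
gamma,Cr,1.0e-3,fraction,skin absorption coefficient
gamma,Ni,1.6e-2,fraction,skin absorption coefficient
gamma,Cu,1.0e-3,fraction,skin absorption coefficient
gamma,Zn,6.0e-4,fraction,skin absorption coefficient
gamma,As,1.0e-3,fraction,skin absorption coefficient
gamma,Cd,1.0e-3,fraction,skin absorption coefficient
gamma,Pb,2.08e-5,fraction,skin absorption coefficient
theta,Cr,1.0,fraction,lung absorption coefficient (assumed)
theta,Ni,0.016,fraction,lung absorption coefficient
theta,Cu,0.3,fraction,lung absorption coefficient
theta,Zn,0.2,fraction,lung absorption coefficient
theta,As,1.0,fraction,lung absorption coefficient (assumed)
theta,Cd,0.01,fraction,lung absorption coefficient
theta,Pb,0.15,fraction,lung absorption coefficient
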