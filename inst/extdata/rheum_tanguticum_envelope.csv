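variable,unit,min,max,mean,se,n,f_value,cv_pct
elevation,m,1980,4550,3630,44,206,191.2,17.4
relative_humidity,%,54.8,69.0,63.7,2.2,206,219.3,49.6
sunshine_duration,hr/yr,1897,2704,2450,13,206,301.7,7.6
annual_precipitation,mm,331,839,574,7,206,233.2,17.5
accumulated_temperature,degC,3193,22451,9517,951,206,277.1,143.4
mean_annual_temperature,degC,5.1,13.1,8.6,0.1,206,92.6,16.7
mean_march_temperature,degC,-8.0,-2.0,-4.5,0.2,206,42.3,63.8
minimum_temperature,degC,-24.8,-10.6,-19.1,0.2,206,165.8,15.0
maximum_temperature,degC,12.9,24.4,17.2,0.2,206,119.5,16.7
mean_minimum_temperature,degC,-15.6,-5.1,-11.2,0.2,206,129.8,25.6
mean_maximum_temperature,degC,6.0,18.2,10.4,0.2,206,103.3,27.6
soil_ph,pH,5.9,8.5,6.8,0.1,206,112.4,21.1
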