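process,item,gas,factor,unit,source
ENTERIC,dairy_cattle,CH4,100,head,illustrative
ENTERIC,beef_cattle,CH4,60,head,illustrative
ENTERIC,sheep,CH4,8,head,illustrative
ENTERIC,swine,CH4,1.5,head,illustrative
MANURE,dairy_cattle:anaerobic_digester,CH4,4,head,illustrative
MANURE,dairy_cattle:anaerobic_digester,N2O,0,head,illustrative
MANURE,dairy_cattle:liquid_storage,CH4,20,head,illustrative
MANURE,dairy_cattle:liquid_storage,N2O,0.01,head,illustrative
MANURE,dairy_cattle:solid_storage,CH4,2,head,illustrative
MANURE,dairy_cattle:solid_storage,N2O,0.05,head,illustrative
MANURE,dairy_cattle:daily_spread,CH4,0.4,head,illustrative
MANURE,dairy_cattle:daily_spread,N2O,0.002,head,illustrative
MANURE,dairy_cattle:pasture,CH4,0.6,head,illustrative
MANURE,dairy_cattle:pasture,N2O,0.01,head,illustrative
MANURE,sheep:solid_storage,CH4,0.2,head,illustrative
MANURE,sheep:solid_storage,N2O,0.005,head,illustrative
MANURE,sheep:pasture,CH4,0.1,head,illustrative
MANURE,sheep:pasture,N2O,0.002,head,illustrative
SOIL_N2O,synthetic_fertilizer,N2O,0.01,kg N,illustrative
SOIL_N2O,manure,N2O,0.01,kg N,illustrative
SOIL_N2O,sewage_sludge,N2O,0.01,kg N,illustrative
SOIL_N2O,digestate,N2O,0.01,kg N,illustrative
SOIL_N2O,compost,N2O,0.01,kg N,illustrative
SOIL_N2O,crop_residues,N2O,0.01,kg N,illustrative
SOIL_N2O,urine_dung,N2O,0.02,kg N,illustrative
FUEL,diesel,CO2,2.7,L,illustrative
FUEL,diesel,CH4,0,L,illustrative
FUEL,diesel,N2O,0,L,illustrative
FUEL,petrol,CO2,2.3,L,illustrative
FUEL,petrol,CH4,0,L,illustrative
FUEL,petrol,N2O,0,L,illustrative
FUEL,natural_gas,CO2,2,m3,illustrative
FUEL,natural_gas,CH4,0.0001,m3,illustrative
FUEL,natural_gas,N2O,0,m3,illustrative
FUEL,coal,CO2,2.4,kg,illustrative
FUEL,coal,CH4,0.0003,kg,illustrative
FUEL,coal,N2O,0.00004,kg,illustrative
FUEL,biomass,CO2,0,kg,illustrative
FUEL,biomass,CH4,0.003,kg,illustrative
FUEL,biomass,N2O,0.0001,kg,illustrative
ENERGY_S2,electricity,CO2,0.5,kWh,illustrative
ENERGY_S2,electricity,CH4,0,kWh,illustrative
ENERGY_S2,electricity,N2O,0,kWh,illustrative
ENERGY_S2,heat,CO2,0.25,kWh,illustrative
ENERGY_S2,heat,CH4,0,kWh,illustrative
ENERGY_S2,heat,N2O,0,kWh,illustrative
ENERGY_S2,cold,CO2,0.6,kWh,illustrative
ENERGY_S2,cold,CH4,0,kWh,illustrative
ENERGY_S2,cold,N2O,0,kWh,illustrative
COMPOST,composted_waste,CH4,4,t,illustrative
COMPOST,composted_waste,N2O,0.12,t,illustrative
WASTEWATER,cod,CH4,0.25,kg COD,illustrative
INPUT,seeds,CO2eq,500,t,illustrative
INPUT,pesticides,CO2eq,10000,t,illustrative
INPUT,synthetic_fertilizers,CO2eq,3000,t,illustrative
INPUT,livestock,CO2eq,1500,head,illustrative
INPUT,industrial_feed,CO2eq,700,t,illustrative
INPUT,silage,CO2eq,150,t,illustrative
INPUT,hay,CO2eq,100,t,illustrative
INPUT,water,CO2eq,0.3,m3,illustrative
INPUT,refrigerant,CO2eq,10,kg,illustrative
INPUT,diesel_upstream,CO2eq,0.6,L,illustrative
INPUT,plastic,CO2eq,2000,t,illustrative
INPUT,paper,CO2eq,900,t,illustrative
INPUT,concrete,CO2eq,150,t,illustrative
INPUT,iron,CO2eq,1800,t,illustrative
CAPITAL,tractor,CO2eq,60000,unit,illustrative
CAPITAL,harvester,CO2eq,100000,unit,illustrative
CAPITAL,tillage_machine,CO2eq,15000,unit,illustrative
CAPITAL,truck,CO2eq,40000,unit,illustrative
CAPITAL,car,CO2eq,25000,unit,illustrative
CAPITAL,computer,CO2eq,300,unit,illustrative
CAPITAL,solar_panel,CO2eq,2500,unit,illustrative
WASTE_OFFSITE,paper,CO2eq,1000,t,illustrative
WASTE_OFFSITE,plastic,CO2eq,100,t,illustrative
WASTE_OFFSITE,metal,CO2eq,50,t,illustrative
WASTE_OFFSITE,bio,CO2eq,200,t,illustrative
WASTE_OFFSITE,glass,CO2eq,20,t,illustrative
WASTE_OFFSITE,construction,CO2eq,10,t,illustrative
WASTE_OFFSITE,municipal,CO2eq,500,t,illustrative
WASTE_OFFSITE,other,CO2eq,400,t,illustrative
SINK,cropland_tillage,CO2,0,kg C per ha per yr,illustrative
SINK,cropland_no_till,CO2,60,kg C per ha per yr,illustrative
SINK,grassland,CO2,80,kg C per ha per yr,illustrative
SINK,builtup,CO2,0,kg C per ha per yr,illustrative
SINK_CONVERSION,grassland_to_cropland,CO2,-500,kg C per ha conversion,illustrative
SINK_CONVERSION,cropland_to_grassland,CO2,300,kg C per ha conversion,illustrative
SINK_CONVERSION,forest_to_cropland,CO2,-800,kg C per ha conversion,illustrative
SINK_CONVERSION,forest_to_grassland,CO2,-400,kg C per ha conversion,illustrative
SINK_CONVERSION,cropland_to_forest,CO2,600,kg C per ha conversion,illustrative
SINK_CONVERSION,grassland_to_forest,CO2,500,kg C per ha conversion,illustrative
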