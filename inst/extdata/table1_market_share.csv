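# Company roster and market shares of the 33 assessed companies (2016
# Euromonitor retail-value shares as published in the study's roster table).
# Subcategory assignments are fixture design: each company is keyed to its
# leading category (retailers to distinct retail channels, reflecting that
# every retailer led its channel). retail_value is share_pct expressed in an
# arbitrary currency unit (40 per share point); the study's absolute retail
# values are not public. The study did not disclose which 6 companies
# participated, so participating is FALSE throughout this fixture.
company_id,name,sector,scope,participating,listed,subcategory,retail_value,share_pct
fraser_neave,Fraser & Neave,manufacturer,regional,FALSE,TRUE,ice_cream,452,11.3
nestle,Nestle,manufacturer,global,FALSE,TRUE,confectionery,436,10.9
yeo_hiap_seng,Yeo Hiap Seng,manufacturer,regional,FALSE,FALSE,ready_meals,240,6.0
mondelez,Mondelez,manufacturer,global,FALSE,FALSE,biscuits,160,4.0
etika_group,Etika Group,manufacturer,global,FALSE,FALSE,dairy,148,3.7
campbells_soup,Campbell's Soup,manufacturer,global,FALSE,FALSE,soup,136,3.4
malaysia_milk,Malaysia Milk,manufacturer,regional,FALSE,FALSE,drinking_milk,132,3.3
unilever,Unilever,manufacturer,global,FALSE,FALSE,ice_cream,128,3.2
coca_cola,Coca-Cola,manufacturer,global,FALSE,FALSE,carbonates,124,3.1
fonterra,Fonterra,manufacturer,global,FALSE,FALSE,cheese,88,2.2
kelloggs,Kellogg's,manufacturer,global,FALSE,FALSE,rte_cereal,88,2.2
barkath_coro,Barkath Co-Ro,manufacturer,global,FALSE,FALSE,concentrates,64,1.6
dutch_lady,Dutch Lady,manufacturer,global,FALSE,TRUE,drinking_milk,60,1.5
mamee,Mamee,manufacturer,national,FALSE,FALSE,savoury_snacks,56,1.4
gardenia,Gardenia,manufacturer,regional,FALSE,FALSE,baked_goods,48,1.2
hup_seng,Hup Seng,manufacturer,national,FALSE,TRUE,biscuits,32,0.8
munchys,Munchy's,manufacturer,national,FALSE,FALSE,biscuits,32,0.8
ferrero,Ferrero,manufacturer,global,FALSE,FALSE,confectionery,24,0.6
ayam_brand,Ayam Brand,manufacturer,global,FALSE,FALSE,processed_meat,24,0.6
massimo,Massimo,manufacturer,national,FALSE,FALSE,baked_goods,24,0.6
ayamas,Ayamas,manufacturer,national,FALSE,FALSE,processed_meat,12,0.3
ramly,Ramly,manufacturer,national,FALSE,FALSE,processed_meat,12,0.3
pizza_hut,Pizza Hut,qsr,global,FALSE,FALSE,pizza_foodservice,1052,26.3
kfc,KFC,qsr,global,FALSE,FALSE,fast_food,840,21.0
dominos,Domino's,qsr,global,FALSE,FALSE,pizza_foodservice,632,15.8
mcdonalds,McDonald's,qsr,global,FALSE,FALSE,fast_food,552,13.8
dunkin_donuts,Dunkin' Donuts,qsr,global,FALSE,FALSE,fast_food,96,2.4
giant,Giant,retailer,global,FALSE,FALSE,hypermarkets,372,9.3
tesco,Tesco,retailer,global,FALSE,FALSE,supermarkets,280,7.0
seven_eleven,7-Eleven,retailer,global,FALSE,TRUE,convenience_stores,136,3.4
aeon_group,Aeon Group,retailer,global,FALSE,TRUE,department_grocery,116,2.9
econsave,Econsave,retailer,national,FALSE,FALSE,discount_stores,104,2.6
mydin,Mydin,retailer,national,FALSE,FALSE,wholesale_grocery,40,1.0
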