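food_id,name,food_group,energy_density,protein_density,source
C01,steamed white rice,cereals and products,130,2.4,cereals
C02,boiled wheat noodles,cereals and products,138,4.5,cereals
C03,white bread,cereals and products,265,9.0,cereals
L01,tempeh fried,legumes and products,192,20.8,legumes
L02,tofu,legumes and products,76,8.0,legumes
L03,peanuts roasted,legumes and products,567,25.8,legumes
E01,chicken egg boiled,eggs,155,12.6,eggs
D01,sweetened condensed milk,milk and products,321,7.9,dairy
D02,fresh cow milk,milk and products,61,3.2,dairy
B01,beef cooked,meat and products,250,26.0,beef
B02,goat meat cooked,meat and products,143,27.0,beef
P01,pork cooked,meat and products,297,25.7,pork
Y01,chicken meat cooked,poultry,239,27.3,poultry
Y02,chicken fried with skin,poultry,260,28.0,poultry
F01,mackerel fried,fish and seafood,206,22.0,fish
F02,dried anchovy,fish and seafood,170,33.0,fish
F03,tuna cooked,fish and seafood,132,28.0,fish
N01,coconut cooking oil,oils and fats,884,0.0,non_protein_source
N02,cassava boiled,tubers,160,1.4,non_protein_source
N03,water spinach cooked,vegetables,36,3.4,non_protein_source
N04,banana,fruits,89,1.1,non_protein_source
N05,granulated sugar,sugars,387,0.0,non_protein_source
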