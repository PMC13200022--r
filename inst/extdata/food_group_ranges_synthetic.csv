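group,moisture_lo,moisture_hi,energy_kcal_lo,energy_kcal_hi,protein_g_lo,protein_g_hi,fat_g_lo,fat_g_hi,calcium_mg_lo,calcium_mg_hi,iron_mg_lo,iron_mg_hi,zinc_mg_lo,zinc_mg_hi,folate_ug_lo,folate_ug_hi,vitamin_a_ug_lo,vitamin_a_ug_hi,vitamin_b6_mg_lo,vitamin_b6_mg_hi,vitamin_b12_ug_lo,vitamin_b12_ug_hi,price_lo,price_hi
cereals_millets,9,13,320,360,6,12,1,4,10,45,2,5,1.2,3,15,50,0,5,0.1,0.5,0,0,25,50
pulses_legumes,8,12,315,350,20,25,1,6,50,150,4,8,2,4,100,250,0,10,0.2,0.6,0,0,80,140
milk_products,82,88,60,100,3,4.5,3.5,6,100,130,0,0.3,0.3,0.6,5,10,30,60,0.03,0.08,0.1,0.5,45,70
eggs,74,77,130,160,12,14,9,12,45,60,1.5,2.5,1,1.5,40,60,140,200,0.1,0.2,0.9,1.5,110,160
flesh_foods,70,76,100,160,18,22,2,8,5,20,1,3,1,3,5,15,10,50,0.3,0.6,0.5,3,180,350
green_leafy_veg,85,92,25,60,2,4.5,0.3,1,80,350,1.5,5,0.3,0.8,60,150,150,500,0.1,0.3,0,0,30,80
other_veg,88,94,20,50,1,2.5,0.1,0.5,15,60,0.3,1.5,0.2,0.6,20,80,5,100,0.05,0.2,0,0,25,60
roots_tubers,75,85,70,115,1,2.5,0.1,0.4,10,40,0.3,1,0.2,0.5,10,30,0,10,0.1,0.3,0,0,20,45
fruits,75,88,40,110,0.5,1.5,0.1,0.6,5,30,0.2,1,0.1,0.3,10,40,5,90,0.05,0.3,0,0,40,120
oils_fats,0,0.5,880,900,0,0,99,100,0,1,0,0.1,0,0.1,0,1,0,1,0,0.01,0,0,110,180
sugars,3,10,370,390,0.4,2,0,0.2,40,90,2,5,0.2,0.5,0,5,0,1,0,0.05,0,0,40,65
nuts_seeds,3,8,520,600,17,26,40,55,50,200,2,6,3,7,40,100,0,10,0.3,0.8,0,0,300,800
condiments_other,8,15,250,350,5,15,5,15,50,300,2,10,1,5,20,100,0,50,0.2,0.8,0,0,100,300
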