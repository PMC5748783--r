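"food_id","name","group","protein_g_per_100g","energy_kcal_per_100g","alcohol_kcal_per_100g","iaa_his","iaa_ile","iaa_leu","iaa_lys","iaa_saa","iaa_aaa","iaa_thr","iaa_trp","iaa_val","animal_protein_fraction","substitutable"
"beef_steak","Beef steak, grilled","red_meat","28.0","150","0","34","47","81","90","39","77","44","12","50","1.00","TRUE"
"roast_chicken","Chicken, roasted","poultry","26.5","150","0","30","48","76","85","40","73","43","12","49","1.00","TRUE"
"venison","Venison, cooked","game","22.0","115","0","34","47","81","90","39","77","44","12","50","1.00","TRUE"
"veal_liver","Veal liver, cooked","offal","24.0","135","0","27","46","86","75","38","82","42","13","57","1.00","TRUE"
"cooked_ham","Ham, cooked","delicatessen","21.0","120","0","40","46","78","87","38","74","43","12","50","1.00","TRUE"
"salmon","Salmon, baked","fish","25.0","200","0","29","46","81","91","41","75","44","11","51","1.00","TRUE"
"semi_skimmed_milk","Milk, semi-skimmed","milk","3.4","46","0","27","49","98","79","33","101","44","14","63","1.00","TRUE"
"plain_yogurt","Yogurt, plain","yogurt","4.0","60","0","27","49","98","79","33","101","44","14","63","1.00","TRUE"
"emmental","Emmental cheese","cheese","28.0","380","0","31","51","95","77","28","108","36","13","67","1.00","TRUE"
"fromage_blanc","Fromage blanc","other_dairy","7.5","100","0","27","49","98","79","33","101","44","14","63","1.00","TRUE"
"boiled_egg","Egg, boiled","eggs","12.5","143","0","24","53","86","72","55","94","47","17","66","1.00","TRUE"
"baguette","Baguette","cereals","9.9","265","0","23","37","69","28","40","78","29","12","44","0.00","TRUE"
"cooked_pasta","Pasta, cooked","cereals","5.5","147","0","23","37","69","30","40","78","29","12","44","0.00","TRUE"
"cooked_rice","Rice, cooked","cereals","4.9","130","0","24","42","82","35","42","89","35","13","58","0.00","TRUE"
"boiled_potatoes","Potatoes, boiled","potatoes","2.0","85","0","19","39","60","56","30","72","37","14","50","0.00","TRUE"
"apple","Apple","fruit","0.3","52","0","15","35","55","45","25","55","30","9","42","0.00","TRUE"
"green_beans","Green beans, cooked","vegetables","1.8","30","0","25","40","63","55","25","67","38","11","46","0.00","TRUE"
"almonds","Almonds","nuts_seeds","21.0","600","0","26","38","69","30","33","72","28","10","42","0.00","TRUE"
"cooked_lentils","Lentils, cooked","legumes","8.1","116","0","28","43","72","70","22","80","36","9","49","0.00","TRUE"
"cooked_chickpeas","Chickpeas, cooked","legumes","8.4","120","0","27","43","71","67","26","83","37","10","42","0.00","TRUE"
"tofu","Tofu, plain","other_plant","12.0","120","0","26","48","80","62","26","90","40","13","49","0.00","TRUE"
"vegetable_oil","Vegetable oil and fats","seasonings","0.0","884","0","0","0","0","0","0","0","0","0","0","0.00","TRUE"
"red_wine","Red wine","other_plant","0.2","15","68","25","40","63","55","25","67","38","11","46","0.00","TRUE"
"beef_lasagna","Beef lasagna (mixed dish)","cereals","7.5","160","0","29","45","79","65","37","82","38","12","50","0.55","FALSE"
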