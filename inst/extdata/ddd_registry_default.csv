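aai,long_acting,ddd_mg_per_kg_day,antimicrobial_class,hc_category
amoxicillin,FALSE,20,Penicillins,II
apramycin,FALSE,10,Aminoglycosides,II
avilamycin,FALSE,7,Orthosomycin,IV
bacitracin,FALSE,10,Bacitracins,III
benzathine_penicillin_g,FALSE,15,Penicillins,II
ceftiofur,FALSE,3,Cephalosporins,I
ceftiofur,TRUE,3,Cephalosporins,I
chlortetracycline,FALSE,20,Tetracyclines,III
enrofloxacin,FALSE,2.5,Fluoroquinolones,I
florfenicol,FALSE,15,Phenicols,III
gentamicin,FALSE,2,Aminoglycosides,II
lincomycin,FALSE,10,Lincosamides,II
oxytetracycline,FALSE,10,Tetracyclines,III
penicillin_g_potassium,FALSE,15,Penicillins,II
procaine_penicillin_g,FALSE,15,Penicillins,II
procaine_penicillin_g,TRUE,15,Penicillins,II
salinomycin,FALSE,3,Ionophores,IV
sulfadiazine,FALSE,8,Sulfonamides,III
sulfadoxine,FALSE,8,Sulfonamides,III
sulfamethazine,FALSE,25,Sulfonamides,III
sulfathiazole,FALSE,25,Sulfonamides,III
tetracycline,FALSE,20,Tetracyclines,III
tiamulin,FALSE,10,Pleuromutilins,uncategorized
tilmicosin,FALSE,16,Macrolides,II
trimethoprim,FALSE,1.6,Dihydrofolate reductase inhibitors,III
tulathromycin,FALSE,2.5,Macrolides,II
tylosin,FALSE,9,Macrolides,II
tylvalosin,FALSE,4,Macrolides,II
virginiamycin,FALSE,10,Streptogramins,II
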