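profession,year,band,headcount,uncertain
endocrinology,2023,metropolitan,1635,FALSE
gastroenterology_hepatology,2023,metropolitan,1992,FALSE
palliative_medicine,2023,metropolitan,463,FALSE
pain_medicine,2023,metropolitan,236,FALSE
general_surgery,2023,metropolitan,3174,FALSE
radiation_oncology,2023,metropolitan,734,FALSE
medical_oncology,2023,metropolitan,1588,FALSE
endocrinology,2023,regional_centres,55,TRUE
gastroenterology_hepatology,2023,regional_centres,49,TRUE
palliative_medicine,2023,regional_centres,53,TRUE
pain_medicine,2023,regional_centres,30,TRUE
general_surgery,2023,regional_centres,274,TRUE
radiation_oncology,2023,regional_centres,87,TRUE
medical_oncology,2023,regional_centres,166,TRUE
endocrinology,2023,large_rural,7,TRUE
gastroenterology_hepatology,2023,large_rural,19,TRUE
palliative_medicine,2023,large_rural,11,TRUE
pain_medicine,2023,large_rural,0,TRUE
general_surgery,2023,large_rural,296,TRUE
radiation_oncology,2023,large_rural,28,TRUE
medical_oncology,2023,large_rural,96,TRUE
endocrinology,2023,medium_small_rural_plus,7,TRUE
gastroenterology_hepatology,2023,medium_small_rural_plus,15,TRUE
palliative_medicine,2023,medium_small_rural_plus,3,TRUE
pain_medicine,2023,medium_small_rural_plus,0,TRUE
general_surgery,2023,medium_small_rural_plus,176,TRUE
radiation_oncology,2023,medium_small_rural_plus,0,TRUE
medical_oncology,2023,medium_small_rural_plus,3,TRUE
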