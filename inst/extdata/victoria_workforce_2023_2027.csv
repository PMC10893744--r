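profession,year,headcount
endocrinology,2023,1862
endocrinology,2024,1986
endocrinology,2025,2091
endocrinology,2026,2202
endocrinology,2027,2318
gastroenterology_hepatology,2023,2274
gastroenterology_hepatology,2024,2379
gastroenterology_hepatology,2025,2488
gastroenterology_hepatology,2026,2603
gastroenterology_hepatology,2027,2723
palliative_medicine,2023,601
palliative_medicine,2024,646
palliative_medicine,2025,695
palliative_medicine,2026,747
palliative_medicine,2027,803
pain_medicine,2023,310
pain_medicine,2024,336
pain_medicine,2025,364
pain_medicine,2026,395
pain_medicine,2027,429
general_surgery,2023,4135
general_surgery,2024,4248
general_surgery,2025,4364
general_surgery,2026,4483
general_surgery,2027,4605
radiation_oncology,2023,914
radiation_oncology,2024,946
radiation_oncology,2025,979
radiation_oncology,2026,1013
radiation_oncology,2027,1048
medical_oncology,2023,2104
medical_oncology,2024,2241
medical_oncology,2025,2388
medical_oncology,2026,2544
medical_oncology,2027,2711
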