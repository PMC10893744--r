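year,stage,cases,year_total
2023,I-II,198,991
2023,III,297,991
2023,IV,495,991
2024,I-II,206,1028
2024,III,308,1028
2024,IV,514,1028
2025,I-II,210,1051
2025,III,315,1051
2025,IV,526,1051
2026,I-II,215,1075
2026,III,323,1075
2026,IV,538,1075
2027,I-II,220,1100
2027,III,330,1100
2027,IV,550,1100
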