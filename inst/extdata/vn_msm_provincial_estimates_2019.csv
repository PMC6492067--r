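province,count_30d,count_method,proportion,prop_lo,prop_hi,pop_estimate,pop_lo,pop_hi,weighted_pct
Bac Giang,360,dedup,0.42,0.28,0.55,864,653,1274,0.23
Binh Dinh,260,dedup,0.35,0.23,0.47,743,559,1108,0.21
Can Tho,713,dedup,0.11,0.03,0.19,6276,3677,21418,1.22
Da Nang,1713,dedup,0.43,0.28,0.58,3990,2974,6059,1.70
Dak Lak,279,dedup,0.15,0.07,0.23,1895,1226,4180,0.46
Dong Nai,1191,capture_recapture,0.15,0.02,0.28,7759,4216,68370,1.10
Dong Thap,303,dedup,0.14,0.06,0.21,2181,1420,4711,0.48
Hanoi,12848,provider,0.42,0.32,0.52,30417,24656,39691,1.81
Hai Phong,1141,dedup,0.34,0.25,0.43,3336,2645,4515,0.73
Nam Dinh,446,dedup,0.39,0.26,0.52,1131,850,1687,0.29
Thanh Hoa,670,provider,0.22,0.11,0.33,3017,2032,5846,0.40
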