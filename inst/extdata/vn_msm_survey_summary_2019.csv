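province,participants,eligible,mean_age,mean_network_size,msm_by_preference,jackd_account,jackd_30d
An Giang,173,167,22,8,39,33,18
Bac Giang,132,125,28,46,28,77,52
Binh Dinh,134,126,27,5,26,101,43
Can Tho,195,167,23,6,28,37,19
Da Nang,193,167,24,5,17,114,80
Dak Lak,123,121,24,8,52,41,21
Dong Nai,238,227,25,7,15,69,17
Dong Thap,217,212,24,9,61,47,33
Hanoi,296,264,23,13,22,209,130
Hai Phong,345,279,25,10,70,155,96
Nam Dinh,132,122,25,10,21,84,65
Thanh Hoa,244,200,25,9,34,107,67
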