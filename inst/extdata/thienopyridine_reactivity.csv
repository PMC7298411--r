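compound_id,mu_eV,eta_eV,softness_published,omega_published
4,-3.7843,3.8036,0.2629,1.8825
9,-3.8531,3.7443,0.2670,1.9826
28,-2.8058,1.8096,0.5526,2.1752
29,-2.7818,1.7660,0.5662,2.1910
32,-2.4749,1.6359,0.6112,1.8720
37,-3.5558,3.3342,0.2999,1.8961
39,-2.8369,1.6847,0.5936,2.3887
43,-3.5617,3.6267,0.2757,1.7489
44,-3.5320,3.5277,0.2835,1.7682
46,-3.6697,3.6256,0.2758,1.8572
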