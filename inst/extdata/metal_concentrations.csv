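metal,category,mean,sd,n_samples
iAs,pelagic_fish,0.0006,0.0011,26
iAs,inshore_fish,0.0023,0.0036,45
iAs,other_fish,0.0024,0.0036,98
iAs,crustaceans,0.0027,0.0046,324
iAs,shellfish,0.025,0.0054,3
iAs,cephalopods,0.0042,0.0096,16
iAs,algae,0.036,0.054,18
Cd,pelagic_fish,0.025,0.053,26
Cd,inshore_fish,0.0066,0.011,45
Cd,other_fish,0.0088,0.03,98
Cd,crustaceans,0.10,0.16,324
Cd,shellfish,1.25,3.06,3
Cd,cephalopods,0.43,0.78,16
Cd,algae,0.097,0.066,18
Co,pelagic_fish,0.003,0.002,26
Co,inshore_fish,0.006,0.009,45
Co,other_fish,0.0051,0.0049,98
Co,crustaceans,0.019,0.024,324
Co,shellfish,0.19,0.31,3
Co,cephalopods,0.0067,0.0081,16
Co,algae,0.024,0.024,18
Cr,pelagic_fish,0.10,0.16,26
Cr,inshore_fish,0.14,0.62,45
Cr,other_fish,0.063,0.11,98
Cr,crustaceans,0.22,0.52,324
Cr,shellfish,0.16,0.23,3
Cr,cephalopods,0.094,0.10,16
Cr,algae,0.20,0.18,18
Cu,pelagic_fish,1.23,1.61,26
Cu,inshore_fish,1.31,3.31,45
Cu,other_fish,2.97,8.01,98
Cu,crustaceans,9.34,4.24,324
Cu,shellfish,6.98,8.80,3
Cu,cephalopods,5.34,4.36,16
Cu,algae,2.61,3.44,18
Fe,pelagic_fish,5.15,4.06,26
Fe,inshore_fish,5.68,7.97,45
Fe,other_fish,6.17,8.90,98
Fe,crustaceans,10.45,14.42,324
Fe,shellfish,71.46,67.25,3
Fe,cephalopods,2.36,2.34,16
Fe,algae,39.84,52.52,18
Mn,pelagic_fish,0.09,0.03,26
Mn,inshore_fish,0.16,0.22,45
Mn,other_fish,0.35,1.23,98
Mn,crustaceans,0.83,0.86,324
Mn,shellfish,3.57,2.65,3
Mn,cephalopods,0.20,0.14,16
Mn,algae,6.19,9.68,18
Ni,pelagic_fish,0.05,0.07,26
Ni,inshore_fish,0.079,0.29,45
Ni,other_fish,0.037,0.072,98
Ni,crustaceans,0.15,0.27,324
Ni,shellfish,0.55,0.56,3
Ni,cephalopods,0.055,0.066,16
Ni,algae,0.12,0.091,18
Pb,pelagic_fish,0.002,0.002,26
Pb,inshore_fish,0.0052,0.0056,45
Pb,other_fish,0.0079,0.014,98
Pb,crustaceans,0.013,0.019,324
Pb,shellfish,0.082,0.071,3
Pb,cephalopods,0.015,0.017,16
Pb,algae,0.13,0.11,18
Sr,pelagic_fish,0.27,0.16,26
Sr,inshore_fish,0.80,1.04,45
Sr,other_fish,2.47,9.12,98
Sr,crustaceans,14.12,23.33,324
Sr,shellfish,6.29,3.59,3
Sr,cephalopods,2.63,1.18,16
Sr,algae,20.90,21.47,18
Tl,pelagic_fish,0.0002,0.0002,26
Tl,inshore_fish,0.00037,0.00031,45
Tl,other_fish,0.00069,0.001,98
Tl,crustaceans,0.00031,0.00026,324
Tl,shellfish,0.00074,0.00073,3
Tl,cephalopods,0.00020,0.00012,16
Tl,algae,0.00057,0.00050,18
Zn,pelagic_fish,4.78,1.45,26
Zn,inshore_fish,4.86,2.91,45
Zn,other_fish,6.49,7.23,98
Zn,crustaceans,23.87,13.85,324
Zn,shellfish,36.50,34.14,3
Zn,cephalopods,12.51,3.85,16
Zn,algae,3.88,3.43,18
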