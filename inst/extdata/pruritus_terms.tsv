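term	patients
Pruritus	40618
Rash Pruritic	6287
Injection Site Pruritus	3034
Application Site Pruritus	2401
Eye Pruritus	2278
Vulvovaginal Pruritus	647
Oral Pruritus	400
Ear Pruritus	294
Eyelids Pruritus	263
Anal Pruritus	253
Pruritus Genital	195
Pruritus Allergic	127
Tongue Pruritus	124
Infusion Site Pruritus	122
Implant Site Pruritus	97
Nasal Pruritus	89
Lip Pruritus	80
Instillation Site Pruritus	46
Catheter Site Pruritus	23
Gingival Pruritus	14
Itching Scar	7
Administration Site Pruritus	6
Incision Site Pruritus	6
Vaccination Site Pruritus	6
Aquagenic Pruritus	5
Cholestatic Pruritus	4
Stoma Site Pruritus	2
Vessel Puncture Site Pruritus	2
Medical Device Site Pruritus	1
Popular Pruritic Eruption of HIV	0
Vascular Access Site Pruritus	0
Tumor Pruritus	0
Post-Procedural Pruritus	0
Puncture Site Pruritus	0
Uraemic Pruritus	0
Senile Pruritus	0
Brachioradial Pruritus	0
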