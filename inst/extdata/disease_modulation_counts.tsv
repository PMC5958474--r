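disease	disease_class	n_modulated	reported_percent	reported_group
Coronary artery disease	inflammation	18	26	high
Acute coronary syndromes	inflammation	7	10	high
Hutchinson-Gilford progeria syndrome	inflammation	13	19	high
High glucose (25 mM)	inflammation	9	13	high
Type 2 diabetes	inflammation	7	10	high
Ovarian carcinomas	cancer	16	24	high
Esophageal squamous cell carcinoma	cancer	12	18	high
Breast cancer	cancer	12	18	high
Non-small cell lung cancers	cancer	12	18	high
Burkitt lymphoma	cancer	12	18	high
Adult male germ cell tumors	cancer	10	15	high
Clear cell renal cell carcinomas	cancer	9	13	high
Colorectal carcinoma	cancer	7	10	high
Gastric cancer	cancer	7	10	high
Crohn's colitis	inflammation	6	9	medium
Ulcerative colitis	inflammation	4	6	medium
Atrophic gastritis	inflammation	4	6	medium
Proliferative diabetic retinopathy	inflammation	6	9	medium
Old sepsis induced multiple organ failure	inflammation	6	9	medium
Rheumatoid arthritis	inflammation	4	6	medium
Osteoarthritis	inflammation	4	6	medium
Intrahepatic cancer	cancer	6	9	medium
Aortic occlusive disease	inflammation	3	4	low
Atherosclerosis	inflammation	3	4	low
Oxidized LDL	inflammation	3	4	low
Crohn's ileitis	inflammation	3	4	low
HP-Infection with corpus-predominant atrophic gastritis	inflammation	2	3	low
Alzheimer's disease	inflammation	3	4	low
Old (macular retina)	inflammation	2	3	low
Homozygous familial hypercholesterolemia	inflammation	2	3	low
Psoriasis	inflammation	2	3	low
Asthma patient	inflammation	1	1	low
Systemic lupus erythematosus	inflammation	0	0	low
Diabetic Kidney Disease	inflammation	0	0	low
Type 1 diabetes	inflammation	0	0	low
Metabolic syndrome	inflammation	0	0	low
Homocysteine (100 umol/L)	inflammation	0	0	low
Pancreatic tumors	cancer	0	0	low
Prostate cancer	cancer	0	0	low
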