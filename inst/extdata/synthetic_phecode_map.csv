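code,phecode,label,exclusion_range_start,exclusion_range_end,sex_flag
I48.0,427.21,Atrial fibrillation,427,427.99,
I48.1,427.21,Atrial fibrillation,427,427.99,
I48.2,427.21,Atrial fibrillation,427,427.99,
I48.3,427.22,Atrial flutter,427,427.99,
I48.4,427.22,Atrial flutter,427,427.99,
I47.1,427.11,Paroxysmal supraventricular tachycardia,427,427.99,
I49.9,427.5,Cardiac arrhythmia NOS,427,427.99,
I25.1,411.4,Coronary atherosclerosis,410,414.99,
I21.9,411.2,Myocardial infarction,410,414.99,
I20.9,411.1,Angina pectoris,410,414.99,
I50.9,428.2,Heart failure NOS,428,428.99,
I50.1,428.1,Congestive heart failure,428,428.99,
I10,401.1,Essential hypertension,401,405.99,
I11.9,401.2,Hypertensive heart disease,401,405.99,
E11.9,250.2,Type 2 diabetes,249,250.99,
E10.9,250.1,Type 1 diabetes,249,250.99,
E78.5,272.1,Hyperlipidemia,272,272.99,
E78.0,272.11,Hypercholesterolemia,272,272.99,
N18.9,585.3,Chronic kidney disease,585,585.99,
G47.33,327.3,Sleep apnea,327,327.99,
I63.9,433.21,Cerebral infarction,430,438.99,
E03.9,244.4,Hypothyroidism,240,246.99,
E05.9,242.2,Hyperthyroidism,240,246.99,
I35.0,395.1,Aortic valve stenosis,394,396.99,
I34.0,394.2,Mitral valve disease,394,396.99,
F17.2,318,Tobacco use disorder,,,
J44.9,496,Chronic airway obstruction,490,496.99,
M81.0,743.1,Osteoporosis,743,743.99,
C61,185,Prostate cancer,185,187.99,male
N80.9,615,Endometriosis,614,616.99,female
C50.9,174.1,Breast cancer,174,175.99,female
K21.9,530.11,GERD,530,530.99,
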