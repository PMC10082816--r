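code_system,icd_code,phecode,phenotype,category
ICD10CM,G30.1,290.11,Alzheimer's disease,mental disorders
ICD10CM,G30.8,290.11,Alzheimer's disease,mental disorders
ICD10CM,G30.9,290.11,Alzheimer's disease,mental disorders
ICD9CM,331.0,290.11,Alzheimer's disease,mental disorders
ICD10CM,F03.90,290.1,Dementias,mental disorders
ICD9CM,294.20,290.1,Dementias,mental disorders
ICD10CM,I10,401.1,Essential hypertension,circulatory system
ICD9CM,401.1,401.1,Essential hypertension,circulatory system
ICD9CM,401.9,401.1,Essential hypertension,circulatory system
ICD10CM,E11.9,250.2,Type 2 diabetes,endocrine/metabolic
ICD10CM,E11.65,250.2,Type 2 diabetes,endocrine/metabolic
ICD9CM,250.00,250.2,Type 2 diabetes,endocrine/metabolic
ICD10CM,E78.5,272.1,Hyperlipidemia,endocrine/metabolic
ICD9CM,272.4,272.1,Hyperlipidemia,endocrine/metabolic
ICD10CM,I50.9,428.2,Heart failure NOS,circulatory system
ICD9CM,428.0,428.2,Heart failure NOS,circulatory system
ICD10CM,I48.91,427.21,Atrial fibrillation,circulatory system
ICD9CM,427.31,427.21,Atrial fibrillation,circulatory system
ICD10CM,N18.9,585.3,Chronic renal failure [CKD],genitourinary
ICD9CM,585.9,585.3,Chronic renal failure [CKD],genitourinary
ICD10CM,N39.0,591,Urinary tract infection,genitourinary
ICD9CM,599.0,591,Urinary tract infection,genitourinary
ICD10CM,J44.9,496,Chronic airway obstruction,respiratory
ICD9CM,496,496,Chronic airway obstruction,respiratory
ICD10CM,J18.9,480,Pneumonia,respiratory
ICD9CM,486,480,Pneumonia,respiratory
ICD10CM,F32.9,296.2,Depression,mental disorders
ICD9CM,311,296.2,Depression,mental disorders
ICD10CM,F41.9,300.1,Anxiety disorder,mental disorders
ICD9CM,300.00,300.1,Anxiety disorder,mental disorders
ICD10CM,F31.9,296.1,Bipolar,mental disorders
ICD9CM,296.80,296.1,Bipolar,mental disorders
ICD10CM,I63.9,433.21,Cerebral ischemia,circulatory system
ICD9CM,434.91,433.21,Cerebral ischemia,circulatory system
ICD10CM,E03.9,244.4,Hypothyroidism NOS,endocrine/metabolic
ICD9CM,244.9,244.4,Hypothyroidism NOS,endocrine/metabolic
ICD10CM,M81.0,743.1,Osteoporosis,musculoskeletal
ICD9CM,733.00,743.1,Osteoporosis,musculoskeletal
ICD10CM,M19.90,740.9,Osteoarthrosis NOS,musculoskeletal
ICD9CM,715.90,740.9,Osteoarthrosis NOS,musculoskeletal
ICD10CM,D64.9,285,Anemia NOS,hematopoietic
ICD9CM,285.9,285,Anemia NOS,hematopoietic
ICD10CM,R26.81,350.2,Abnormality of gait,neurological
ICD9CM,781.2,350.2,Abnormality of gait,neurological
ICD10CM,G47.00,327.4,Insomnia,neurological
ICD9CM,780.52,327.4,Insomnia,neurological
ICD10CM,H90.3,389.1,Sensorineural hearing loss,sense organs
ICD9CM,389.10,389.1,Sensorineural hearing loss,sense organs
ICD10CM,H25.9,366.2,Senile cataract,sense organs
ICD9CM,366.10,366.2,Senile cataract,sense organs
ICD10CM,K21.9,530.11,GERD,digestive
ICD9CM,530.81,530.11,GERD,digestive
ICD10CM,K59.00,563,Constipation,digestive
ICD9CM,564.00,563,Constipation,digestive
ICD10CM,L30.9,939,Dermatitis NOS,dermatologic
ICD9CM,692.9,939,Dermatitis NOS,dermatologic
ICD10CM,J06.9,465,Acute upper respiratory infection,respiratory
ICD9CM,465.9,465,Acute upper respiratory infection,respiratory
ICD10CM,R41.82,292.4,Altered mental status,
ICD9CM,780.93,292.4,Altered mental status,
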