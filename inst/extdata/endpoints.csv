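id,label,codes,chapter,who_flag
tuberculosis,Tuberculosis,A15;A16;A17;A18;A19;B90,I,TRUE
lip_oral_pharynx_cancer,Cancer of lips oral cavity and pharynx,C00;C01;C02;C03;C04;C05;C06;C07;C08;C09;C10;C11;C12;C13;C14,II,TRUE
oesophageal_cancer,Oesophageal cancer,C15,II,TRUE
stomach_cancer,Stomach cancer,C16,II,FALSE
colon_cancer,Colon cancer,C18,II,TRUE
rectal_cancer,Rectal cancer,C19;C20,II,TRUE
liver_cancer,Liver cancer,C22,II,TRUE
larynx_cancer,Laryngeal cancer,C32,II,TRUE
lung_cancer,Lung cancer,C34,II,FALSE
purpura_haemorrhagic,Purpura and other haemorrhagic conditions,D69,III,FALSE
other_nontoxic_goiter,Other nontoxic goiter,E04,IV,FALSE
diabetes,Diabetes mellitus,E10;E11;E12;E13;E14,IV,TRUE
epilepsy,Epilepsy,G40;G41,VI,TRUE
transient_ischaemic_attack,Transient cerebral ischaemic attacks,G45,VI,TRUE
cataract,Cataract,H25;H26,VII,FALSE
hypertension,Essential primary hypertension,I10,IX,TRUE
hypertensive_heart_disease,Hypertensive heart disease,I11,IX,TRUE
angina,Angina pectoris,I20,IX,FALSE
acute_mi,Acute myocardial infarction,I21,IX,FALSE
chronic_ihd,Chronic ischaemic heart disease,I25,IX,TRUE
cardiomyopathy,Cardiomyopathy,I42,IX,TRUE
atrial_fibrillation,Atrial fibrillation and flutter,I48,IX,FALSE
intracerebral_haemorrhage,Intracerebral haemorrhage,I61,IX,TRUE
cerebral_infarction,Cerebral infarction,I63,IX,TRUE
occlusion_stenosis_cerebral,Occlusion and stenosis of cerebral arteries,I65;I66,IX,TRUE
other_cerebrovascular,Other cerebrovascular diseases,I67,IX,TRUE
sequelae_cerebrovascular,Sequelae of cerebrovascular disease,I69,IX,TRUE
pneumonia,Pneumonia,J12;J13;J14;J15;J16;J17;J18,X,TRUE
copd,Other chronic obstructive pulmonary disease,J44,X,FALSE
gerd,Gastro-oesophageal reflux disease,K21,XI,FALSE
gastric_ulcer,Gastric ulcer,K25,XI,FALSE
inguinal_hernia,Inguinal hernia,K40,XI,FALSE
alcoholic_liver_disease,Alcoholic liver disease,K70,XI,TRUE
liver_cirrhosis,Fibrosis and cirrhosis of liver,K74,XI,TRUE
pancreatitis,Pancreatitis,K85;K86,XI,TRUE
gout,Gout,M10,XIII,FALSE
renal_colic,Renal colic and calculus,N20,XIV,FALSE
prostate_hyperplasia,Hyperplasia of prostate,N40,XIV,FALSE
abdominal_pain,Abdominal and pelvic pain,R10,XVIII,FALSE
fracture_rib_sternum,Fracture of rib sternum or thoracic spine,S22,XIX,FALSE
fracture_shoulder_arm,Fracture of shoulder and upper arm,S42,XIX,FALSE
fracture_femur,Fracture of femur,S72,XIX,FALSE
falls,Falls,W00;W01;W05;W06;W10;W13;W17;W18;W19,XX,TRUE
self_harm,Intentional self-harm,X60;X64;X70;X78;X80;X84,XX,TRUE
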