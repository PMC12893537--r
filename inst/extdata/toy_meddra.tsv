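pt	soc
haematoma	vascular disorders
haemorrhage	vascular disorders
haemorrhagic shock	vascular disorders
muscle haemorrhage	vascular disorders
deep vein thrombosis	vascular disorders
pulmonary embolism	vascular disorders
anaemia	blood and lymphatic system disorders
thrombocytopenia	blood and lymphatic system disorders
heparin-induced thrombocytopenia	blood and lymphatic system disorders
thrombosis with thrombocytopenia syndrome	blood and lymphatic system disorders
eosinophilia	blood and lymphatic system disorders
thrombocytosis	blood and lymphatic system disorders
leukocytosis	blood and lymphatic system disorders
normochromic normocytic anaemia	blood and lymphatic system disorders
coagulation factor x level abnormal	investigations
haemoglobin decreased	investigations
platelet count decreased	investigations
renal failure	renal and urinary disorders
haematuria	renal and urinary disorders
hepatic function abnormal	hepatobiliary disorders
abortion spontaneous	pregnancy, puerperium and perinatal conditions
gastrointestinal haemorrhage	gastrointestinal disorders
melaena	gastrointestinal disorders
nausea	gastrointestinal disorders
incision site haematoma	injury, poisoning and procedural complications
post procedural haemorrhage	injury, poisoning and procedural complications
epistaxis	respiratory, thoracic and mediastinal disorders
dyspnoea	respiratory, thoracic and mediastinal disorders
myocardial infarction	cardiac disorders
atrial fibrillation	cardiac disorders
cerebral haemorrhage	nervous system disorders
headache	nervous system disorders
dizziness	nervous system disorders
hip arthroplasty	surgical and medical procedures
rash	skin and subcutaneous tissue disorders
ecchymosis	skin and subcutaneous tissue disorders
arthralgia	musculoskeletal and connective tissue disorders
back pain	musculoskeletal and connective tissue disorders
pyrexia	general disorders and administration site conditions
injection site pain	general disorders and administration site conditions
fatigue	general disorders and administration site conditions
congenital coagulopathy	congenital, familial and genetic disorders
hypothyroidism	endocrine disorders
menorrhagia	reproductive system and breast disorders
neoplasm malignant	neoplasms benign, malignant and unspecified (incl cysts and polyps)
decreased appetite	metabolism and nutrition disorders
hyperkalaemia	metabolism and nutrition disorders
anaphylactic reaction	immune system disorders
hypersensitivity	immune system disorders
conjunctival haemorrhage	eye disorders
vision blurred	eye disorders
pneumonia	infections and infestations
urinary tract infection	infections and infestations
vertigo	ear and labyrinth disorders
tinnitus	ear and labyrinth disorders
insomnia	psychiatric disorders
anxiety	psychiatric disorders
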