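pt	soc
death	General disorders and administration site conditions
disease progression	General disorders and administration site conditions
drug ineffective	General disorders and administration site conditions
fatigue	General disorders and administration site conditions
condition aggravated	General disorders and administration site conditions
asthenia	General disorders and administration site conditions
therapeutic response unexpected	General disorders and administration site conditions
gait disturbance	General disorders and administration site conditions
no adverse event	General disorders and administration site conditions
gait inability	General disorders and administration site conditions
adverse event	General disorders and administration site conditions
general physical health deterioration	General disorders and administration site conditions
energy increased	General disorders and administration site conditions
adverse drug reaction	General disorders and administration site conditions
catheter site swelling	General disorders and administration site conditions
catheter site pain	General disorders and administration site conditions
infusion site extravasation	General disorders and administration site conditions
catheter site thrombosis	General disorders and administration site conditions
infusion site pain	General disorders and administration site conditions
secretion discharge	General disorders and administration site conditions
loss of control of legs	General disorders and administration site conditions
amyotrophic lateral sclerosis	Nervous system disorders
aphasia	Nervous system disorders
speech disorder	Nervous system disorders
cerebral infarction	Nervous system disorders
balance disorder	Nervous system disorders
cerebral haemorrhage	Nervous system disorders
dysarthria	Nervous system disorders
muscle contractions involuntary	Nervous system disorders
dysstasia	Nervous system disorders
subarachnoid haemorrhage	Nervous system disorders
headache	Nervous system disorders
dizziness	Nervous system disorders
respiratory distress	Respiratory, thoracic and mediastinal disorders
respiratory failure	Respiratory, thoracic and mediastinal disorders
respiratory arrest	Respiratory, thoracic and mediastinal disorders
dependence on respirator	Respiratory, thoracic and mediastinal disorders
aspiration	Respiratory, thoracic and mediastinal disorders
sputum retention	Respiratory, thoracic and mediastinal disorders
acute lung injury	Respiratory, thoracic and mediastinal disorders
muscular weakness	Musculoskeletal and connective tissue disorders
muscle twitching	Musculoskeletal and connective tissue disorders
pneumonia aspiration	Infections and infestations
pneumonia	Infections and infestations
device related infection	Infections and infestations
injection site infection	Infections and infestations
deep vein thrombosis	Vascular disorders
vasculitis	Vascular disorders
vein collapse	Vascular disorders
transaminases increased	Investigations
blood urea increased	Investigations
cystatin c increased	Investigations
hepatic function abnormal	Hepatobiliary disorders
cardiac arrest	Cardiac disorders
dysphagia	Gastrointestinal disorders
gastric fistula	Gastrointestinal disorders
gastric ulcer	Gastrointestinal disorders
nausea	Gastrointestinal disorders
vomiting	Gastrointestinal disorders
gastrostomy site leakage	Injury, poisoning and procedural complications
fall	Injury, poisoning and procedural complications
insomnia	Psychiatric disorders
rash	Skin and subcutaneous tissue disorders
disseminated intravascular coagulation	Blood and lymphatic system disorders
acute kidney injury	Renal and urinary disorders
nephrotic syndrome	Renal and urinary disorders
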