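soc,case_reports,ic,ic025
General disorders and administration site conditions,2140,1.24,1.16
Nervous system disorders,717,0.87,0.76
"Respiratory, thoracic and mediastinal disorders",358,0.61,0.45
Vascular disorders,93,-0.07,-0.36
Musculoskeletal and connective tissue disorders,238,-0.14,-0.33
Infections and infestations,242,-0.22,-0.41
Hepatobiliary disorders,28,-0.62,-1.14
Cardiac disorders,66,-0.67,-1.02
Metabolism and nutrition disorders,63,-0.7,-1.06
Investigations,160,-0.9,-1.13
Renal and urinary disorders,50,-1.06,-1.45
"Injury, poisoning and procedural complications",289,-1.04,-1.21
Gastrointestinal disorders,196,-1.09,-1.29
Skin and subcutaneous tissue disorders,127,-1.25,-1.5
Immune system disorders,24,-1.4,-1.97
Psychiatric disorders,82,-1.75,-2.06
Blood and lymphatic system disorders,25,-1.79,-2.34
Ear and labyrinth disorders,6,-1.87,-2.94
Eye disorders,15,-2.73,-3.44
"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",15,-3.5,-4.21
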