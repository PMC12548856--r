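variable,level,count
sex,Female,796
sex,Male,1193
sex,Unknown,942
age,<18,8
age,18-45,35
age,45-60,208
age,>=60,663
age,Unknown,2017
reporter,Consumer,1724
reporter,Physician,647
reporter,Pharmacist,285
reporter,OtherHealthProfessional,271
reporter,Unknown,3
reporter,Lawyer,1
country,US,2287
country,JP,461
country,Other,183
route,other,1274
route,intravenous,1015
route,intravenous drip,426
route,oral,190
route,parenteral,26
outcome,Death,962
outcome,Other serious,375
outcome,Hospitalization,362
outcome,Life threatening,19
outcome,Disability,11
outcome,Required intervention,5
onset,<7,134
onset,7-28,76
onset,28-60,34
onset,>=60,160
onset,Unknown,838
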