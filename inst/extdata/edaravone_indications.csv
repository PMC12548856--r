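term,count,percent
amyotrophic lateral sclerosis,2025,72.45
product used for unknown indication,675,24.15
cerebral infarction,58,2.08
thrombotic cerebral infarction,5,0.18
lacunar infarction,3,0.11
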