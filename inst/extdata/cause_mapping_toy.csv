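"cause","disease_id"
"Ischemic heart disease","IHD"
"Low back pain","LBP"
"Chronic liver disease","CLD"
"Major depressive disorder","MDD"
"Asthma","ASTHMA"
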