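"cause","sex","measure","val"
"Ischemic heart disease","Male","DALYs (Disability-Adjusted Life Years)",3450.2
"Ischemic heart disease","Female","DALYs (Disability-Adjusted Life Years)",1620.8
"Ischemic heart disease","Both","DALYs (Disability-Adjusted Life Years)",2535.5
"Low back pain","Male","DALYs (Disability-Adjusted Life Years)",1210.4
"Low back pain","Female","DALYs (Disability-Adjusted Life Years)",1480.6
"Low back pain","Both","DALYs (Disability-Adjusted Life Years)",1345.5
"Chronic liver disease","Male","DALYs (Disability-Adjusted Life Years)",412.6
"Chronic liver disease","Female","DALYs (Disability-Adjusted Life Years)",171.4
"Chronic liver disease","Both","DALYs (Disability-Adjusted Life Years)",292.0
"Major depressive disorder","Male","DALYs (Disability-Adjusted Life Years)",610.3
"Major depressive disorder","Female","DALYs (Disability-Adjusted Life Years)",940.7
"Major depressive disorder","Both","DALYs (Disability-Adjusted Life Years)",775.5
"Asthma","Male","DALYs (Disability-Adjusted Life Years)",320.9
"Asthma","Female","DALYs (Disability-Adjusted Life Years)",355.1
"Asthma","Both","DALYs (Disability-Adjusted Life Years)",338.0
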