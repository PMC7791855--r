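block,category,arm,round,n,percent
age,18–24,5pt,1,2,2
age,18–24,9pt,1,1,1
age,18–24,5pt,2,1,1
age,18–24,9pt,2,0,0
age,18–24,5pt,3,1,1
age,18–24,9pt,3,0,0
age,25–34,5pt,1,19,19
age,25–34,9pt,1,22,21
age,25–34,5pt,2,16,21
age,25–34,9pt,2,12,17
age,25–34,5pt,3,13,19
age,25–34,9pt,3,9,14
age,35–44,5pt,1,34,34
age,35–44,9pt,1,40,38
age,35–44,5pt,2,23,30
age,35–44,9pt,2,28,39
age,35–44,5pt,3,20,29
age,35–44,9pt,3,24,38
age,45–54,5pt,1,24,24
age,45–54,9pt,1,20,19
age,45–54,5pt,2,19,25
age,45–54,9pt,2,16,23
age,45–54,5pt,3,18,26
age,45–54,9pt,3,15,24
age,55–64,5pt,1,18,18
age,55–64,9pt,1,15,14
age,55–64,5pt,2,15,20
age,55–64,9pt,2,11,15
age,55–64,5pt,3,15,22
age,55–64,9pt,3,11,17
age,65+,5pt,1,4,4
age,65+,9pt,1,6,6
age,65+,5pt,2,2,3
age,65+,9pt,2,4,6
age,65+,5pt,3,2,3
age,65+,9pt,3,4,6
stakeholder,clinician,5pt,1,43,43
stakeholder,clinician,9pt,1,48,46
stakeholder,clinician,5pt,2,30,39
stakeholder,clinician,9pt,2,29,41
stakeholder,clinician,5pt,3,27,39
stakeholder,clinician,9pt,3,25,40
stakeholder,clinician_researcher,5pt,1,23,23
stakeholder,clinician_researcher,9pt,1,15,14
stakeholder,clinician_researcher,5pt,2,19,25
stakeholder,clinician_researcher,9pt,2,14,20
stakeholder,clinician_researcher,5pt,3,19,28
stakeholder,clinician_researcher,9pt,3,14,22
stakeholder,patient,5pt,1,20,20
stakeholder,patient,9pt,1,22,21
stakeholder,patient,5pt,2,14,18
stakeholder,patient,9pt,2,12,17
stakeholder,patient,5pt,3,10,14
stakeholder,patient,9pt,3,8,13
stakeholder,researcher,5pt,1,10,10
stakeholder,researcher,9pt,1,13,13
stakeholder,researcher,5pt,2,10,13
stakeholder,researcher,9pt,2,11,15
stakeholder,researcher,5pt,3,10,14
stakeholder,researcher,9pt,3,11,17
stakeholder,service_provider_policy_maker,5pt,1,5,5
stakeholder,service_provider_policy_maker,9pt,1,6,6
stakeholder,service_provider_policy_maker,5pt,2,3,4
stakeholder,service_provider_policy_maker,9pt,2,5,7
stakeholder,service_provider_policy_maker,5pt,3,3,4
stakeholder,service_provider_policy_maker,9pt,3,5,8
gender,Female,5pt,1,73,72
gender,Female,9pt,1,86,83
gender,Female,5pt,2,57,75
gender,Female,9pt,2,57,80
gender,Female,5pt,3,51,74
gender,Female,9pt,3,50,79
gender,Male,5pt,1,27,27
gender,Male,9pt,1,18,17
gender,Male,5pt,2,19,25
gender,Male,9pt,2,14,25
gender,Male,5pt,3,18,26
gender,Male,9pt,3,13,21
gender,Prefer not to say,5pt,1,1,0
gender,Prefer not to say,9pt,1,0,0
gender,Prefer not to say,5pt,2,0,0
gender,Prefer not to say,9pt,2,0,0
gender,Prefer not to say,5pt,3,0,0
gender,Prefer not to say,9pt,3,0,0
country,Argentina,5pt,1,1,1
country,Argentina,9pt,1,0,0
country,Argentina,5pt,2,0,0
country,Argentina,9pt,2,0,0
country,Argentina,5pt,3,0,0
country,Argentina,9pt,3,0,0
country,Australia,5pt,1,4,4
country,Australia,9pt,1,4,4
country,Australia,5pt,2,3,4
country,Australia,9pt,2,3,4
country,Australia,5pt,3,3,4
country,Australia,9pt,3,3,5
country,Austria,5pt,1,1,1
country,Austria,9pt,1,0,0
country,Austria,5pt,2,1,1
country,Austria,9pt,2,0,0
country,Austria,5pt,3,1,1
country,Austria,9pt,3,0,0
country,Belgium,5pt,1,3,3
country,Belgium,9pt,1,1,1
country,Belgium,5pt,2,3,4
country,Belgium,9pt,2,1,1
country,Belgium,5pt,3,3,4
country,Belgium,9pt,3,1,2
country,Brazil,5pt,1,1,1
country,Brazil,9pt,1,0,0
country,Brazil,5pt,2,1,1
country,Brazil,9pt,2,0,0
country,Brazil,5pt,3,1,1
country,Brazil,9pt,3,0,0
country,Canada,5pt,1,6,6
country,Canada,9pt,1,11,11
country,Canada,5pt,2,4,5
country,Canada,9pt,2,9,13
country,Canada,5pt,3,4,6
country,Canada,9pt,3,9,14
country,Colombia,5pt,1,1,1
country,Colombia,9pt,1,0,0
country,Colombia,5pt,2,1,1
country,Colombia,9pt,2,0,0
country,Colombia,5pt,3,1,1
country,Colombia,9pt,3,0,0
country,Cook Islands,5pt,1,0,0
country,Cook Islands,9pt,1,1,1
country,Cook Islands,5pt,2,0,0
country,Cook Islands,9pt,2,0,0
country,Cook Islands,5pt,3,0,0
country,Cook Islands,9pt,3,0,0
country,Croatia,5pt,1,1,1
country,Croatia,9pt,1,0,0
country,Croatia,5pt,2,0,0
country,Croatia,9pt,2,0,0
country,Croatia,5pt,3,0,0
country,Croatia,9pt,3,0,0
country,Denmark,5pt,1,1,1
country,Denmark,9pt,1,2,2
country,Denmark,5pt,2,1,1
country,Denmark,9pt,2,2,3
country,Denmark,5pt,3,1,1
country,Denmark,9pt,3,2,3
country,Egypt,5pt,1,0,0
country,Egypt,9pt,1,1,1
country,Egypt,5pt,2,0,0
country,Egypt,9pt,2,0,0
country,Egypt,5pt,3,0,0
country,Egypt,9pt,3,0,0
country,Finland,5pt,1,1,1
country,Finland,9pt,1,0,0
country,Finland,5pt,2,1,1
country,Finland,9pt,2,0,0
country,Finland,5pt,3,1,1
country,Finland,9pt,3,0,0
country,Germany,5pt,1,1,1
country,Germany,9pt,1,0,0
country,Germany,5pt,2,1,1
country,Germany,9pt,2,0,0
country,Germany,5pt,3,1,1
country,Germany,9pt,3,0,0
country,Iceland,5pt,1,1,1
country,Iceland,9pt,1,0,0
country,Iceland,5pt,2,0,0
country,Iceland,9pt,2,0,0
country,Iceland,5pt,3,0,0
country,Iceland,9pt,3,0,0
country,Iran,5pt,1,0,0
country,Iran,9pt,1,2,2
country,Iran,5pt,2,0,0
country,Iran,9pt,2,2,3
country,Iran,5pt,3,0,0
country,Iran,9pt,3,2,3
country,Ireland,5pt,1,26,26
country,Ireland,9pt,1,19,18
country,Ireland,5pt,2,18,24
country,Ireland,9pt,2,13,18
country,Ireland,5pt,3,14,20
country,Ireland,9pt,3,10,16
country,Israel,5pt,1,1,1
country,Israel,9pt,1,0,0
country,Israel,5pt,2,1,1
country,Israel,9pt,2,0,0
country,Israel,5pt,3,1,1
country,Israel,9pt,3,0,0
country,Malaysia,5pt,1,4,4
country,Malaysia,9pt,1,0,0
country,Malaysia,5pt,2,2,3
country,Malaysia,9pt,2,0,0
country,Malaysia,5pt,3,2,3
country,Malaysia,9pt,3,0,0
country,Mexico,5pt,1,0,0
country,Mexico,9pt,1,3,3
country,Mexico,5pt,2,0,0
country,Mexico,9pt,2,3,4
country,Mexico,5pt,3,0,0
country,Mexico,9pt,3,2,3
country,Nepal,5pt,1,2,2
country,Nepal,9pt,1,0,0
country,Nepal,5pt,2,2,3
country,Nepal,9pt,2,0,0
country,Nepal,5pt,3,2,3
country,Nepal,9pt,3,0,0
country,Netherlands,5pt,1,3,3
country,Netherlands,9pt,1,1,1
country,Netherlands,5pt,2,3,4
country,Netherlands,9pt,2,1,1
country,Netherlands,5pt,3,3,4
country,Netherlands,9pt,3,1,2
country,New Zealand,5pt,1,1,1
country,New Zealand,9pt,1,2,2
country,New Zealand,5pt,2,1,1
country,New Zealand,9pt,2,1,1
country,New Zealand,5pt,3,1,1
country,New Zealand,9pt,3,1,2
country,Norway,5pt,1,7,7
country,Norway,9pt,1,7,7
country,Norway,5pt,2,7,9
country,Norway,9pt,2,4,6
country,Norway,5pt,3,7,10
country,Norway,9pt,3,4,6
country,Philippines,5pt,1,0,0
country,Philippines,9pt,1,1,1
country,Philippines,5pt,2,0,0
country,Philippines,9pt,2,0,0
country,Philippines,5pt,3,0,0
country,Philippines,9pt,3,0,0
country,Poland,5pt,1,0,0
country,Poland,9pt,1,1,1
country,Poland,5pt,2,0,0
country,Poland,9pt,2,1,1
country,Poland,5pt,3,0,0
country,Poland,9pt,3,1,2
country,Portugal,5pt,1,1,1
country,Portugal,9pt,1,2,2
country,Portugal,5pt,2,1,1
country,Portugal,9pt,2,1,1
country,Portugal,5pt,3,1,1
country,Portugal,9pt,3,1,2
country,South Africa,5pt,1,0,0
country,South Africa,9pt,1,1,1
country,South Africa,5pt,2,0,0
country,South Africa,9pt,2,1,1
country,South Africa,5pt,3,0,0
country,South Africa,9pt,3,1,2
country,Sweden,5pt,1,11,11
country,Sweden,9pt,1,15,14
country,Sweden,5pt,2,9,12
country,Sweden,9pt,2,9,13
country,Sweden,5pt,3,9,13
country,Sweden,9pt,3,9,14
country,Switzerland,5pt,1,1,1
country,Switzerland,9pt,1,3,3
country,Switzerland,5pt,2,1,1
country,Switzerland,9pt,2,3,4
country,Switzerland,5pt,3,0,0
country,Switzerland,9pt,3,3,5
country,UK,5pt,1,11,11
country,UK,9pt,1,17,16
country,UK,5pt,2,8,11
country,UK,9pt,2,9,13
country,UK,5pt,3,7,10
country,UK,9pt,3,5,8
country,USA,5pt,1,11,11
country,USA,9pt,1,9,9
country,USA,5pt,2,7,9
country,USA,9pt,2,7,10
country,USA,5pt,3,6,9
country,USA,9pt,3,7,11
country,Zimbabwe,5pt,1,0,0
country,Zimbabwe,9pt,1,1,1
country,Zimbabwe,5pt,2,0,0
country,Zimbabwe,9pt,2,1,1
country,Zimbabwe,5pt,3,0,0
country,Zimbabwe,9pt,3,1,2
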