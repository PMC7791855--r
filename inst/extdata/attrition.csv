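group,arm,transition,percent
clinician,5pt,r1_to_r2,30
clinician,5pt,r2_to_r3,10
clinician,5pt,overall,37
clinician,9pt,r1_to_r2,40
clinician,9pt,r2_to_r3,14
clinician,9pt,overall,48
clinician_researcher,5pt,r1_to_r2,17
clinician_researcher,5pt,r2_to_r3,0
clinician_researcher,5pt,overall,17
clinician_researcher,9pt,r1_to_r2,7
clinician_researcher,9pt,r2_to_r3,0
clinician_researcher,9pt,overall,7
patient,5pt,r1_to_r2,30
patient,5pt,r2_to_r3,29
patient,5pt,overall,50
patient,9pt,r1_to_r2,45
patient,9pt,r2_to_r3,33
patient,9pt,overall,64
researcher,5pt,r1_to_r2,0
researcher,5pt,r2_to_r3,0
researcher,5pt,overall,0
researcher,9pt,r1_to_r2,15
researcher,9pt,r2_to_r3,0
researcher,9pt,overall,15
service_provider_policy_maker,5pt,r1_to_r2,40
service_provider_policy_maker,5pt,r2_to_r3,0
service_provider_policy_maker,5pt,overall,40
service_provider_policy_maker,9pt,r1_to_r2,17
service_provider_policy_maker,9pt,r2_to_r3,0
service_provider_policy_maker,9pt,overall,17
overall,5pt,r1_to_r2,25
overall,5pt,r2_to_r3,9
overall,5pt,overall,32
overall,9pt,r1_to_r2,32
overall,9pt,r2_to_r3,11
overall,9pt,overall,39
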