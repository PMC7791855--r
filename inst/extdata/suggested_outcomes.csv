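raw_text,outcome_name,decision,mapped_outcome_id
Alternative therapy - impact and access,,not_an_outcome,
"Likelihood of planning subsequent pregnancies, due to risk of reoccurrence",Likelihood of planning subsequent pregnancies,include_new,likelihood_of_planning_subsequent_pregnancies
Onset of PGP: pregnancy week or postpartum,,not_an_outcome,
Maternal comorbidities,,not_an_outcome,
"Inability to bond with child, relationship damage",Family life Impact,already_included,family_life_impact
Information on lactation,Function,already_included,function_disability_activity_limitation
Menstruation when returned after birth and PGP in connection with menstruation,Symptoms during menstruation,include_new,symptoms_during_menstruation
Postnatal experiences of PGP,,not_an_outcome,
Length of time to become pain free again,Full symptom recovery,already_included,recovery_of_symptoms
Mattress and cushion needs to relieve pressure on the pelvic girdle,Needs for additional supports,include_new,need_for_additional_supports
Need for help with taking care of the baby,Dependence on others,already_included,dependence_on_others
Need for help with daily housework,Activity Daily Life,already_included,function_disability_activity_limitation
Perseverance in standing,Function,already_included,function_disability_activity_limitation
Accessibility of treatment,,not_an_outcome,
Hormonal influence on ability and pain,,not_an_outcome,
Fitness levels prior to pain onset,Exercise/activity levels,already_included,physical_activity_levels_exercise_limitations
How long the PGP pain has lasted,Pain duration,include_new,pain_duration_pain_pattern
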