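outcome_id,name,sources,first_round
pain_behaviour,Pain behaviour,systematic_review,1
pain_character_type,Pain character/type,interview,1
pain_frequency,Pain frequency,systematic_review,1
pain_intensity_severity,Pain intensity/severity,systematic_review,1
pain_location,Pain location,systematic_review,1
full_pain_recovery,Full pain recovery,systematic_review,1
function_disability_activity_limitation,Function/disability/activity limitation,systematic_review,1
physical_activity_levels_exercise_limitations,Physical activity levels/exercise limitations,systematic_review,1
need_for_mobility_aid,Need for mobility aid,interview,1
perceived_body_imbalance,Perceived body imbalance,interview,1
sexual_functioning,Sexual functioning,interview,1
health_related_quality_of_life,Health related quality of life,systematic_review,1
health_status,Health status,systematic_review,1
family_life_impact,Family life impact,interview,1
social_life_impact,Social life impact,interview,1
patient_satisfaction_with_life,Patient satisfaction with life,systematic_review,1
patient_satisfaction_with_treatment,Patient satisfaction with treatment,systematic_review,1
patient_expectations_of_treatment,Patient expectations of treatment,systematic_review,1
anxiety,Anxiety,systematic_review,1
confidence,Confidence,systematic_review,1
depression,Depression,systematic_review,1
dependence_on_others,Dependence on others,systematic_review,1
emotional_symptoms,Emotional symptoms,interview,1
fear_avoidance,Fear avoidance,systematic_review,1
frustration,Frustration,interview,1
pain_catastrophizing,Pain catastrophizing,systematic_review,1
self_efficacy,Self-efficacy,systematic_review,1
well_being,Well-being,systematic_review,1
fatigue,Fatigue,systematic_review,1
sleep_function,Sleep function,systematic_review,1
work_ability,Work ability,systematic_review,1
work_performance,Work performance,systematic_review,1
analgesia_use,Analgesia use,systematic_review,1
cost,Cost,systematic_review,1
healthcare_utilisation,Healthcare utilisation,systematic_review,1
anthropomorphic_outcomes,Anthropomorphic outcomes,systematic_review,1
body_flexibility,Body flexibility,systematic_review,1
functional_mobility,Functional mobility,systematic_review,1
gait_endurance,Gait endurance,systematic_review,1
gait_speed,Gait speed,systematic_review,1
new_born_outcomes,New-born outcomes,systematic_review,1
outcomes_from_pain_provocation_location_tests,Outcomes from pain provocation/location tests,systematic_review,1
posture,Posture,systematic_review,1
pubis_symphysis_mobility,Pubis symphysis mobility,systematic_review,1
maternal_pregnancy_outcomes,Maternal pregnancy outcomes,systematic_review,1
muscle_endurance,Muscle endurance,systematic_review,1
muscle_strength,Muscle strength,systematic_review,1
recovery_of_symptoms,Recovery of symptoms,systematic_review,1
step_length,Step length,systematic_review,1
surgical_outcomes,Surgical outcomes,systematic_review,1
urinary_incontinence,Urinary Incontinence,systematic_review,1
maternal_adverse_outcomes_undesirable_effects,Maternal adverse outcomes/undesirable effects,systematic_review,1
unborn_born_adverse_outcomes_undesirable_effects,Unborn/born adverse outcomes/ undesirable effects,systematic_review,1
breathing_function,Breathing function,round1_suggestion,2
clinical_findings_on_motion_palpation_joint_play_of_pelvic_girdle_joints,Clinical findings on motion palpation/joint play of pelvic girdle joints,round1_suggestion,2
coping_strategies_coping_styles,Coping strategies/coping styles,round1_suggestion,2
global_perceived_improvement_global_rate_of_change,Global perceived improvement/global rate of change,round1_suggestion,2
goal_attainment,Goal attainment,round1_suggestion,2
likelihood_of_planning_subsequent_pregnancies,Likelihood of planning subsequent pregnancies,round1_suggestion,2
motor_control_movement_strategies_movement_patterns,Motor control/movement strategies/ movement patterns,round1_suggestion,2
muscle_tightness,Muscle tightness,round1_suggestion,2
need_for_additional_supports,Need for additional supports,round1_suggestion,2
outcomes_from_functional_tests,Outcomes from functional tests,round1_suggestion,2
pain_duration_pain_pattern,Pain duration/pain pattern,round1_suggestion,2
patients_beliefs_about_pain_meaning_of_complaints_to_patient,Patients beliefs about pain/meaning of complaints to patient,round1_suggestion,2
patient_understanding_knowledge_of_pgp,Patient understanding/knowledge of PGP,round1_suggestion,2
postural_observation,Postural observation,round1_suggestion,2
symptoms_during_menstruation,Symptoms during menstruation,round1_suggestion,2
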